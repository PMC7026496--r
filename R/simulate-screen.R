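#' Ground truth for a simulated high-throughput viability screen
#'
#' Bundles everything the screen simulator needs: a compound catalog with
#' target and pathway annotations, the true killing fraction per compound,
#' which targets/pathways are planted as sensitive, the multiplicative
#' measurement noise, and the seed.
#'
#' @param annotations Tibble/data frame with columns `compound_id`, `target`,
#'   `pathway` (one row per compound).
#' @param true_killing Named numeric vector, one entry per compound, each in
#'   \[-0.5, 1\]. Negative values model growth stimulation.
#' @param sensitive_targets,sensitive_pathways Character vectors naming the
#'   planted sensitive groups (bookkeeping only; the killing values carry the
#'   actual signal).
#' @param noise_cv Coefficient of variation of the lognormal well noise
#'   (dimensionless, >= 0).
#' @param seed Integer seed; the same truth simulates to identical tables.
#'
#' @return An object of class `screen_truth`.
#' @export
screen_truth <- function(annotations, true_killing,
                         sensitive_targets = character(),
                         sensitive_pathways = character(),
                         noise_cv = 0.1, seed = 1L) {
  annotations <- as_tibble(annotations)
  stopifnot(all(c("compound_id", "target", "pathway") %in% names(annotations)))
  if (anyDuplicated(annotations$compound_id)) {
    abort("`annotations$compound_id` must be unique.")
  }
  if (is.null(names(true_killing)) || any(names(true_killing) == "")) {
    abort("`true_killing` must be named by compound_id.")
  }
  missing <- setdiff(names(true_killing), annotations$compound_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "Compounds in `true_killing` absent from the catalog: %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  if (any(true_killing < -0.5 | true_killing > 1)) {
    abort("`true_killing` fractions must lie in [-0.5, 1].")
  }
  check_scalar_number(noise_cv, "noise_cv", lower = 0)
  structure(
    list(
      annotations = annotations,
      true_killing = true_killing,
      sensitive_targets = sensitive_targets,
      sensitive_pathways = sensitive_pathways,
      noise_cv = noise_cv,
      seed = as.integer(seed)
    ),
    class = "screen_truth"
  )
}

#' Example screen truth emulating a 2,100-compound annotated library
#'
#' Builds a catalog of `n_compounds` compounds spread over annotated targets
#' nested within pathways, and plants one clearly sensitive pathway: all of
#' its compounds get high true killing. Background killing fractions are
#' drawn so that roughly 6.6% of the library exceeds 50% killing and 4.2%
#' exceeds 75%, the hit-rate regime of a bioactive library screened at 1 uM
#' on a sensitive sarcoma line; the bulk of compounds cluster near zero
#' effect, some mildly growth-stimulatory.
#'
#' @param seed Integer seed.
#' @param n_compounds Library size.
#' @param n_pathways Number of annotated pathways; targets are nested 3 per
#'   pathway, so pathway classes average ~15 drugs at the default library
#'   size (the scale of real annotated inhibitor classes).
#' @param sensitive_pathway Name given to the planted sensitive pathway.
#' @param noise_cv Well-level noise CV passed through to the truth.
#' @return A [screen_truth()] object.
#' @export
example_screen_truth <- function(seed = 1L, n_compounds = 2100L,
                                 n_pathways = 140L,
                                 sensitive_pathway = "proteasome",
                                 noise_cv = 0.1) {
  n_compounds <- as.integer(n_compounds)
  n_pathways <- as.integer(n_pathways)
  stopifnot(n_compounds >= n_pathways * 3L)
  with_seed(seed, {
    pathways <- c(sensitive_pathway,
                  sprintf("pathway_%02d", seq_len(n_pathways - 1L)))
    targets <- paste0(rep(pathways, each = 3L), "_t",
                      rep(1:3, times = n_pathways))
    ann <- tibble(
      compound_id = sprintf("CPD%04d", seq_len(n_compounds)),
      target = sample(targets, n_compounds, replace = TRUE),
      pathway = stringr::str_remove(.data$target, "_t[0-9]+$")
    )
    # background: mild effects centred on zero, clipped below the 50% line
    killing <- pmin(pmax(rnorm(n_compounds, 0, 0.12), -0.5), 0.45)
    # planted sensitive pathway: uniformly strong killers
    sens <- which(ann$pathway == sensitive_pathway)
    killing[sens] <- runif(length(sens), 0.85, 0.98)
    # extra scattered hits so the library-wide hit fractions sit near the
    # 6.6% / 4.2% regime: top up to 4.2% above 0.75 and 2.4% in (0.5, 0.7)
    n_hi <- max(0L, round(0.042 * n_compounds) - length(sens))
    pool <- setdiff(seq_len(n_compounds), sens)
    hi <- sample(pool, n_hi)
    killing[hi] <- runif(n_hi, 0.78, 0.97)
    mid <- sample(setdiff(pool, hi), round(0.024 * n_compounds))
    killing[mid] <- runif(length(mid), 0.55, 0.70)
    screen_truth(
      annotations = ann,
      true_killing = setNames(killing, ann$compound_id),
      sensitive_targets = unique(ann$target[sens]),
      sensitive_pathways = sensitive_pathway,
      noise_cv = noise_cv,
      seed = seed
    )
  })
}

#' Plate geometry for the screen simulator
#'
#' @param wells_per_plate Total wells per plate (default 384).
#' @param dmso_wells Vehicle-control wells reserved per plate; at least 4.
#' @param n_replicates Number of replicate plate sets (default 3, i.e. the
#'   library screened in triplicate).
#' @param baseline Expected DMSO-well luminescence (arbitrary units, > 0).
#' @param plate_effect_cv CV of a per-plate lognormal multiplier applied to
#'   every well on the plate (models plate-to-plate intensity drift; the
#'   per-plate DMSO normalisation downstream removes it).
#' @return A `plate_layout` list.
#' @export
plate_layout <- function(wells_per_plate = 384L, dmso_wells = 16L,
                         n_replicates = 3L, baseline = 1e6,
                         plate_effect_cv = 0.05) {
  if (dmso_wells == 0) {
    abort("Layout reserves zero DMSO wells per plate; normalisation is impossible.")
  }
  if (dmso_wells < 4) {
    warn("Fewer than 4 DMSO wells per plate gives a noisy plate baseline.")
  }
  if (baseline <= 0) abort("`baseline` luminescence must be positive.")
  stopifnot(wells_per_plate > dmso_wells, n_replicates >= 1)
  structure(
    list(
      wells_per_plate = as.integer(wells_per_plate),
      dmso_wells = as.integer(dmso_wells),
      n_replicates = as.integer(n_replicates),
      baseline = baseline,
      plate_effect_cv = plate_effect_cv
    ),
    class = "plate_layout"
  )
}

well_names <- function(n) {
  ncol <- 24L
  idx <- seq_len(n) - 1L
  paste0(LETTERS[idx %/% ncol + 1L], sprintf("%02d", idx %% ncol + 1L))
}

#' Simulate raw plate luminescence for an annotated compound screen
#'
#' Compounds are stamped across plates in catalog order; each plate reserves
#' `layout$dmso_wells` vehicle wells. Compound-well luminescence is drawn as
#' `plate_baseline * (1 - true_killing) * lognormal(noise_cv)`; DMSO wells as
#' `plate_baseline * lognormal(noise_cv)`. Each replicate is an independent
#' plate set. The truth is returned alongside the data.
#'
#' @param truth A [screen_truth()].
#' @param layout A [plate_layout()].
#' @return List with `plates` (tibble: plate, well, compound_id, role,
#'   replicate, luminescence), `annotations`, and `truth`.
#' @export
simulate_screen <- function(truth, layout = plate_layout()) {
  stopifnot(inherits(truth, "screen_truth"), inherits(layout, "plate_layout"))
  compounds <- names(truth$true_killing)
  per_plate <- layout$wells_per_plate - layout$dmso_wells
  n_plates <- ceiling(length(compounds) / per_plate)
  with_seed(truth$seed, {
    plates <- map(seq_len(layout$n_replicates), function(rep_i) {
      map(seq_len(n_plates), function(p) {
        cpds <- compounds[seq((p - 1L) * per_plate + 1L,
                              min(p * per_plate, length(compounds)))]
        n_wells <- layout$dmso_wells + length(cpds)
        plate_base <- layout$baseline *
          rlnorm_cv(1L, layout$plate_effect_cv)
        role <- c(rep("DMSO", layout$dmso_wells), rep("compound", length(cpds)))
        cpd <- c(rep(NA_character_, layout$dmso_wells), cpds)
        expected <- ifelse(role == "DMSO", plate_base,
                           plate_base * (1 - truth$true_killing[cpd]))
        tibble(
          plate = sprintf("R%dP%03d", rep_i, p),
          well = well_names(n_wells),
          compound_id = cpd,
          role = role,
          replicate = rep_i,
          luminescence = unname(expected) * rlnorm_cv(n_wells, truth$noise_cv)
        )
      }) |> list_rbind()
    }) |> list_rbind()
    list(plates = plates, annotations = truth$annotations, truth = truth)
  })
}
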