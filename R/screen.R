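#' Percent-killing profiles from raw plate luminescence
#'
#' Per replicate plate, killing for a compound is
#' `100 * (1 - mean(compound luminescence) / mean(DMSO luminescence of that
#' plate))`; the per-plate DMSO mean removes plate-to-plate intensity drift.
#' Replicate killings are then averaged per compound with the arithmetic
#' mean. Negative killing (growth stimulation) is retained, never clipped.
#'
#' @param plates Tibble of raw wells: `plate`, `well`, `compound_id`,
#'   `role` (`"compound"` or `"DMSO"`), `replicate`, `luminescence`.
#' @param annotations Optional tibble `compound_id`, `target`, `pathway`.
#'   Compounds missing from it keep `NA` group fields (with a warning).
#' @return A `killing_profile` tibble: `compound_id`, `target`, `pathway`,
#'   `killing` (list column of per-replicate values), `mean_killing`.
#' @export
percent_killing <- function(plates, annotations = NULL) {
  plates <- as_tibble(plates)
  stopifnot(all(c("plate", "compound_id", "role", "replicate", "luminescence")
                %in% names(plates)))
  dmso <- plates |>
    filter(.data$role == "DMSO") |>
    group_by(.data$plate) |>
    summarise(dmso_mean = mean(.data$luminescence), .groups = "drop")
  no_ctrl <- setdiff(unique(plates$plate), dmso$plate)
  if (length(no_ctrl) > 0) {
    abort(sprintf("Plate(s) without DMSO wells: %s",
                  paste(no_ctrl, collapse = ", ")))
  }
  bad <- dmso$plate[dmso$dmso_mean <= 0]
  if (length(bad) > 0) {
    abort(sprintf("Non-positive DMSO mean on plate(s): %s",
                  paste(bad, collapse = ", ")))
  }
  per_rep <- plates |>
    filter(.data$role == "compound") |>
    group_by(.data$plate, .data$replicate, .data$compound_id) |>
    summarise(lum = mean(.data$luminescence), .groups = "drop") |>
    left_join(dmso, by = "plate") |>
    mutate(killing = 100 * (1 - .data$lum / .data$dmso_mean))
  prof <- per_rep |>
    arrange(.data$compound_id, .data$replicate) |>
    group_by(.data$compound_id) |>
    summarise(mean_killing = mean(.data$killing),
              killing = list(.data$killing),
              .groups = "drop") |>
    relocate("killing", .before = "mean_killing")
  if (!is.null(annotations)) {
    annotations <- as_tibble(annotations)
    missing <- setdiff(prof$compound_id, annotations$compound_id)
    if (length(missing) > 0) {
      warn(sprintf("%d compound(s) absent from the annotation table; group fields left NA.",
                   length(missing)))
    }
    prof <- left_join(prof,
                      select(annotations, "compound_id", "target", "pathway"),
                      by = "compound_id")
  } else {
    prof$target <- NA_character_
    prof$pathway <- NA_character_
  }
  prof <- relocate(prof, "compound_id", "target", "pathway")
  class(prof) <- c("killing_profile", class(prof))
  prof
}

#' Call screen hits at one or more killing thresholds
#'
#' A compound is a hit at threshold `t` iff its mean percent killing is
#' strictly greater than `t`.
#'
#' @param profile A [percent_killing()] profile.
#' @param thresholds Percent thresholds, each in (0, 100].
#' @return List of class `hit_calls`: `hits` (threshold, compound_id,
#'   mean_killing, target, pathway) and `summary` (threshold, n_hits,
#'   n_compounds, pct_library).
#' @export
call_hits <- function(profile, thresholds = c(50, 75, 90)) {
  if (nrow(profile) == 0) abort("Empty killing profile.")
  if (length(thresholds) == 0 || any(thresholds <= 0 | thresholds > 100)) {
    abort("`thresholds` must be non-empty, each in (0, 100].")
  }
  hits <- map(sort(thresholds), function(t) {
    profile |>
      filter(.data$mean_killing > t) |>
      mutate(threshold = t) |>
      select("threshold", "compound_id", "mean_killing", "target", "pathway") |>
      arrange(desc(.data$mean_killing))
  }) |> list_rbind()
  summary <- tibble(threshold = sort(thresholds)) |>
    mutate(
      n_hits = map_int(.data$threshold,
                       \(t) sum(profile$mean_killing > t)),
      n_compounds = nrow(profile),
      pct_library = 100 * .data$n_hits / .data$n_compounds
    )
  structure(list(hits = hits, summary = summary), class = "hit_calls")
}

#' Rank targets or pathways by screen vulnerability
#'
#' For each annotation group, counts how many of its compounds exceed the
#' killing threshold (strictly) and reports the fraction and the group mean
#' killing. Groups are ordered by fraction, then mean killing, then name, so
#' the ranking is deterministic and invariant to input compound order.
#'
#' @param profile A [percent_killing()] profile.
#' @param group_by `"pathway"` or `"target"`.
#' @param threshold Percent-killing threshold (strict `>`).
#' @return A `vulnerability_ranking` tibble: group, n_drugs, k_above,
#'   fraction, mean_killing. Compounds without the grouping annotation are
#'   excluded (their count is reported via a message).
#' @export
rank_vulnerability <- function(profile, group_by = c("pathway", "target"),
                               threshold = 50) {
  group_by <- match.arg(group_by)
  check_scalar_number(threshold, "threshold", 0, 100)
  n_na <- sum(is.na(profile[[group_by]]))
  if (n_na > 0) {
    inform(sprintf("Excluding %d compound(s) without a %s annotation.",
                   n_na, group_by))
  }
  rk <- profile |>
    filter(!is.na(.data[[group_by]])) |>
    group_by(group = .data[[group_by]]) |>
    summarise(
      n_drugs = n(),
      k_above = sum(.data$mean_killing > threshold),
      mean_killing = mean(.data$mean_killing),
      .groups = "drop"
    ) |>
    mutate(fraction = .data$k_above / .data$n_drugs) |>
    select("group", "n_drugs", "k_above", "fraction", "mean_killing") |>
    arrange(desc(.data$fraction), desc(.data$mean_killing), .data$group)
  attr(rk, "threshold") <- threshold
  attr(rk, "group_by") <- group_by
  class(rk) <- c("vulnerability_ranking", class(rk))
  rk
}

#' Hierarchically cluster compounds on their replicate killing vectors
#'
#' Agglomerative clustering (Euclidean distance, average linkage by
#' default) on the per-replicate percent-killing vectors. Compounds are
#' sorted by id before clustering so tie-breaking is deterministic;
#' compounds with missing replicate values are excluded with a warning.
#'
#' @param profile A [percent_killing()] profile.
#' @param method Linkage passed to [stats::hclust()].
#' @param metric Distance passed to [stats::dist()].
#' @return An [stats::hclust] object (labels are compound ids).
#' @export
cluster_compounds <- function(profile, method = "average",
                              metric = "euclidean") {
  lens <- map_int(profile$killing, length)
  ok <- lens == max(lens) & !map_lgl(profile$killing, anyNA)
  if (any(!ok)) {
    warn(sprintf("Excluding %d compound(s) with missing replicate values.",
                 sum(!ok)))
  }
  prof <- profile[ok, ] |> arrange(.data$compound_id)
  if (nrow(prof) < 2) abort("Need >= 2 compounds with complete replicates.")
  m <- do.call(rbind, prof$killing)
  rownames(m) <- prof$compound_id
  hclust(dist(m, method = metric), method = method)
}

map_lgl <- function(x, f) vapply(x, f, logical(1))
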