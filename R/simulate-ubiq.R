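#' Ground truth for a simulated ubiquitin-remnant proteomics experiment
#'
#' @param n_proteins Total proteins quantified.
#' @param up_set,down_set Disjoint protein-name sets planted with increased /
#'   decreased ubiquitination in the treated arm. Names outside the default
#'   `PROTnnnn` labels are allowed (e.g. gene symbols shared with the
#'   variant simulator); they replace the first labels of the catalog.
#' @param log2_effect Planted shift magnitude on the log2 scale (> 0).
#' @param group_size Samples per arm (>= 2).
#' @param sigma Log2-scale measurement SD (>= 0; 0 gives the noise-free
#'   limit used for exact-recovery checks).
#' @param seed Integer seed.
#' @return Object of class `ubiq_truth`.
#' @export
ubiq_truth <- function(n_proteins = 2000L, up_set = character(),
                       down_set = character(), log2_effect = 2,
                       group_size = 3L, sigma = 0.5, seed = 1L) {
  if (length(intersect(up_set, down_set)) > 0) {
    abort("`up_set` and `down_set` must be disjoint.")
  }
  if (length(up_set) + length(down_set) > n_proteins) {
    abort("Planted sets larger than `n_proteins`.")
  }
  if (group_size < 2) abort("`group_size` must be >= 2.")
  if (sigma < 0) abort("`sigma` must be >= 0.")
  check_scalar_number(log2_effect, "log2_effect", lower = 0)
  planted <- c(up_set, down_set)
  extra <- setdiff(planted, sprintf("PROT%04d", seq_len(n_proteins)))
  proteins <- c(extra, sprintf("PROT%04d", seq_len(n_proteins - length(extra))))
  structure(
    list(
      proteins = proteins,
      up_set = up_set, down_set = down_set,
      log2_effect = log2_effect,
      group_size = as.integer(group_size),
      sigma = sigma, seed = as.integer(seed)
    ),
    class = "ubiq_truth"
  )
}

#' Simulate a site-level ubiquitin-remnant abundance table
#'
#' Each protein gets 1-3 K-GG sites; each site's log2 abundance is drawn
#' Normal(mu_site, sigma) per sample, where mu_site combines a protein
#' baseline and a site offset. Treated-arm samples are shifted by
#' `+log2_effect` for `up_set` proteins and `-log2_effect` for `down_set`.
#' Abundances are emitted on the linear (area-under-curve-like) scale.
#'
#' @param truth A [ubiq_truth()].
#' @return List with `table` (tibble: protein, site, sample, group,
#'   abundance) and `truth`.
#' @export
simulate_ubiquitinome <- function(truth) {
  stopifnot(inherits(truth, "ubiq_truth"))
  with_seed(truth$seed, {
    proteins <- truth$proteins
    n_sites <- sample(1:3, length(proteins), replace = TRUE)
    site_tbl <- tibble(
      protein = rep(proteins, n_sites),
      site = unlist(lapply(n_sites, function(k) paste0("K", sample(30:900, k))))
    ) |>
      mutate(mu = rep(rnorm(length(proteins), 20, 1.5), n_sites) +
               rnorm(sum(n_sites), 0, 0.5))
    samples <- c(paste0("vehicle_", seq_len(truth$group_size)),
                 paste0("treated_", seq_len(truth$group_size)))
    group <- rep(c("vehicle", "treated"), each = truth$group_size)
    shift <- setNames(rep(0, length(proteins)), proteins)
    shift[truth$up_set] <- truth$log2_effect
    shift[truth$down_set] <- -truth$log2_effect
    tab <- tidyr::expand_grid(site_tbl, tibble(sample = samples, group = group)) |>
      mutate(
        log2_ab = .data$mu +
          ifelse(.data$group == "treated", shift[.data$protein], 0) +
          rnorm(n(), 0, truth$sigma),
        abundance = 2^.data$log2_ab
      ) |>
      select("protein", "site", "sample", "group", "abundance")
    list(table = tab, truth = truth)
  })
}
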