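#' Roll site-level abundances up to proteins and normalize
#'
#' Site abundances are combined per (protein, sample) — summed by default,
#' matching the area-under-curve additivity of site chromatograms — then
#' log2-transformed with a pseudocount and median-centred per sample.
#'
#' @param table Site-level tibble: `protein`, `site`, `sample`, `group`
#'   (vehicle/treated), `abundance` (>= 0); (protein, site, sample) unique.
#' @param pseudocount Added before log2 (> 0); small relative to typical
#'   abundances so planted effects survive unchanged.
#' @param site_summary `"sum"` (default) or `"median"` across sites.
#' @param center `"median"` (default) subtracts each sample's median log2
#'   abundance, removing loading differences; `"none"` skips centring.
#'   Median centring is neutral only up to the spacing of the order
#'   statistics around the median, so exact-recovery checks in the
#'   noise-free limit use `"none"`.
#' @return Numeric matrix (protein x sample) of centred log2 abundances,
#'   with attributes `groups` (named sample -> group vector) and `n_sites`
#'   (named per-protein site count).
#' @export
rollup_and_normalize <- function(table, pseudocount = 0.5,
                                 site_summary = c("sum", "median"),
                                 center = c("median", "none")) {
  site_summary <- match.arg(site_summary)
  center <- match.arg(center)
  if (pseudocount <= 0) abort("`pseudocount` must be > 0.")
  table <- as_tibble(table)
  stopifnot(all(c("protein", "site", "sample", "group", "abundance")
                %in% names(table)))
  if (anyDuplicated(table[c("protein", "site", "sample")])) {
    abort("(protein, site, sample) rows must be unique.")
  }
  if (length(unique(table$group)) < 2) {
    abort("Both groups (vehicle, treated) must be present.")
  }
  agg <- table |>
    group_by(.data$protein, .data$sample) |>
    summarise(
      value = if (site_summary == "sum") sum(.data$abundance)
              else median(.data$abundance),
      .groups = "drop"
    )
  zero <- agg |>
    group_by(.data$sample) |>
    summarise(all_zero = all(.data$value == 0), .groups = "drop") |>
    filter(.data$all_zero)
  if (nrow(zero) > 0) {
    abort(sprintf("Sample(s) with all-zero abundances: %s",
                  paste(zero$sample, collapse = ", ")))
  }
  wide <- agg |>
    mutate(log2_ab = log2(.data$value + pseudocount)) |>
    select(-"value") |>
    pivot_wider(names_from = "sample", values_from = "log2_ab")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$protein
  if (center == "median") {
    m <- sweep(m, 2, apply(m, 2, median, na.rm = TRUE))
  }
  groups <- table |> distinct(.data$sample, .data$group)
  attr(m, "groups") <- setNames(groups$group, groups$sample)[colnames(m)]
  n_sites <- table |>
    distinct(.data$protein, .data$site) |>
    dplyr::count(.data$protein)
  attr(m, "n_sites") <- setNames(n_sites$n, n_sites$protein)[rownames(m)]
  m
}

#' Per-protein differential ubiquitination test
#'
#' Welch two-sample t-test on centred log2 abundances, treated minus
#' vehicle, with Benjamini-Hochberg adjustment across all tested proteins.
#' Direction is called from the fold-change sign at adjusted p < alpha.
#' Proteins with fewer than 2 finite values in either group are excluded
#' from testing (their count is kept as an attribute).
#'
#' @param mat Protein x sample log2 matrix from [rollup_and_normalize()]
#'   (or any matrix with a `groups` attribute / `groups` argument).
#' @param groups Optional named sample -> group vector overriding the
#'   attribute; must contain "vehicle" and "treated".
#' @param alpha FDR level in (0, 1).
#' @return A `differential_result` tibble: protein, log2fc, p, padj,
#'   direction, n_sites; attributes `alpha`, `n_excluded`.
#' @export
differential_test <- function(mat, groups = NULL, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  groups <- groups %||% attr(mat, "groups")
  if (is.null(groups)) abort("Supply `groups` (sample -> vehicle/treated).")
  groups <- groups[colnames(mat)]
  if (!all(c("vehicle", "treated") %in% groups)) {
    abort("`groups` must contain both 'vehicle' and 'treated'.")
  }
  veh <- mat[, groups == "vehicle", drop = FALSE]
  trt <- mat[, groups == "treated", drop = FALSE]
  ok <- rowSums(is.finite(veh)) >= 2 & rowSums(is.finite(trt)) >= 2
  n_excluded <- sum(!ok)
  res <- tibble(
    protein = rownames(mat)[ok],
    log2fc = rowMeans(trt[ok, , drop = FALSE], na.rm = TRUE) -
      rowMeans(veh[ok, , drop = FALSE], na.rm = TRUE),
    p = vapply(which(ok), function(i) {
      vi <- veh[i, ][is.finite(veh[i, ])]
      ti <- trt[i, ][is.finite(trt[i, ])]
      if (var(vi) == 0 && var(ti) == 0) {
        if (isTRUE(all.equal(mean(vi), mean(ti)))) 1 else 0
      } else {
        t.test(ti, vi)$p.value
      }
    }, numeric(1))
  ) |>
    mutate(
      padj = p.adjust(.data$p, method = "BH"),
      direction = dplyr::case_when(
        .data$padj < alpha & .data$log2fc > 0 ~ "increased",
        .data$padj < alpha & .data$log2fc < 0 ~ "decreased",
        .default = "unchanged"
      )
    )
  ns <- attr(mat, "n_sites")
  res$n_sites <- if (is.null(ns)) NA_integer_ else unname(ns[res$protein])
  attr(res, "alpha") <- alpha
  attr(res, "n_excluded") <- n_excluded
  class(res) <- c("differential_result", class(res))
  res
}

#' @method glance differential_result
#' @export
glance.differential_result <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_excluded = attr(x, "n_excluded") %||% NA_integer_,
    n_differential = sum(x$direction != "unchanged"),
    n_increased = sum(x$direction == "increased"),
    n_decreased = sum(x$direction == "decreased"),
    alpha = attr(x, "alpha")
  )
}

#' Hypergeometric pathway over-representation test
#'
#' Upper-tail hypergeometric p for observing at least the actual overlap
#' between the flagged set and each pathway, testing within the quantified
#' background; BH adjustment across pathways.
#'
#' @param flagged Protein set of interest (must be a subset of
#'   `background`).
#' @param background All quantified proteins.
#' @param pathways Named list of pathway member vectors (see [read_gmt()]).
#' @return Tibble: pathway, k (overlap), K (pathway size in background),
#'   p, padj; sorted by padj then name.
#' @export
enrich_pathways <- function(flagged, background, pathways) {
  if (length(background) == 0) abort("Empty background set.")
  if (!all(flagged %in% background)) {
    abort("`flagged` must be a subset of `background`.")
  }
  flagged <- unique(flagged)
  background <- unique(background)
  res <- imap(pathways, function(members, name) {
    members <- intersect(members, background)
    k <- length(intersect(members, flagged))
    K <- length(members)
    tibble(
      pathway = name, k = k, K = K,
      p = if (K == 0) 1 else
        phyper(k - 1, K, length(background) - K, length(flagged),
               lower.tail = FALSE)
    )
  }) |> list_rbind()
  res |>
    mutate(padj = p.adjust(.data$p, method = "BH")) |>
    arrange(.data$padj, .data$p, .data$pathway)
}

#' Read / write GMT pathway files
#'
#' @param path GMT file path (tab-separated: name, description, members).
#' @return `read_gmt`: named list of member vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param pathways Named list of member vectors.
#' @export
write_gmt <- function(pathways, path) {
  writeLines(
    map_chr(names(pathways), function(nm) {
      paste(c(nm, "na", pathways[[nm]]), collapse = "\t")
    }),
    path
  )
  invisible(path)
}
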