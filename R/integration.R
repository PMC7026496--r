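#' Integrate mutated-gene sets with differential ubiquitination
#'
#' Candidates are genes that (a) carry a deleterious mutation in at least
#' one sample — with the PDX gene set pre-filtered by the cell line to
#' remove host-tissue contamination — and (b) are differentially
#' ubiquitinated (increased or decreased). Optionally, candidates must also
#' carry an identical variant key (chrom, pos, ref, alt) in >= 2 samples
#' ("identical somatic mutations across multiple samples").
#'
#' @param mutated_gene_sets Named list: per sample, genes with deleterious
#'   mutations (see [deleterious_gene_sets()]).
#' @param diff A [differential_test()] result (or any tibble with
#'   `protein` and `direction` columns).
#' @param pdx_filtered Optional pre-filtered PDX gene set (from
#'   [pdx_contamination_filter()]); replaces the entry named `pdx_sample`.
#' @param pdx_sample Name of the PDX entry in `mutated_gene_sets`.
#' @param require_shared_identical Demand one identical variant key in
#'   >= 2 samples for the candidate gene.
#' @param variants Long variant tibble (needed for the shared-identical
#'   flag; columns sample, chrom, pos, ref, alt, gene).
#' @return A `candidate_table` tibble: gene, direction, one 0/1 presence
#'   column per sample, shared_identical; ordered by (direction, gene).
#' @export
integrate_candidates <- function(mutated_gene_sets, diff,
                                 pdx_filtered = NULL, pdx_sample = NULL,
                                 require_shared_identical = FALSE,
                                 variants = NULL) {
  stopifnot(is.list(mutated_gene_sets), !is.null(names(mutated_gene_sets)))
  if (!is.null(pdx_filtered)) {
    if (is.null(pdx_sample) || !pdx_sample %in% names(mutated_gene_sets)) {
      abort("`pdx_sample` must name an entry of `mutated_gene_sets`.")
    }
    mutated_gene_sets[[pdx_sample]] <- pdx_filtered
  }
  flagged <- unique(diff$protein[diff$direction %in% c("increased", "decreased")])
  if (length(flagged) == 0) {
    warn("No differentially ubiquitinated proteins; empty candidate table.")
  }
  mutated <- sort(unique(unlist(mutated_gene_sets)))
  candidates <- intersect(mutated, flagged)
  if (require_shared_identical) {
    if (is.null(variants)) {
      abort("`variants` is required when `require_shared_identical = TRUE`.")
    }
    shared_genes <- as_tibble(variants) |>
      filter(.data$gene %in% candidates) |>
      distinct(.data$sample, .data$chrom, .data$pos, .data$ref, .data$alt,
               .data$gene) |>
      group_by(.data$gene, .data$chrom, .data$pos, .data$ref, .data$alt) |>
      summarise(n_samples = n(), .groups = "drop") |>
      filter(.data$n_samples >= 2) |>
      pull("gene") |>
      unique()
    candidates <- intersect(candidates, shared_genes)
  }
  dirs <- diff |>
    filter(.data$protein %in% candidates) |>
    distinct(.data$protein, .data$direction)
  out <- tibble(gene = candidates) |>
    left_join(dirs, by = c(gene = "protein"))
  for (s in names(mutated_gene_sets)) {
    out[[s]] <- as.integer(out$gene %in% mutated_gene_sets[[s]])
  }
  out$shared_identical <- if (require_shared_identical) {
    TRUE
  } else if (!is.null(variants)) {
    shared <- as_tibble(variants) |>
      distinct(.data$sample, .data$chrom, .data$pos, .data$ref, .data$alt,
               .data$gene) |>
      group_by(.data$gene, .data$chrom, .data$pos, .data$ref, .data$alt) |>
      summarise(n_samples = n(), .groups = "drop") |>
      filter(.data$n_samples >= 2) |>
      pull("gene")
    out$gene %in% shared
  } else {
    NA
  }
  out <- arrange(out, .data$direction, .data$gene)
  class(out) <- c("candidate_table", class(out))
  out
}
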