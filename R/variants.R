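CANINE_CHROMS <- c(paste0("chr", 1:38), "chrX")

chrom_rank <- function(chrom) {
  r <- match(chrom, CANINE_CHROMS)
  ifelse(is.na(r), length(CANINE_CHROMS) + as.integer(factor(chrom)), r)
}

#' Read per-sample somatic variant sets from VCF files
#'
#' Parses a VCF v4.2 subset (one sample's calls per file) into one long
#' tibble of variant keys. Multiallelic records are split into one key per
#' ALT allele, keys are de-duplicated, and rows with FILTER other than
#' PASS or "." are dropped when `pass_only = TRUE`. INFO keys `GENE` and
#' `EFF` are honoured when present.
#'
#' @param paths Character vector of VCF paths. Names give the sample names;
#'   unnamed paths use the file basename without extension.
#' @param pass_only Drop records whose FILTER is neither PASS nor ".".
#' @return Tibble: `sample`, `chrom`, `pos`, `ref`, `alt`, `gene`, `effect`.
#' @export
read_variant_sets <- function(paths, pass_only = TRUE) {
  nm <- names(paths) %||% rep(NA_character_, length(paths))
  nm[is.na(nm) | nm == ""] <-
    sub("\\.vcf(\\.gz)?$", "", basename(paths[is.na(nm) | nm == ""]))
  if (anyDuplicated(nm)) abort("Duplicate sample names across VCF paths.")
  map2(paths, nm, function(path, s) {
    v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) {
                    abort(sprintf("Failed to parse VCF '%s': %s",
                                  path, conditionMessage(e)))
                  })
    fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                         stringsAsFactors = FALSE)
    pos <- suppressWarnings(as.integer(fix$POS))
    if (anyNA(pos)) {
      abort(sprintf("Malformed POS in '%s' at data row(s): %s", path,
                    paste(which(is.na(pos)), collapse = ", ")))
    }
    out <- tibble(
      sample = s, chrom = fix$CHROM, pos = pos, ref = fix$REF,
      alt = fix$ALT, filter = fix$FILTER %||% NA_character_,
      gene = vcfR::extract.info(v, "GENE"),
      effect = vcfR::extract.info(v, "EFF")
    )
    if (pass_only) {
      out <- filter(out, is.na(.data$filter) | .data$filter %in% c("PASS", "."))
    }
    out |>
      tidyr::separate_rows("alt", sep = ",") |>
      distinct(.data$sample, .data$chrom, .data$pos, .data$ref, .data$alt,
               .keep_all = TRUE) |>
      select(-"filter")
  }) |> list_rbind()
}

#' Keep single-nucleotide variants only
#'
#' Retains keys whose REF and ALT are both single bases in \{A,C,G,T\}
#' with REF != ALT.
#'
#' @param variants Long variant tibble (`sample`, `chrom`, `pos`, `ref`,
#'   `alt`, ...).
#' @return The filtered tibble.
#' @export
filter_snvs <- function(variants) {
  bases <- c("A", "C", "G", "T")
  filter(as_tibble(variants),
         .data$ref %in% bases, .data$alt %in% bases, .data$ref != .data$alt)
}

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

split_keys <- function(variants) {
  variants <- as_tibble(variants)
  lapply(split(variant_key(variants), variants$sample), unique)
}

#' Pairwise shared-mutation similarity between samples
#'
#' For every sample pair, reports the shared variant count
#' `|A intersect B|`, the Jaccard percentage
#' `100 |A intersect B| / |A union B|` (the primary statistic), and the
#' asymmetric containment percentage `100 |A intersect B| / |A|` (row
#' sample as denominator), since "percent shared" is denominator-dependent.
#' Two empty sets are defined as 100% similar (with a note).
#'
#' @param variants Long variant tibble covering >= 2 samples.
#' @param samples Optional sample ordering for the matrices.
#' @return Object of class `similarity_matrix`: `samples`, `shared`,
#'   `jaccard_pct`, `containment_pct` matrices.
#' @export
pairwise_similarity <- function(variants, samples = NULL) {
  keys <- split_keys(variants)
  samples <- samples %||% sort(names(keys))
  stopifnot(all(samples %in% names(keys)))
  n <- length(samples)
  if (n < 2) abort("Need >= 2 samples for pairwise similarity.")
  keys <- keys[samples]
  shared <- jac <- cont <- matrix(0, n, n, dimnames = list(samples, samples))
  noted_empty <- FALSE
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- keys[[i]]; b <- keys[[j]]
      inter <- length(intersect(a, b))
      uni <- length(union(a, b))
      shared[i, j] <- inter
      jac[i, j] <- if (uni == 0) {
        noted_empty <- TRUE
        100
      } else {
        100 * inter / uni
      }
      cont[i, j] <- if (length(a) == 0) NA_real_ else 100 * inter / length(a)
    }
  }
  if (noted_empty) inform("Both-empty sample pair(s): Jaccard defined as 100%.")
  structure(
    list(samples = samples, shared = shared, jaccard_pct = jac,
         containment_pct = cont),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("Pairwise similarity over %d samples (Jaccard %%):\n",
              length(x$samples)))
  print(round(x$jaccard_pct, 1))
  invisible(x)
}

#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$jaccard_pct, responseName = "jaccard_pct",
                                stringsAsFactors = FALSE)) |>
    rename(sample_a = "Var1", sample_b = "Var2") |>
    mutate(shared = as.vector(x$shared),
           containment_pct = as.vector(x$containment_pct))
}

#' UpSet-style intersection pattern counts
#'
#' Assigns every variant in the union to exactly one membership pattern
#' (the sorted set of samples carrying it) and counts variants per pattern;
#' pattern counts always sum to the union size.
#'
#' @param variants Long variant tibble covering >= 1 sample.
#' @return List: `patterns` (tibble pattern, degree, n, sorted by n
#'   descending), `unique_counts` (per-sample count of private variants),
#'   `union_size`.
#' @export
intersection_pattern_counts <- function(variants) {
  keys <- split_keys(variants)
  if (length(keys) < 1) abort("Need >= 1 sample.")
  membership <- tibble(
    sample = rep(names(keys), lengths(keys)),
    key = unlist(keys, use.names = FALSE)
  ) |>
    group_by(.data$key) |>
    summarise(pattern = paste(sort(unique(.data$sample)), collapse = "&"),
              degree = dplyr::n_distinct(.data$sample), .groups = "drop")
  patterns <- membership |>
    group_by(.data$pattern, .data$degree) |>
    summarise(n = n(), .groups = "drop") |>
    arrange(desc(.data$n), .data$pattern)
  uniq <- patterns |>
    filter(.data$degree == 1) |>
    select(sample = "pattern", n_unique = "n")
  uniq <- tibble(sample = names(keys)) |>
    left_join(uniq, by = "sample") |>
    mutate(n_unique = dplyr::coalesce(.data$n_unique, 0L))
  list(patterns = patterns, unique_counts = uniq,
       union_size = nrow(membership))
}

#' Per-sample sets of genes carrying deleterious mutations
#'
#' @param variants Long variant tibble with `gene` and `effect` columns
#'   populated (from VCF INFO or simulator truth). Effect prediction is an
#'   input to this pipeline, not computed here.
#' @param deleterious_effects Effect labels counted as deleterious.
#' @return Named list: per sample, the sorted set of genes with >= 1
#'   deleterious variant.
#' @export
deleterious_gene_sets <- function(variants,
                                  deleterious_effects = DELETERIOUS_EFFECTS) {
  variants <- as_tibble(variants)
  if (!all(c("gene", "effect") %in% names(variants)) ||
      all(is.na(variants$effect))) {
    abort(paste("Variant effect annotations are missing. Effect prediction",
                "(e.g. VEP) is an upstream input: supply `gene`/`effect`",
                "columns or VCF INFO keys GENE/EFF."))
  }
  del <- filter(variants, .data$effect %in% deleterious_effects)
  sets <- lapply(split(del$gene, del$sample), function(g) sort(unique(g)))
  # samples with no deleterious variant still get an (empty) entry
  all_samples <- unique(variants$sample)
  out <- setNames(vector("list", length(all_samples)), all_samples)
  for (s in all_samples) out[[s]] <- sets[[s]] %||% character()
  out
}

#' Filter PDX mutated genes by the cell line to remove host contamination
#'
#' Genes mutated only in the PDX but absent from the matched cell line are
#' likely called from residual mouse tissue; keeping the intersection with
#' the cell line removes them.
#'
#' @param pdx_genes,cellline_genes Character vectors of gene names.
#' @return Sorted intersection.
#' @export
pdx_contamination_filter <- function(pdx_genes, cellline_genes) {
  sort(intersect(pdx_genes, cellline_genes))
}
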