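DELETERIOUS_EFFECTS <- c("stop_gained", "frameshift", "splice_disrupting",
                         "missense_deleterious")
BENIGN_EFFECTS <- c("synonymous", "missense_tolerated", "intron_variant")

#' Ground truth for clonally structured somatic variants
#'
#' Describes a rooted sample tree and how many variants to plant on it:
#' trunk variants shared by every sample, branch variants on each internal
#' edge (inherited by all descendant leaves), and private variants on each
#' terminal edge. An optional set of contaminant variants is given only to
#' the PDX sample (and never to the cell line), mimicking mouse-tissue reads
#' that survive variant calling.
#'
#' @param tree A rooted tree over the sample names: an `ape::phylo` object
#'   or a newick string.
#' @param n_trunk Variants shared by all samples.
#' @param n_branch_per_edge Variants planted on each internal edge.
#' @param n_private_per_leaf Variants private to each sample.
#' @param deleterious_fraction Probability a planted variant gets a
#'   deleterious effect label (the rest get benign labels).
#' @param contaminant_count_pdx Variants present only in `pdx_sample`.
#' @param pdx_sample Leaf name receiving the contaminants (ignored when
#'   `contaminant_count_pdx` is 0).
#' @param gene_pool Candidate gene labels for somatic variants.
#' @param seed Integer seed.
#' @return An object of class `clonal_truth`.
#' @export
clonal_truth <- function(tree, n_trunk = 50L, n_branch_per_edge = 25L,
                         n_private_per_leaf = 40L,
                         deleterious_fraction = 0.3,
                         contaminant_count_pdx = 0L, pdx_sample = NULL,
                         gene_pool = sprintf("GENE%04d", 1:2000),
                         seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    abort("Duplicate sample names in the tree.")
  }
  for (x in c(n_trunk, n_branch_per_edge, n_private_per_leaf,
              contaminant_count_pdx)) {
    check_scalar_number(x, "variant count", lower = 0)
  }
  check_scalar_number(deleterious_fraction, "deleterious_fraction", 0, 1)
  if (contaminant_count_pdx > 0) {
    if (is.null(pdx_sample) || !pdx_sample %in% tree$tip.label) {
      abort("`pdx_sample` must name a leaf when contaminants are requested.")
    }
  }
  structure(
    list(
      tree = tree,
      n_trunk = as.integer(n_trunk),
      n_branch_per_edge = as.integer(n_branch_per_edge),
      n_private_per_leaf = as.integer(n_private_per_leaf),
      deleterious_fraction = deleterious_fraction,
      contaminant_count_pdx = as.integer(contaminant_count_pdx),
      pdx_sample = pdx_sample,
      gene_pool = gene_pool,
      seed = as.integer(seed)
    ),
    class = "clonal_truth"
  )
}

# leaves descending from each edge's child node
edge_leaf_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  lapply(seq_len(nrow(tree$edge)), function(i) {
    child <- tree$edge[i, 2]
    if (child <= n_tip) {
      tree$tip.label[child]
    } else {
      tree$tip.label[unlist(phangorn::Descendants(tree, child, "tips"))]
    }
  })
}

#' Simulate per-sample somatic variant sets along a known clonal tree
#'
#' Every planted variant is assigned to exactly one tree edge and inherited
#' by all leaves below it, so the generated binary presence/absence
#' characters form a perfect phylogeny (no homoplasy). Variant keys are
#' unique `(chrom, pos, ref, alt)` tuples on a 38-autosome + X canine-style
#' chromosome set; each variant carries a gene label and an effect label.
#' Contaminant variants (PDX only) draw gene labels from a separate
#' mouse-style pool so they never collide with somatic genes.
#'
#' @param truth A [clonal_truth()].
#' @return List with `variants` (long tibble: sample, chrom, pos, ref, alt,
#'   gene, effect), `catalog` (one row per planted variant with its edge
#'   class), `tree` (the true rooted tree), and `deleterious_genes` (named
#'   list: per sample, genes carrying >= 1 deleterious variant).
#' @export
simulate_clonal_variants <- function(truth) {
  stopifnot(inherits(truth, "clonal_truth"))
  tree <- truth$tree
  tips <- tree$tip.label
  n_tip <- length(tips)
  with_seed(truth$seed, {
    leaf_sets <- edge_leaf_sets(tree)
    is_terminal <- tree$edge[, 2] <= n_tip

    # per-edge variant counts: trunk -> all leaves; internal edges ->
    # n_branch_per_edge; terminal edges -> n_private_per_leaf
    carriers <- c(list(tips), leaf_sets)
    counts <- c(truth$n_trunk,
                ifelse(is_terminal, truth$n_private_per_leaf,
                       truth$n_branch_per_edge))
    edge_class <- c("trunk",
                    ifelse(is_terminal, "private", "branch"))
    n_somatic <- sum(counts)
    n_total <- n_somatic + truth$contaminant_count_pdx
    if (n_total == 0) {
      abort("Truth plants zero variants; nothing to simulate.")
    }

    chroms <- c(paste0("chr", 1:38), "chrX")
    pos <- sample.int(5e7, n_total)          # without replacement: unique keys
    ref <- sample(c("A", "C", "G", "T"), n_total, replace = TRUE)
    alt <- map_chr(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L))
    genes <- if (length(truth$gene_pool) >= n_somatic) {
      sample(truth$gene_pool, n_somatic)
    } else {
      sample(truth$gene_pool, n_somatic, replace = TRUE)
    }
    if (truth$contaminant_count_pdx > 0) {
      genes <- c(genes, sprintf("MUSG%04d", seq_len(truth$contaminant_count_pdx)))
    }
    deleterious <- runif(n_total) < truth$deleterious_fraction
    effect <- ifelse(deleterious,
                     sample(DELETERIOUS_EFFECTS, n_total, replace = TRUE),
                     sample(BENIGN_EFFECTS, n_total, replace = TRUE))

    catalog <- tibble(
      chrom = sample(chroms, n_total, replace = TRUE),
      pos = pos, ref = ref, alt = alt, gene = genes, effect = effect,
      edge_class = c(rep(edge_class, times = counts),
                     rep("pdx_contaminant", truth$contaminant_count_pdx)),
      carriers = c(rep(carriers, times = counts),
                   rep(list(truth$pdx_sample), truth$contaminant_count_pdx))
    )

    variants <- catalog |>
      tidyr::unnest_longer(carriers, values_to = "sample") |>
      select("sample", "chrom", "pos", "ref", "alt", "gene", "effect") |>
      arrange(.data$sample, .data$chrom, .data$pos)

    del <- catalog |> filter(.data$effect %in% DELETERIOUS_EFFECTS)
    deleterious_genes <- map(setNames(tips, tips), function(s) {
      sort(unique(del$gene[map_lgl_has(del$carriers, s)]))
    })

    list(
      variants = variants,
      catalog = catalog,
      tree = tree,
      deleterious_genes = deleterious_genes
    )
  })
}

map_lgl_has <- function(list_col, value) {
  vapply(list_col, function(x) value %in% x, logical(1))
}

#' Write one minimal VCF v4.2 per sample
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO rows with `GENE=` and `EFF=`
#' INFO keys, FILTER set to PASS, sorted by chromosome then position.
#'
#' @param variants Long variant tibble (as produced by
#'   [simulate_clonal_variants()]): columns sample, chrom, pos, ref, alt and
#'   optionally gene, effect.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of file paths (one per sample).
#' @export
write_variant_vcfs <- function(variants, dir) {
  variants <- as_tibble(variants)
  stopifnot(all(c("sample", "chrom", "pos", "ref", "alt") %in% names(variants)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  chrom_order <- c(paste0("chr", 1:38), "chrX")
  paths <- map_chr(split(variants, variants$sample), function(vs) {
    s <- vs$sample[1]
    vs <- vs |>
      mutate(.c = match(.data$chrom, chrom_order)) |>
      arrange(.data$.c, .data$pos)
    info <- if (all(c("gene", "effect") %in% names(vs))) {
      sprintf("GENE=%s;EFF=%s", vs$gene, vs$effect)
    } else {
      rep(".", nrow(vs))
    }
    path <- file.path(dir, paste0(s, ".vcf"))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
      "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Predicted effect\">",
      sprintf("##SAMPLE=<ID=%s>", s),
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
              vs$chrom, vs$pos, vs$ref, vs$alt, info)
    ), path)
    path
  })
  invisible(paths)
}
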