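#' Seeded end-to-end case study on synthetic data with planted truth
#'
#' Runs the whole precision-medicine workflow the package implements, on
#' data simulated under the case study's design: a 2,100-compound
#' triplicate viability screen with one planted sensitive pathway;
#' dose-response validation curves for the two top candidates at the
#' sub-micromolar IC50s typical of an HSP90 and a proteasome inhibitor
#' (345 and 6 nM); an 11-sample somatic-variant design (seven primary
#' tumors, a recurrent tumor, a PDX and its derived cell line, plus an
#' all-absent normal outgroup) written to and re-read from per-sample
#' VCFs; NJ phylogenetics with bootstrap support; a 3 vs 3
#' ubiquitin-remnant experiment with 160 increased and 130 decreased
#' proteins planted, ten of which are trunk genes carrying shared
#' deleterious mutations; candidate integration; and a 5 vs 5 PDX
#' efficacy study with two-way ANOVA.
#'
#' @param seed Integer master seed; every stage derives its own seed from
#'   it, so the full run is reproducible.
#' @param n_bootstrap Bootstrap replicates for clade support.
#' @param alpha FDR level for the differential and integration stages.
#' @return A named list with each stage's inputs, truths and results; see
#'   the vignette for a walk-through.
#' @export
run_case_study <- function(seed = 1L, n_bootstrap = 200L, alpha = 0.05) {
  seed <- as.integer(seed)

  ## -- drug screen -------------------------------------------------------
  struth <- example_screen_truth(seed = seed)
  screen <- simulate_screen(struth)
  profile <- percent_killing(screen$plates, screen$annotations)
  hits <- call_hits(profile, c(50, 75, 90))
  ranking <- suppressMessages(rank_vulnerability(profile, "pathway", 50))

  ## -- dose-response validation of the two top candidates ----------------
  doses <- 10^seq(-0.5, 4, length.out = 8)  # 0.32 nM .. 10 uM
  dr <- with_seed(seed + 1L, {
    sim_curve <- function(ic50) {
      y <- 100 / (1 + 10^(log10(ic50) - log10(doses)))
      fit_dose_response(doses, y * rlnorm_cv(length(y), 0.05))
    }
    list(alvespimycin = sim_curve(345), bortezomib = sim_curve(6))
  })

  ## -- somatic variants over the 11-sample design ------------------------
  tree_txt <- "(T7,(T6,(T5,(T4,(T3,(T2,(T1,(REC,(PDX,CL)))))))));"
  ctruth <- clonal_truth(tree_txt,
                         n_trunk = 80L, n_branch_per_edge = 50L,
                         n_private_per_leaf = 40L,
                         deleterious_fraction = 0.3,
                         contaminant_count_pdx = 12L, pdx_sample = "PDX",
                         seed = seed + 2L)
  clonal <- simulate_clonal_variants(ctruth)
  vcf_dir <- file.path(tempdir(), sprintf("crossomics_vcfs_%d", seed))
  paths <- write_variant_vcfs(clonal$variants, vcf_dir)
  variants <- filter_snvs(read_variant_sets(paths))
  similarity <- pairwise_similarity(variants)
  patterns <- intersection_pattern_counts(variants)
  gene_sets <- deleterious_gene_sets(variants)
  pdx_filtered <- pdx_contamination_filter(gene_sets$PDX, gene_sets$CL)

  ## -- phylogenetics ------------------------------------------------------
  # the all-absent normal row is kept for rooting displays only; trees and
  # bootstrap are computed unrooted on the tumor samples (the outgroup is
  # equidistant from everything under Jaccard, so its placement carries no
  # signal)
  cm <- build_character_matrix(variants)
  cm_tumor <- build_character_matrix(variants, include_outgroup = FALSE)
  boot <- bootstrap_support(cm_tumor, n_replicates = n_bootstrap,
                            method = "nj", seed = seed + 3L)
  # bootstrap support of the planted tree's informative bipartitions
  true_tree <- clonal$tree
  true_counts <- ape::prop.clades(true_tree, boot$trees, rooted = FALSE)
  true_counts[is.na(true_counts)] <- 0L
  n_tip <- length(true_tree$tip.label)
  clade_sizes <- integer(true_tree$Nnode)
  true_support <- tibble(
    clade = map_chr(seq_len(true_tree$Nnode), function(i) {
      tips <- true_tree$tip.label[
        unlist(phangorn::Descendants(true_tree, n_tip + i, "tips"))]
      clade_sizes[i] <<- length(tips)
      paste(sort(tips), collapse = ",")
    }),
    size = clade_sizes,
    count = true_counts,
    prop = true_counts / n_bootstrap
  ) |>
    filter(.data$size >= 2, .data$size <= n_tip - 2) |>
    select(-"size")

  ## -- ubiquitinomics with planted candidates -----------------------------
  # candidate genes: trunk genes with deleterious variants (present in every
  # sample, so they survive the PDX/cell-line filter and carry an identical
  # variant key in >= 2 samples); 5 planted up, 5 down
  trunk_del <- clonal$catalog |>
    filter(.data$edge_class == "trunk",
           .data$effect %in% DELETERIOUS_EFFECTS) |>
    pull("gene") |>
    unique() |>
    sort()
  cand_genes <- head(trunk_del, 10L)
  up_genes <- cand_genes[seq_len(min(5L, length(cand_genes)))]
  down_genes <- setdiff(cand_genes, up_genes)
  utruth <- ubiq_truth(
    n_proteins = 2000L,
    up_set = c(up_genes, sprintf("PROT%04d", 101:(100 + 160 - length(up_genes)))),
    down_set = c(down_genes, sprintf("PROT%04d", 401:(400 + 130 - length(down_genes)))),
    log2_effect = 4, group_size = 3L, sigma = 0.25, seed = seed + 4L
  )
  ubiq <- simulate_ubiquitinome(utruth)
  mat <- rollup_and_normalize(ubiq$table)
  diff <- differential_test(mat, alpha = alpha)
  pathways <- with_seed(seed + 5L, {
    pw <- map(setNames(1:20, sprintf("pathway_%02d", 1:20)), function(i) {
      sample(utruth$proteins, 40)
    })
    pw$increased_module <- sample(setdiff(utruth$up_set, cand_genes), 40)
    pw$decreased_module <- sample(setdiff(utruth$down_set, cand_genes), 40)
    pw
  })
  enrichment <- list(
    increased = enrich_pathways(diff$protein[diff$direction == "increased"],
                                diff$protein, pathways),
    decreased = enrich_pathways(diff$protein[diff$direction == "decreased"],
                                diff$protein, pathways)
  )

  ## -- integration --------------------------------------------------------
  candidates <- integrate_candidates(
    gene_sets, diff,
    pdx_filtered = pdx_filtered, pdx_sample = "PDX",
    require_shared_identical = TRUE, variants = variants
  )

  ## -- PDX efficacy -------------------------------------------------------
  gtruth <- growth_truth(seed = seed + 6L)
  growth <- simulate_growth(gtruth)
  censored <- apply_censoring(growth$measurements,
                              max_volume = gtruth$censor_volume, max_day = 18)
  # analyse the common uncensored window so the design stays balanced
  last_day <- censored$records |>
    group_by(.data$animal) |>
    summarise(last = max(.data$day), .groups = "drop") |>
    pull("last") |>
    min()
  anova <- two_way_anova(filter(censored$records, .data$day <= last_day))

  list(
    seed = seed,
    screen = list(truth = struth, profile = profile, hits = hits,
                  ranking = ranking),
    dose_response = dr,
    variants = list(truth = ctruth, clonal = clonal, variants = variants,
                    similarity = similarity, patterns = patterns,
                    gene_sets = gene_sets, pdx_filtered = pdx_filtered),
    phylo = list(cm = cm, bootstrap = boot, true_tree = true_tree,
                 true_support = true_support),
    ubiquitin = list(truth = utruth, diff = diff, enrichment = enrichment),
    integration = list(planted = cand_genes, candidates = candidates),
    growth = list(truth = gtruth, measurements = growth$measurements,
                  censored = censored, anova = anova,
                  analysis_window = last_day)
  )
}
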