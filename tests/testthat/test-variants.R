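write_test_vcf <- function(rows, path = withr::local_tempfile(fileext = ".vcf",
                                                              .local_envir = parent.frame())) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"e\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    rows
  ), path)
  path
}

test_that("VCF parsing splits multiallelics, dedupes and honours FILTER", {
  p <- write_test_vcf(c(
    "chr1\t100\t.\tA\tT\t.\tPASS\tGENE=G1;EFF=stop_gained",
    "chr1\t200\t.\tG\tC\t.\tPASS\tGENE=G2;EFF=synonymous",
    "chr2\t50\t.\tAT\tA\t.\tPASS\tGENE=G3;EFF=frameshift",
    "chr3\t70\t.\tG\tT,C\t.\tPASS\tGENE=G4;EFF=missense_deleterious",
    "chr4\t10\t.\tC\tA\t.\tgermline_risk\tGENE=G5;EFF=stop_gained"
  ))
  vs <- read_variant_sets(c(S1 = p))
  expect_equal(nrow(vs), 5)  # 3 simple + multiallelic split into 2
  expect_equal(sum(vs$chrom == "chr3"), 2)
  expect_equal(sort(vs$alt[vs$chrom == "chr3"]), c("C", "T"))
  all_rows <- read_variant_sets(c(S1 = p), pass_only = FALSE)
  expect_equal(nrow(all_rows), 6)
  # deterministic re-read
  expect_identical(vs, read_variant_sets(c(S1 = p)))
  expect_error(read_variant_sets(c(A = p, A = p)), "Duplicate sample names")
})

test_that("simulated variant sets survive a VCF round-trip", {
  sim <- simulate_clonal_variants(small_clonal_truth(seed = 12))
  dir <- withr::local_tempdir()
  paths <- write_variant_vcfs(sim$variants, dir)
  back <- read_variant_sets(paths)
  orig <- dplyr::arrange(sim$variants, sample, chrom, pos, ref, alt)
  back <- dplyr::arrange(back, sample, chrom, pos, ref, alt)
  expect_equal(back$chrom, orig$chrom)
  expect_equal(back$pos, orig$pos)
  expect_equal(back$gene, orig$gene)
  expect_equal(back$effect, orig$effect)
})

test_that("SNV filtering keeps single-base substitutions only", {
  v <- tibble::tibble(
    sample = "S", chrom = c("chr1", "chr2", "chr3"), pos = c(100, 50, 7),
    ref = c("A", "AT", "G"), alt = c("T", "A", "GA")
  )
  expect_equal(nrow(filter_snvs(v)), 1)
  all_snv <- tibble::tibble(sample = "S", chrom = "chr1", pos = 1:3,
                            ref = c("A", "C", "G"), alt = c("T", "G", "A"))
  expect_equal(filter_snvs(all_snv), all_snv)
  expect_equal(nrow(filter_snvs(all_snv[0, ])), 0)
})

two_sample_variants <- function(a, b) {
  tibble::tibble(
    sample = c(rep("A", length(a)), rep("B", length(b))),
    chrom = "chr1", pos = c(a, b), ref = "A", alt = "T"
  )
}

test_that("pairwise similarity computes shared counts and Jaccard", {
  sm <- pairwise_similarity(two_sample_variants(1:3, 2:4))
  expect_equal(sm$shared["A", "B"], 2)
  expect_equal(sm$jaccard_pct["A", "B"], 50)
  expect_equal(sm$containment_pct["A", "B"], 100 * 2 / 3)
  expect_equal(pairwise_similarity(two_sample_variants(1:3, 1:3))$jaccard_pct["A", "B"], 100)
  expect_equal(pairwise_similarity(two_sample_variants(1:3, 4:6))$jaccard_pct["A", "B"], 0)
  expect_error(pairwise_similarity(two_sample_variants(1:3, integer(0))), ">= 2")
})

test_that("similarity matrices are symmetric with exact diagonals", {
  withr::with_seed(31, {
    for (i in 1:5) {
      sets <- lapply(1:4, function(j) sample(1:40, sample(5:20, 1)))
      v <- tibble::tibble(
        sample = rep(paste0("S", 1:4), lengths(sets)),
        chrom = "chr1", pos = unlist(sets), ref = "A", alt = "T"
      )
      sm <- pairwise_similarity(v)
      expect_equal(sm$jaccard_pct, t(sm$jaccard_pct))
      expect_equal(unname(diag(sm$jaccard_pct)), rep(100, 4))
      expect_equal(unname(diag(sm$shared)), lengths(lapply(sets, unique)))
      # invariant to sample ordering up to permutation
      sm2 <- pairwise_similarity(v, samples = c("S3", "S1", "S4", "S2"))
      expect_equal(sm2$jaccard_pct[rownames(sm$jaccard_pct),
                                   colnames(sm$jaccard_pct)],
                   sm$jaccard_pct)
    }
  })
})

test_that("intersection patterns match the brute-force membership tally", {
  v <- tibble::tibble(
    sample = c("A", "A", "A", "B", "B", "B", "C"),
    chrom = "chr1", pos = c(1, 2, 3, 2, 3, 4, 3), ref = "A", alt = "T"
  )
  ip <- intersection_pattern_counts(v)
  pat <- stats::setNames(ip$patterns$n, ip$patterns$pattern)
  expect_equal(pat[["A"]], 1)       # pos 1
  expect_equal(pat[["A&B"]], 1)     # pos 2
  expect_equal(pat[["A&B&C"]], 1)   # pos 3
  expect_equal(pat[["B"]], 1)       # pos 4
  expect_equal(ip$union_size, 4)
  # singleton collection: one pattern holding everything
  solo <- intersection_pattern_counts(dplyr::filter(v, sample == "A"))
  expect_equal(solo$patterns$pattern, "A")
  expect_equal(solo$patterns$n, 3)
})

test_that("pattern counts agree with the oracle on random collections", {
  withr::with_seed(17, {
    for (i in 1:10) {
      sets <- lapply(1:5, function(j) sample(1:100, sample(10:60, 1)))
      names(sets) <- paste0("S", 1:5)
      v <- tibble::tibble(
        sample = rep(names(sets), lengths(sets)),
        chrom = "chr1", pos = unlist(sets), ref = "A", alt = "T"
      )
      ip <- intersection_pattern_counts(v)
      oracle <- brute_patterns(lapply(sets, function(s)
        paste("chr1", s, "A", "T", sep = ":")))
      got <- dplyr::arrange(ip$patterns[, c("pattern", "n")], pattern)
      want <- dplyr::arrange(oracle, pattern)
      expect_equal(got$pattern, want$pattern)
      expect_equal(got$n, want$n)
      expect_equal(sum(ip$patterns$n), ip$union_size)
    }
  })
})

test_that("deleterious gene sets filter by effect with set semantics", {
  v <- tibble::tibble(
    sample = "S1", chrom = "chr1", pos = 1:3, ref = "A", alt = "T",
    gene = c("G1", "G2", "G1"),
    effect = c("missense_deleterious", "synonymous", "stop_gained")
  )
  gs <- deleterious_gene_sets(v, "missense_deleterious")
  expect_equal(gs$S1, "G1")
  # two deleterious variants in the same gene appear once
  gs2 <- deleterious_gene_sets(v)
  expect_equal(gs2$S1, "G1")
  no_ann <- dplyr::select(v, -gene, -effect)
  expect_error(deleterious_gene_sets(no_ann), "input")
})

test_that("recovered deleterious gene sets equal the planted truth", {
  sim <- simulate_clonal_variants(small_clonal_truth(seed = 23))
  got <- deleterious_gene_sets(sim$variants)
  expect_equal(got[sort(names(got))],
               sim$deleterious_genes[sort(names(got))])
})

test_that("the PDX contamination filter is a plain intersection", {
  expect_equal(pdx_contamination_filter(c("G1", "G2", "G3"), c("G2", "G3", "G4")),
               c("G2", "G3"))
  expect_equal(pdx_contamination_filter(c("A", "B"), c("A", "B")), c("A", "B"))
  expect_length(pdx_contamination_filter(c("A"), c("B")), 0)
})
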