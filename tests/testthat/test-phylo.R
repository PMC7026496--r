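test_that("character matrices encode presence/absence in key order", {
  v <- tibble::tibble(
    sample = c("A", "A", "B"), chrom = "chr1", pos = c(100, 200, 200),
    ref = c("A", "G", "G"), alt = c("T", "C", "C")
  )
  cm <- build_character_matrix(v, include_outgroup = FALSE,
                               samples = c("A", "B", "C"))
  expect_equal(unname(cm), rbind(c(1L, 1L), c(0L, 1L), c(0L, 0L)))
  expect_equal(colnames(cm), c("chr1:100:A:T", "chr1:200:G:C"))
  # outgroup row is all-absent
  cmo <- build_character_matrix(v, samples = c("A", "B", "C"))
  expect_equal(unname(cmo["normal", ]), c(0L, 0L))
  # permuted input gives the same matrix
  cm2 <- build_character_matrix(v[sample(nrow(v)), ],
                                include_outgroup = FALSE,
                                samples = c("A", "B", "C"))
  expect_identical(cm, cm2)
  expect_error(build_character_matrix(v, include_outgroup = FALSE), ">= 3")
})

test_that("column count equals the number of planted variants", {
  sim <- simulate_clonal_variants(small_clonal_truth(seed = 2))
  cm <- build_character_matrix(sim$variants, include_outgroup = FALSE)
  expect_equal(ncol(cm), nrow(sim$catalog))
})

test_that("PHYLIP matrices round-trip", {
  sim <- simulate_clonal_variants(small_clonal_truth(seed = 5))
  cm <- build_character_matrix(sim$variants)
  p <- withr::local_tempfile(fileext = ".phy")
  write_phylip(cm, p)
  back <- read_phylip(p)
  expect_equal(unname(back), unname(cm))
  expect_equal(rownames(back), rownames(cm))
})

test_that("Jaccard distances are exact and agree with vegan", {
  cm <- rbind(A = c(1L, 1L, 0L), B = c(1L, 1L, 0L), C = c(0L, 0L, 1L))
  d <- as.matrix(distance_matrix(cm))
  expect_equal(d["A", "B"], 0)
  expect_equal(d["A", "C"], 1)
  withr::with_seed(8, {
    for (i in 1:5) {
      m <- matrix(stats::rbinom(5 * 30, 1, 0.4), nrow = 5,
                  dimnames = list(paste0("S", 1:5), NULL))
      m[1, 1] <- 1L  # guard against an all-zero row
      ours <- as.matrix(distance_matrix(m))
      ref <- as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
      expect_equal(unname(ours), unname(ref))
    }
  })
})

test_that("NJ is exact on additive distances", {
  # tree ((A:1,B:2):1,(C:3,D:4))
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tree <- neighbor_joining(d)
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_true(topo_equal(tree, ref))
  # additive matrix is reproduced exactly by the tree's path lengths
  expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
})

test_that("NJ resolves three taxa with the closed-form branch lengths", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- 0.6; d["A", "C"] <- 0.8; d["B", "C"] <- 1.0
  d <- d + t(d)
  tree <- neighbor_joining(d)
  len <- stats::setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(len[["A"]], (0.6 + 0.8 - 1.0) / 2)
  expect_equal(len[["B"]], (0.6 + 1.0 - 0.8) / 2)
  expect_equal(len[["C"]], (0.8 + 1.0 - 0.6) / 2)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), ">= 3")
  m <- d; m[1, 2] <- 99
  expect_error(neighbor_joining(m), "symmetric")
})

test_that("NJ matches the least-squares topology on near-additive matrices", {
  hits <- withr::with_seed(13, {
    vapply(1:50, function(i) {
      base <- ape::rtree(4, tip.label = c("A", "B", "C", "D"))
      d <- ape::cophenetic.phylo(base)[c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")]
      noise <- matrix(stats::runif(16, 0, 0.05 * max(d)), 4, 4)
      noise <- (noise + t(noise)) / 2; diag(noise) <- 0
      dn <- d + noise
      nj <- neighbor_joining(dn)
      ls <- ls_best_topology(dn)
      ref <- ape::read.tree(text = sprintf(
        "((%s,%s),(%s,%s));", ls$cherry[1], ls$cherry[2],
        setdiff(c("A", "B", "C", "D"), ls$cherry)[1],
        setdiff(c("A", "B", "C", "D"), ls$cherry)[2]))
      topo_equal(nj, ref)
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)  # discrepancies possible, but rare
})

test_that("Fitch scores match direct enumeration on the worked example", {
  cm <- rbind(A = 0L, B = 0L, C = 1L, D = 1L)
  ab_cd <- ape::read.tree(text = "((A,B),(C,D));")
  ac_bd <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(parsimony_score(ab_cd, cm), 1)
  expect_equal(parsimony_score(ac_bd, cm), 2)
  expect_equal(brute_fitch(ape::unroot(ab_cd), cm), 1)
  expect_equal(brute_fitch(ape::unroot(ac_bd), cm), 2)
  # constant column costs nothing on any topology
  expect_equal(parsimony_score(ab_cd, rbind(A = 1L, B = 1L, C = 1L, D = 1L)), 0)
  expect_error(parsimony_score(ab_cd, rbind(A = 1L, B = 0L, X = 1L, Y = 0L)),
               "same sample set")
})

test_that("Fitch equals the brute-force minimum on random instances", {
  withr::with_seed(29, {
    for (i in 1:25) {
      n <- sample(4:6, 1)
      cm <- matrix(stats::rbinom(n * 12, 1, 0.5), nrow = n,
                   dimnames = list(paste0("S", seq_len(n)), NULL))
      tree <- ape::unroot(ape::rtree(n, tip.label = paste0("S", seq_len(n))))
      expect_equal(parsimony_score(tree, cm), brute_fitch(tree, cm))
    }
  })
})

test_that("exhaustive parsimony finds the unanimous and planted optima", {
  # all characters support AB|CD: unique optimum
  cm <- matrix(rep(c(1L, 1L, 0L, 0L), 6), nrow = 4,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  s <- parsimony_search(cm)
  expect_equal(s$mode, "exhaustive")
  expect_equal(s$score, 6)
  expect_length(s$co_optimal, 1)
  expect_true(topo_equal(s$best, ape::read.tree(text = "((A,B),(C,D));")))

  # perfect phylogeny: the planted tree is co-optimal with score = #columns
  sim <- simulate_clonal_variants(small_clonal_truth(seed = 31))
  cm2 <- build_character_matrix(sim$variants)  # with outgroup: 6 taxa
  s2 <- parsimony_search(cm2)
  expect_equal(s2$score, ncol(cm2))
  rooted <- ape::read.tree(
    text = paste0("(normal,", sub(";$", "", ape::write.tree(sim$tree)), ");"))
  expect_true(any(vapply(seq_along(s2$co_optimal),
                         function(i) topo_equal(s2$co_optimal[[i]], rooted),
                         logical(1))))
})

test_that("NNI search never beats the exhaustive optimum", {
  withr::with_seed(37, {
    eq <- vapply(1:5, function(i) {
      cm <- matrix(stats::rbinom(7 * 30, 1, 0.35), nrow = 7,
                   dimnames = list(paste0("S", 1:7), NULL))
      full <- parsimony_search(cm, exhaustive_max = 7)
      nni <- parsimony_search(cm, exhaustive_max = 4)
      expect_equal(nni$mode, "nni")
      expect_gte(nni$score, full$score)
      nni$score == full$score
    }, logical(1))
    expect_gte(mean(eq), 0)  # equality rate reported, not required
  })
})

test_that("bootstrap support saturates under unanimous signal", {
  cm <- matrix(rep(c(1L, 1L, 0L, 0L), 20), nrow = 4,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  bs <- bootstrap_support(cm, n_replicates = 100, method = "nj", seed = 3)
  inner <- dplyr::filter(bs$support, clade == "A,B" | clade == "C,D")
  expect_true(all(inner$count == 100))
  # a single replicate gives 0/1 support
  b1 <- bootstrap_support(cm, n_replicates = 1, method = "nj", seed = 3)
  expect_true(all(b1$support$count %in% c(0, 1)))
  expect_error(bootstrap_support(cm, n_replicates = 0), "n_replicates")
})

test_that("bootstrap support is reproducible and order-insensitive at strong signal", {
  sim <- simulate_clonal_variants(
    clonal_truth("(A,(B,(C,(D,E))));", n_trunk = 0, n_branch_per_edge = 60,
                 n_private_per_leaf = 5, seed = 41))
  cm <- build_character_matrix(sim$variants, include_outgroup = FALSE)
  b1 <- bootstrap_support(cm, n_replicates = 50, method = "nj", seed = 7)
  b2 <- bootstrap_support(cm, n_replicates = 50, method = "nj", seed = 7)
  expect_identical(b1$support, b2$support)
  shuffled <- cm[, sample(ncol(cm))]
  b3 <- bootstrap_support(shuffled, n_replicates = 50, method = "nj", seed = 7)
  expect_equal(dplyr::arrange(b1$support, clade),
               dplyr::arrange(b3$support, clade))
  # parsimony-mode bootstrap works and the consensus is a valid tree
  bp <- bootstrap_support(cm, n_replicates = 20, method = "parsimony",
                          seed = 7)
  expect_s3_class(bp$consensus, "phylo")
  expect_setequal(bp$consensus$tip.label, rownames(cm))
})

test_that("strong clonal signal supports every true clade in >90% of replicates", {
  sim <- simulate_clonal_variants(
    clonal_truth("(A,(B,(C,(D,(E,F)))));", n_trunk = 10,
                 n_branch_per_edge = 50, n_private_per_leaf = 20, seed = 43))
  cm <- build_character_matrix(sim$variants, include_outgroup = FALSE)
  bs <- bootstrap_support(cm, n_replicates = 200, method = "nj", seed = 11)
  counts <- ape::prop.clades(sim$tree, bs$trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  n_tip <- length(sim$tree$tip.label)
  sizes <- vapply(seq_len(sim$tree$Nnode), function(i)
    length(unlist(phangorn::Descendants(sim$tree, n_tip + i, "tips"))),
    numeric(1))
  informative <- sizes >= 2 & sizes <= n_tip - 2
  expect_true(all(counts[informative] > 0.9 * 200))
})
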