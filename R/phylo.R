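#' Binary presence/absence character matrix from variant sets
#'
#' One row per sample, one column per variant key in the union, entries 1
#' when the sample carries the variant. Columns are ordered by
#' (chrom, pos, ref, alt); an optional outgroup row of all-absent states
#' (the matched normal) can be appended for rooting displays.
#'
#' @param variants Long variant tibble covering >= 3 samples.
#' @param include_outgroup Append an all-zero outgroup row.
#' @param outgroup_name Row name for the outgroup.
#' @param samples Optional full sample list (covers samples with zero
#'   variants, which get all-zero rows); defaults to the samples present.
#' @return Integer matrix (samples x variants) with informative dimnames.
#' @export
build_character_matrix <- function(variants, include_outgroup = TRUE,
                                   outgroup_name = "normal",
                                   samples = NULL) {
  variants <- as_tibble(variants)
  samples <- sort(samples %||% unique(variants$sample))
  stopifnot(all(variants$sample %in% samples))
  if (length(samples) < 3) abort("Need >= 3 samples for a character matrix.")
  if (include_outgroup && outgroup_name %in% samples) {
    abort(sprintf("Outgroup name '%s' collides with a sample name.",
                  outgroup_name))
  }
  cols <- variants |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    arrange(chrom_rank(.data$chrom), .data$pos, .data$ref, .data$alt)
  keys <- paste(cols$chrom, cols$pos, cols$ref, cols$alt, sep = ":")
  m <- matrix(0L, length(samples), length(keys),
              dimnames = list(samples, keys))
  idx <- cbind(match(variants$sample, samples),
               match(variant_key(variants), keys))
  m[idx] <- 1L
  m <- m[, colSums(m) > 0, drop = FALSE]  # drop constant-absent columns
  if (include_outgroup) {
    m <- rbind(m, matrix(0L, 1, ncol(m),
                         dimnames = list(outgroup_name, NULL)))
  }
  m
}

#' Write / read a relaxed sequential PHYLIP matrix of 0/1 states
#'
#' @param cm Binary character matrix (samples x characters).
#' @param path File path.
#' @return `write_phylip` returns `path` invisibly; `read_phylip` the
#'   integer matrix.
#' @export
write_phylip <- function(cm, path) {
  width <- max(nchar(rownames(cm))) + 2L
  lines <- c(
    sprintf("%d %d", nrow(cm), ncol(cm)),
    sprintf("%-*s%s", width, rownames(cm),
            apply(cm, 1, paste, collapse = ""))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- strsplit(trimws(lines[-1]), "\\s+")
  stopifnot(length(body) == hdr[1])
  names <- map_chr(body, 1)
  states <- map(body, function(x) as.integer(strsplit(x[2], "")[[1]]))
  stopifnot(all(lengths(states) == hdr[2]))
  matrix(unlist(states), nrow = hdr[1], byrow = TRUE,
         dimnames = list(names, NULL))
}

#' Jaccard distance matrix between samples' variant profiles
#'
#' `d(i, j) = 1 - |A intersect B| / |A union B|` computed on the binary
#' rows; two all-zero rows get distance 0 with a warning.
#'
#' @param cm Binary character matrix with >= 3 rows.
#' @return A [stats::dist] object.
#' @export
distance_matrix <- function(cm) {
  n <- nrow(cm)
  if (n < 3) abort("Need >= 3 rows.")
  d <- matrix(0, n, n, dimnames = list(rownames(cm), rownames(cm)))
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- sum(cm[i, ] & cm[j, ])
      uni <- sum(cm[i, ] | cm[j, ])
      if (uni == 0) {
        warned <- TRUE
        d[i, j] <- d[j, i] <- 0
      } else {
        d[i, j] <- d[j, i] <- 1 - inter / uni
      }
    }
  }
  if (warned) warn("All-zero row pair(s): distance defined as 0.")
  as.dist(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (exact on additive distances). Negative branch
#' lengths are clamped to zero and the total clamped deficit reported.
#'
#' @param d A [stats::dist] or symmetric matrix with zero diagonal.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) abort("Need >= 3 taxa.")
  if (!isSymmetric(unname(m), tol = 1e-8) || any(abs(diag(m)) > 1e-12)) {
    abort("Distance matrix must be symmetric with zero diagonal.")
  }
  tree <- ape::nj(as.dist(m))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    inform(sprintf("Clamped %d negative NJ branch length(s); total deficit %.4g.",
                   sum(neg), -sum(tree$edge.length[neg])))
    tree$edge.length[neg] <- 0
  }
  tree
}

# root an unrooted binary tree for postorder traversal; Fitch counts are
# rooting-invariant on binary trees
rooted_binary <- function(tree) {
  if (ape::is.rooted(tree) && ape::is.binary(tree)) return(tree)
  ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
}

#' Fitch small-parsimony score of a tree on binary characters
#'
#' Minimum number of 0/1 state changes required over the tree, summed over
#' all character columns (the classic Fitch dynamic program, evaluated
#' bottom-up with set intersection/union on every internal node).
#'
#' @param tree `ape::phylo`; leaves must match the matrix rows.
#' @param cm Binary character matrix.
#' @param per_column Return the per-column change counts instead of the sum.
#' @return Integer total (or integer vector when `per_column`).
#' @export
parsimony_score <- function(tree, cm, per_column = FALSE) {
  if (!setequal(tree$tip.label, rownames(cm))) {
    abort("Tree leaves and matrix rows must be the same sample set.")
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  ncols <- ncol(cm)
  # state-set bitmasks per node: 1 = {0}, 2 = {1}, 3 = {0,1}; tips are
  # certain, internal nodes accumulate children by intersection/union.
  # The basal trichotomy of an unrooted binary tree combines sequentially,
  # which equals rooting on the edge to its last child (the Fitch count is
  # rooting-invariant on binary trees).
  tip_masks <- cm[tr$tip.label, , drop = FALSE] + 1L
  storage.mode(tip_masks) <- "integer"
  node_masks <- vector("list", n_node)
  changes <- integer(ncols)
  parents <- tr$edge[, 1]
  children <- tr$edge[, 2]
  for (e in seq_along(parents)) {
    child <- children[e]
    cmask <- if (child <= n_tip) tip_masks[child, ] else node_masks[[child]]
    parent <- parents[e]
    p <- node_masks[[parent]]
    if (is.null(p)) {
      node_masks[[parent]] <- cmask
    } else {
      inter <- bitwAnd(p, cmask)
      empty <- inter == 0L
      if (any(empty)) {
        changes <- changes + empty
        inter[empty] <- bitwOr(p[empty], cmask[empty])
      }
      node_masks[[parent]] <- inter
    }
  }
  if (per_column) changes else sum(changes)
}

# materialise a (possibly compressed) multiPhylo as a plain list of phylo
as_phylo_list <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  lapply(seq_along(trees), function(i) trees[[i]])
}

canonical_newick <- function(tree) {
  n_tip <- length(tree$tip.label)
  tr <- rooted_binary(tree)
  children <- split(tr$edge[, 2], tr$edge[, 1])
  rec <- function(node) {
    if (node <= n_tip) return(tr$tip.label[node])
    kids <- sort(map_chr(children[[as.character(node)]], rec))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  paste0(rec(n_tip + 1L), ";")
}

#' Maximum-parsimony tree search on binary characters
#'
#' For `n <= exhaustive_max` taxa every unrooted binary topology is scored
#' (exact optimum, all co-optimal trees returned, canonically ordered);
#' otherwise nearest-neighbor-interchange hill climbing starts from the
#' neighbor-joining tree, with lexicographic tie-breaking on the canonical
#' newick string.
#'
#' @param cm Binary character matrix with >= 3 rows.
#' @param exhaustive_max Largest taxon count for exhaustive enumeration.
#' @return List of class `parsimony_search`: `best` (phylo), `co_optimal`
#'   (multiPhylo), `score`, `mode`.
#' @export
parsimony_search <- function(cm, exhaustive_max = 8L) {
  n <- nrow(cm)
  if (n < 3) abort("Need >= 3 taxa.")
  if (n <= exhaustive_max) {
    trees <- as_phylo_list(
      phangorn::allTrees(n, rooted = FALSE, tip.label = rownames(cm))
    )
    scores <- map_int(trees, parsimony_score, cm = cm)
    best_score <- min(scores)
    co <- trees[scores == best_score]
    ord <- order(map_chr(co, canonical_newick))
    co <- co[ord]
    mode <- "exhaustive"
  } else {
    cur <- neighbor_joining(distance_matrix(cm))
    cur$edge.length <- NULL
    cur_score <- parsimony_score(cur, cm)
    repeat {
      nbrs <- as_phylo_list(phangorn::nni(cur))
      scores <- map_int(nbrs, parsimony_score, cm = cm)
      if (min(scores) >= cur_score) {
        ties <- nbrs[scores == cur_score]
        co <- c(list(cur), ties)
        break
      }
      cands <- nbrs[scores == min(scores)]
      cur <- cands[[order(map_chr(cands, canonical_newick))[1]]]
      cur_score <- min(scores)
    }
    keys <- map_chr(co, canonical_newick)
    ord <- order(keys)
    co <- co[ord][!duplicated(keys[ord])]
    best_score <- cur_score
    mode <- "nni"
  }
  class(co) <- "multiPhylo"
  structure(
    list(best = co[[1]], co_optimal = co, score = best_score, mode = mode),
    class = "parsimony_search"
  )
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat(sprintf("Parsimony search (%s): score %d, %d co-optimal tree(s)\n",
              x$mode, x$score, length(x$co_optimal)))
  invisible(x)
}

#' Bootstrap clade support and majority-rule consensus
#'
#' Characters (columns) are resampled with replacement `n_replicates`
#' times; a tree is rebuilt on each pseudo-matrix with the chosen method,
#' and the support of each clade of the reference tree is the number of
#' replicate trees containing it. The majority-rule consensus keeps clades
#' present in > 50% of replicate trees.
#'
#' @param cm Binary character matrix.
#' @param n_replicates Bootstrap replicates (the conventional full analysis
#'   uses 1,000).
#' @param method `"nj"` (neighbor joining on Jaccard distances) or
#'   `"parsimony"` ([parsimony_search()] best tree).
#' @param seed Integer seed for the resampling.
#' @return List of class `bootstrap_support`: `tree` (reference tree with
#'   support counts as node labels), `consensus` (majority-rule), `support`
#'   (tibble: clade, count, prop), `trees` (the replicate trees),
#'   `n_replicates`, `method`.
#' @export
bootstrap_support <- function(cm, n_replicates = 1000L,
                              method = c("nj", "parsimony"), seed = 1L) {
  method <- match.arg(method)
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  builder <- switch(method,
    nj = function(m) neighbor_joining(suppressWarnings(distance_matrix(m))),
    parsimony = function(m) parsimony_search(m)$best
  )
  ref <- builder(cm)
  boots <- with_seed(seed, {
    map(seq_len(n_replicates), function(i) {
      builder(cm[, sample.int(ncol(cm), replace = TRUE), drop = FALSE])
    })
  })
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- counts
  cons <- ape::consensus(boots, p = 0.5, rooted = FALSE)
  n_tip <- length(ref$tip.label)
  clade_tips <- map_chr(seq_len(ref$Nnode), function(i) {
    tips <- ref$tip.label[unlist(phangorn::Descendants(ref, n_tip + i, "tips"))]
    paste(sort(tips), collapse = ",")
  })
  structure(
    list(
      tree = ref,
      consensus = cons,
      support = tibble(clade = clade_tips, count = counts,
                       prop = counts / n_replicates),
      trees = boots,
      n_replicates = n_replicates,
      method = method
    ),
    class = "bootstrap_support"
  )
}

#' @export
print.bootstrap_support <- function(x, ...) {
  cat(sprintf("Bootstrap support (%s, %d replicates)\n",
              x$method, x$n_replicates))
  print(x$support)
  invisible(x)
}
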