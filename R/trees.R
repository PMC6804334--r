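# Distance matrices, dendrograms, and weighted Robinson-Foulds comparison -----

#' Pairwise Euclidean distance between sample coordinates
#'
#' @param coords A data.frame with columns \code{sample_id}, \code{x},
#'   \code{y} (Cartesian, e.g. mm on the tumor slice).
#' @return A symmetric distance matrix with sample ids as dimnames.
#' @export
coordinate_matrix <- function(coords) {
  need <- c("sample_id", "x", "y")
  if (!all(need %in% names(coords)))
    stop("coords needs columns sample_id, x, y")
  if (anyDuplicated(coords$sample_id)) stop("duplicate sample ids")
  if (nrow(coords) < 2L) stop("need at least 2 samples")
  m <- as.matrix(stats::dist(coords[, c("x", "y")]))
  dimnames(m) <- list(coords$sample_id, coords$sample_id)
  m
}

#' Distance between per-sample heteroplasmy MAF profiles
#'
#' Each sample is a vector of minor-allele fractions over the union of
#' heteroplasmic sites; a site not called in a sample contributes 0 (absent
#' means no detectable minor allele). Distance is the Euclidean (default) or
#' Manhattan norm of the difference vector.
#'
#' @param maf A samples x sites numeric matrix of MAFs in [0, 0.5]; NA is
#'   treated as 0.
#' @param metric \code{"euclidean"} (default) or \code{"manhattan"}.
#' @return A symmetric distance matrix over the row names of \code{maf}.
#' @export
het_matrix <- function(maf, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  maf <- as.matrix(maf)
  maf[is.na(maf)] <- 0
  if (any(maf < 0 | maf > 0.5)) stop("MAFs must lie in [0, 0.5]")
  if (is.null(rownames(maf))) stop("maf matrix needs sample row names")
  m <- as.matrix(stats::dist(maf, method = metric))
  dimnames(m) <- list(rownames(maf), rownames(maf))
  m
}

#' Distance between scalar per-sample values
#'
#' Absolute differences; the resulting dendrogram cannot branch (a
#' caterpillar), since a one-dimensional character carries no nested
#' structure.
#'
#' @param values A named numeric vector (names are sample ids).
#' @return A symmetric distance matrix.
#' @export
scalar_matrix <- function(values) {
  if (is.null(names(values))) stop("values must be named by sample id")
  m <- abs(outer(values, values, "-"))
  dimnames(m) <- list(names(values), names(values))
  m
}

#' Min-max normalize a distance matrix
#'
#' Off-diagonal entries are mapped to [0, 1] by (d - min) / (max - min)
#' over the off-diagonal values; the diagonal stays 0. A constant matrix
#' maps to all zeros. \code{method = "maxscale"} instead divides by the
#' maximum, preserving ratios.
#'
#' @param m A symmetric distance matrix.
#' @param method \code{"minmax"} (default) or \code{"maxscale"}.
#' @return The normalized matrix.
#' @export
normalize_distances <- function(m, method = c("minmax", "maxscale")) {
  method <- match.arg(method)
  m <- as.matrix(m)
  off <- row(m) != col(m)
  v <- m[off]
  if (!length(v)) return(m)
  rng <- range(v)
  out <- m
  if (method == "minmax") {
    out[off] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else 0
  } else {
    out[off] <- if (rng[2] > 0) v / rng[2] else 0
  }
  diag(out) <- 0
  out
}

#' Build a dendrogram from a distance matrix
#'
#' Neighbor-joining (default) or UPGMA. Negative NJ branch lengths are
#' clamped to zero. When \code{root_id} is given, the tree is rooted on that
#' leaf's pendant edge (outgroup rooting).
#'
#' @param m A symmetric distance matrix with sample dimnames (or a dist).
#' @param method \code{"nj"} or \code{"upgma"}.
#' @param root_id Optional leaf label to root on.
#' @return An \code{ape} \code{phylo} tree.
#' @export
build_tree <- function(m, method = c("nj", "upgma"), root_id = NULL) {
  method <- match.arg(method)
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 samples to build a tree")
  if (is.null(rownames(m))) stop("distance matrix needs sample dimnames")
  if (method == "nj") {
    tr <- if (n == 3L) three_leaf_tree(m) else ape::nj(stats::as.dist(m))
    tr$edge.length[tr$edge.length < 0] <- 0
  } else {
    tr <- ape::as.phylo(stats::hclust(stats::as.dist(m), method = "average"))
  }
  if (!is.null(root_id)) {
    if (!root_id %in% tr$tip.label) stop("root_id not among the leaves")
    tr <- ape::root(tr, outgroup = root_id, resolve.root = TRUE)
  }
  tr
}

# Unique unrooted 3-leaf tree solved from the additive system.
three_leaf_tree <- function(m) {
  lab <- rownames(m)
  a <- (m[1, 2] + m[1, 3] - m[2, 3]) / 2
  b <- (m[1, 2] + m[2, 3] - m[1, 3]) / 2
  c <- (m[1, 3] + m[2, 3] - m[1, 2]) / 2
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", lab[1], a, lab[2], b,
                 lab[3], c)
  ape::read.tree(text = txt)
}

# Nontrivial bipartitions of an unrooted tree with their branch weights.
# Returned as a named numeric vector; the name is the sorted label set of
# the split side NOT containing the alphabetically smallest leaf.
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  wts <- tree$edge.length
  if (is.null(wts)) wts <- rep(0, nrow(edge))
  sets <- vector("list", nt + tree$Nnode)
  sets[seq_len(nt)] <- as.list(seq_len(nt))
  for (k in seq_len(nrow(edge)))
    sets[[edge[k, 1L]]] <- c(sets[[edge[k, 1L]]], sets[[edge[k, 2L]]])
  anchor <- min(tree$tip.label)
  keys <- character(0L); w <- numeric(0L)
  for (k in seq_len(nrow(edge))) {
    child <- edge[k, 2L]
    if (child <= nt) next
    tips <- tree$tip.label[sets[[child]]]
    if (length(tips) < 2L || length(tips) > nt - 2L) next
    if (anchor %in% tips) tips <- setdiff(tree$tip.label, tips)
    keys <- c(keys, paste(sort(tips), collapse = "\r"))
    w <- c(w, wts[k])
  }
  if (anyDuplicated(keys)) {
    agg <- tapply(w, keys, sum)
    w <- as.numeric(agg); keys <- names(agg)
  }
  stats::setNames(w, keys)
}

#' Weighted Robinson-Foulds distance
#'
#' Sum over the union of nontrivial bipartitions of the absolute difference
#' in branch weight, where a bipartition absent from a tree has weight 0.
#' Unrooted semantics: trees are unrooted before splits are extracted, so
#' pendant edges never contribute.
#'
#' @param t1,t2 \code{phylo} trees over identical leaf sets.
#' @return Nonnegative numeric; 0 for trees with identical weighted splits.
#' @export
wrfd <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share an identical leaf set")
  wrfd_from_splits(tree_splits(t1), tree_splits(t2))
}

wrfd_from_splits <- function(s1, s2) {
  keys <- union(names(s1), names(s2))
  w1 <- ifelse(keys %in% names(s1), s1[keys], 0)
  w2 <- ifelse(keys %in% names(s2), s2[keys], 0)
  sum(abs(w1 - w2))
}

#' Leaf-label permutation test for tree similarity
#'
#' The null distribution is the wRFD between \code{t1} and \code{t2} with
#' its leaf labels uniformly permuted; small observed distances (more
#' similar than label-scrambled trees) give small p-values. The p-value
#' uses the add-one convention p = (1 + #\{null <= observed\}) / (1 + n) and
#' can therefore never be 0.
#'
#' @param t1,t2 \code{phylo} trees over identical leaf sets.
#' @param n_permutations Number of label permutations; default 1000.
#' @param seed Optional integer seed.
#' @return A list of class \code{tree_comparison}: \code{wrfd},
#'   \code{p_value}, \code{n_permutations}, \code{null} (the null draws).
#' @export
permutation_test <- function(t1, t2, n_permutations = 1000L, seed = NULL) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share an identical leaf set")
  if (!is.null(seed)) set.seed(seed)
  s1 <- tree_splits(t1)
  obs <- wrfd_from_splits(s1, tree_splits(t2))

  # permuting leaf labels only relabels t2's split sides; precompute the
  # index sets once and remap labels per permutation
  t2u <- ape::unroot(t2)
  nt <- length(t2u$tip.label)
  t2u <- stats::reorder(t2u, "postorder")
  edge <- t2u$edge
  wts <- t2u$edge.length
  sets <- vector("list", nt + t2u$Nnode)
  sets[seq_len(nt)] <- as.list(seq_len(nt))
  for (k in seq_len(nrow(edge)))
    sets[[edge[k, 1L]]] <- c(sets[[edge[k, 1L]]], sets[[edge[k, 2L]]])
  keep <- which(edge[, 2L] > nt)
  idx_sets <- lapply(keep, function(k) sets[[edge[k, 2L]]])
  sizes <- lengths(idx_sets)
  ok <- sizes >= 2L & sizes <= nt - 2L
  idx_sets <- idx_sets[ok]
  split_w <- wts[keep][ok]
  labels <- sort(t2u$tip.label)
  anchor <- labels[1L]

  null <- vapply(seq_len(n_permutations), function(i) {
    perm <- sample(labels)
    names(perm) <- t2u$tip.label
    keys <- vapply(idx_sets, function(ix) {
      tips <- perm[t2u$tip.label[ix]]
      if (anchor %in% tips) tips <- setdiff(labels, tips)
      paste(sort(tips), collapse = "\r")
    }, character(1L))
    w <- split_w
    if (anyDuplicated(keys)) {
      agg <- tapply(w, keys, sum); w <- as.numeric(agg); keys <- names(agg)
    }
    wrfd_from_splits(s1, stats::setNames(w, keys))
  }, numeric(1L))

  structure(list(wrfd = obs,
                 p_value = (1 + sum(null <= obs)) / (1 + n_permutations),
                 n_permutations = as.integer(n_permutations),
                 null = null),
            class = "tree_comparison")
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat(sprintf("wRFD = %.4g, permutation p = %.4g (%d permutations)\n",
              x$wrfd, x$p_value, x$n_permutations))
  invisible(x)
}

#' Compare a set of dendrograms
#'
#' Computes the pairwise wRFD matrix over named trees, the permutation
#' p-value for each pair, and a second-level dendrogram built from the wRFD
#' matrix itself (how similar are the characteristics to one another).
#'
#' @param trees A named list of \code{phylo} trees with identical leaves.
#' @param n_permutations Permutations per pair.
#' @param seed Optional integer seed.
#' @param tree_method Method for the second-level dendrogram.
#' @return A list: \code{wrfd} (matrix), \code{p_values} (matrix),
#'   \code{tree} (phylo, \code{NULL} when fewer than 3 trees).
#' @export
compare_all <- function(trees, n_permutations = 1000L, seed = NULL,
                        tree_method = "nj") {
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    stop("trees must be a named list")
  if (!is.null(seed)) set.seed(seed)
  k <- length(trees)
  d <- matrix(0, k, k, dimnames = list(names(trees), names(trees)))
  p <- matrix(NA_real_, k, k, dimnames = dimnames(d))
  for (i in seq_len(k)) for (j in seq_len(k)) if (j > i) {
    cmp <- permutation_test(trees[[i]], trees[[j]], n_permutations)
    d[i, j] <- d[j, i] <- cmp$wrfd
    p[i, j] <- p[j, i] <- cmp$p_value
  }
  list(wrfd = d, p_values = p,
       tree = if (k >= 3L) build_tree(d, method = tree_method) else NULL)
}

#' Read / write a labelled distance matrix TSV
#'
#' @param m A matrix with dimnames.
#' @param path File path.
#' @return \code{write_matrix_tsv}: path invisibly; \code{read_matrix_tsv}:
#'   the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1L, check.names = FALSE))
}
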