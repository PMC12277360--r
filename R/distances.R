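#' Community distance matrices
#'
#' Square, labeled, symmetric matrices with zero diagonal. Bray-Curtis is
#' delegated to vegan; the tree-aware UniFrac family is computed from branch
#' descendant proportions of a rooted genus tree: for branch i with length
#' b_i and descendant relative abundances p_i, q_i in the two samples, the
#' generalized distance with exponent alpha is
#' `sum b_i (p_i+q_i)^alpha |p_i-q_i|/(p_i+q_i) / sum b_i (p_i+q_i)^alpha`
#' (branches absent from both samples skipped). alpha = 1 is the weighted
#' normalized UniFrac; the unweighted variant replaces the proportions by
#' presence/absence on the same branch decomposition.
#'
#' @name distances
NULL

#' Bray-Curtis dissimilarity
#'
#' @param table samples x genera count (or abundance) matrix, >= 2 samples.
#' @return square labeled distance matrix.
#' @export
bray_curtis <- function(table) {
  m <- .check_table(table)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (any(rowSums(m) == 0)) stop("zero-sum sample(s): ",
    paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  as.matrix(vegan::vegdist(m, method = "bray"))
}

# branch decomposition of a rooted tree: per-edge lengths and a
# tips x edges 0/1 descendant indicator (postorder accumulation)
.branch_decomposition <- function(tree) {
  nt <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  ne <- nrow(tr$edge)
  desc <- matrix(FALSE, nt + tr$Nnode, nt)
  desc[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (i in seq_len(ne)) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  ind <- t(desc[tr$edge[, 2], , drop = FALSE])  # tips x edges
  rownames(ind) <- tr$tip.label
  list(indicator = ind, lengths = tr$edge.length)
}

.unifrac_engine <- function(table, tree, pair_fun) {
  m <- .check_table(table)
  tree <- if (is.character(tree)) ape::read.tree(text = tree) else tree
  missing_leaves <- setdiff(colnames(m), tree$tip.label)
  if (length(missing_leaves))
    stop("genera absent from the tree: ", paste(missing_leaves, collapse = ", "))
  bd <- .branch_decomposition(tree)
  p <- relative_abundance(m)
  # tip proportions aligned to the tree's tip order (tree-only tips get 0),
  # then samples x branches descendant proportions
  full <- matrix(0, nrow(p), nrow(bd$indicator),
                 dimnames = list(rownames(p), rownames(bd$indicator)))
  full[, colnames(p)] <- p
  branch_prop <- full %*% bd$indicator
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- pair_fun(branch_prop[i, ], branch_prop[j, ], bd$lengths)
  }
  d
}

#' Generalized UniFrac distance
#'
#' @param table samples x genera count matrix; every genus must be a tree
#'   leaf.
#' @param tree rooted `phylo` tree (or Newick string) over the genus labels.
#' @param alpha abundance-weighting exponent in [0, 1]; 0.5 is the canonical
#'   compromise, 1 recovers weighted normalized UniFrac.
#' @return square labeled distance matrix.
#' @export
generalized_unifrac <- function(table, tree, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  .unifrac_engine(table, tree, function(p, q, b) {
    s <- p + q
    keep <- s > 0
    w <- b[keep] * s[keep]^alpha
    sum(w * abs(p[keep] - q[keep]) / s[keep]) / sum(w)
  })
}

#' Unweighted UniFrac distance
#'
#' Presence/absence variant on the same branch decomposition: the fraction
#' of branch length leading to lineages present in exactly one of the two
#' samples, over the branch length present in either.
#'
#' @inheritParams generalized_unifrac
#' @return square labeled distance matrix.
#' @export
unweighted_unifrac <- function(table, tree) {
  .unifrac_engine(table, tree, function(p, q, b) {
    pa <- p > 0; qa <- q > 0
    keep <- pa | qa
    sum(b[keep] * xor(pa[keep], qa[keep])) / sum(b[keep])
  })
}

#' Write a labeled square distance matrix as TSV
#'
#' @param d square labeled matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
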