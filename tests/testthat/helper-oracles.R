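# Independent oracles used across the suite. Each is deliberately coded on a
# different path than the implementation it checks.

# two-pass Pearson correlation for one column pair
pearson_two_pass <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# weighted normalized UniFrac via ape::prop.part clades (independent of the
# package's postorder branch accumulation)
weighted_unifrac_oracle <- function(p, q, tree) {
  stopifnot(setequal(names(p), tree$tip.label))
  p <- p[tree$tip.label]; q <- q[tree$tip.label]
  parts <- ape::prop.part(tree)
  nt <- length(tree$tip.label)
  clade_of_node <- function(node) {
    if (node <= nt) node else parts[[node - nt]]
  }
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- clade_of_node(tree$edge[e, 2])
    pe <- sum(p[tips]); qe <- sum(q[tips])
    num <- num + tree$edge.length[e] * abs(pe - qe)
    den <- den + tree$edge.length[e] * (pe + qe)
  }
  num / den
}

# brute-force AUC over all positive/negative pairs, ties half credit
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) for (sn in neg)
    total <- total + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
  total / (length(pos) * length(neg))
}

# brute-force tertile typing by explicit sort-and-cut
tertile_oracle <- function(x) {
  n <- length(x)
  s <- sort(x)
  lo <- s[ceiling(n / 3)]; hi <- s[ceiling(2 * n / 3)]
  vapply(x, function(v) if (v <= lo) "L" else if (v <= hi) "M" else "H",
         character(1))
}

# relabeling-invariant agreement between two partitions: best matching over
# label permutations (small numbers of clusters only)
partition_agreement <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  la <- unique(a); lb <- unique(b)
  if (length(la) > 6) stop("too many labels for exhaustive matching")
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  best <- 0
  for (p in perms(lb[seq_len(min(length(la), length(lb)))])) {
    m <- stats::setNames(p, la[seq_along(p)])
    best <- max(best, mean(!is.na(m[a]) & m[a] == b))
  }
  best
}

# small planted two-blob distance matrix (Euclidean on 2-D points)
blob_distance <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  rownames(pts) <- sprintf("P%03d", seq_len(nrow(pts)))
  list(d = as.matrix(dist(pts)),
       labels = rep(seq_len(nrow(centers)), each = n_per),
       points = pts)
}

# small random feature table + matching random coalescent tree
random_table_tree <- function(n_samples, n_taxa, seed) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, 20), n_samples, n_taxa,
              dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                              paste0("g", seq_len(n_taxa))))
  m[1, ] <- m[1, ] + 1  # guard against zero-sum rows
  tree <- ape::rcoal(n_taxa, tip.label = paste0("g", seq_len(n_taxa)))
  list(table = m, tree = tree)
}
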