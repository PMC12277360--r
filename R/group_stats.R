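#' Core-genus selection and group statistics
#'
#' @name group_stats
NULL

#' Tie-corrected Kruskal-Wallis test
#'
#' Thin wrapper around [stats::kruskal.test()] that degrades gracefully when
#' every value is tied (H = 0, p = 1).
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @return list with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1) return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Select prevalent and core genera
#'
#' Prevalent genera are detected (count > 0) in at least
#' `prevalence_threshold` of all samples (the default mode); the alternative
#' `"cumulative-abundance"` mode instead takes the most abundant genera whose
#' cumulative mean relative abundance reaches the threshold. Core genera are
#' the prevalent genera whose relative abundance differs across subclusters
#' by Kruskal-Wallis at `p < alpha` (raw p-values by default; optional
#' Benjamini-Hochberg).
#'
#' @param table samples x genera count matrix.
#' @param labels subcluster label per sample (>= 2 levels).
#' @param prevalence_threshold detection fraction (default 0.5).
#' @param alpha significance level (default 0.05).
#' @param mode `"prevalence"` (default) or `"cumulative-abundance"`.
#' @param adjust apply BH correction across tested genera (default FALSE).
#' @return list with `prevalent`, `core` (genus names, `core` a subset of
#'   `prevalent`), and `p_values` (named, for the prevalent genera).
#' @export
core_genus_selection <- function(table, labels, prevalence_threshold = 0.5,
                                 alpha = 0.05,
                                 mode = c("prevalence", "cumulative-abundance"),
                                 adjust = FALSE) {
  mode <- match.arg(mode)
  m <- .check_table(table)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(m))
  if (length(unique(labels)) < 2) stop("need at least 2 subclusters")
  rel <- relative_abundance(m)
  prevalent <- if (mode == "prevalence") {
    colnames(m)[colMeans(m > 0) >= prevalence_threshold]
  } else {
    mu <- sort(colMeans(rel), decreasing = TRUE)
    names(mu)[seq_len(which(cumsum(mu) >= prevalence_threshold)[1])]
  }
  p <- vapply(prevalent, function(g)
    kruskal_wallis(split(rel[, g], labels))$p, numeric(1))
  p_used <- if (adjust) stats::p.adjust(p, "BH") else p
  list(prevalent = prevalent,
       core = prevalent[p_used < alpha],
       p_values = p)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (999 permutations by
#' default) via [vegan::adonis2()]; the permutation p-value is
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`. Deterministic per seed.
#'
#' @param dist square labeled distance matrix.
#' @param labels group label per sample (>= 2 groups).
#' @param n_perm number of permutations (default 999).
#' @param seed seed.
#' @return list with `pseudo_F`, `p`, `n_perm`, and `singleton_groups`
#'   (groups with one member, flagged but allowed).
#' @export
permanova <- function(dist, labels, n_perm = 999, seed = 1L) {
  d <- as.matrix(dist)
  labels <- factor(labels)
  stopifnot(length(labels) == nrow(d))
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  singles <- names(which(table(labels) == 1))
  if (length(singles)) warning("singleton group(s): ",
                               paste(singles, collapse = ", "))
  set.seed(seed)
  df <- data.frame(grp = labels)
  fit <- vegan::adonis2(stats::as.dist(d) ~ grp, data = df,
                        permutations = n_perm)
  list(pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1], n_perm = n_perm,
       singleton_groups = singles)
}

#' LDA-style effect sizes for class-discriminating genera
#'
#' A documented simplification of the LEfSe procedure: features are first
#' screened by Kruskal-Wallis (alpha 0.05) on relative abundances; surviving
#' features are scored over bootstrap subsamples by the discriminant
#' class-mean difference of the feature on a per-million relative-abundance
#' scale, `log10(1 + |mean_hi - mean_lo| * 1e6)` (for more than two classes
#' the least-favourable one-vs-rest split is retained). Features scoring at
#' least `lda_threshold` are reported with their class of enrichment.
#'
#' @param table samples x genera count matrix.
#' @param labels class label per sample (classes with < 3 samples are
#'   excluded with a warning).
#' @param lda_threshold reporting threshold on the log10 score (default 2).
#' @param kw_alpha screening level (default 0.05).
#' @param n_boot bootstrap subsamples (default 30).
#' @param seed seed.
#' @return data.frame `feature`, `class` (enriched class), `score`, `p_kw`,
#'   sorted by decreasing score; only rows with `score >= lda_threshold`.
#' @export
lda_effect_size <- function(table, labels, lda_threshold = 2, kw_alpha = 0.05,
                            n_boot = 30, seed = 1L) {
  m <- .check_table(table)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(m))
  sizes <- table(labels)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("excluding classes with < 3 samples: ", paste(small, collapse = ", "))
    keep <- !labels %in% small
    m <- m[keep, , drop = FALSE]; labels <- labels[keep]
  }
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  rel <- relative_abundance(m)
  p_kw <- apply(rel, 2, function(v) kruskal_wallis(split(v, labels))$p)
  survivors <- colnames(rel)[p_kw < kw_alpha]
  if (length(survivors) == 0)
    return(data.frame(feature = character(0), class = character(0),
                      score = numeric(0), p_kw = numeric(0)))
  set.seed(seed)
  classes <- unique(labels)
  n <- nrow(rel)
  boots <- replicate(n_boot, sample(n, ceiling(2 * n / 3)), simplify = FALSE)
  rows <- lapply(survivors, function(g) {
    eff <- vapply(boots, function(idx) {
      lb <- labels[idx]
      if (length(unique(lb)) < 2) return(NA_real_)
      mu <- vapply(split(rel[idx, g], lb), mean, numeric(1))
      # least-favourable one-vs-rest separation
      min(vapply(names(mu), function(cl) {
        abs(mu[[cl]] - mean(rel[idx, g][lb != cl]))
      }, numeric(1)))
    }, numeric(1))
    score <- mean(log10(1 + eff * 1e6), na.rm = TRUE)
    mu_all <- vapply(split(rel[, g], labels), mean, numeric(1))
    data.frame(feature = g, class = names(mu_all)[which.max(mu_all)],
               score = score, p_kw = p_kw[[g]])
  })
  out <- do.call(rbind, rows)
  out <- out[out$score >= lda_threshold, , drop = FALSE]
  out[order(-out$score), , drop = FALSE]
}

#' Pairwise differential abundance across strata (CLR / Wilcoxon)
#'
#' Counts get a 0.5 pseudocount and a per-sample centered log-ratio
#' transform; each genus is then compared between every pair of strata with
#' a two-sided Wilcoxon rank-sum test, p-values BH-adjusted across the pairs
#' within the genus. The reported entry is
#' `sign(median CLR difference) * (-log10 adjusted p)`; entries with
#' `|entry| > 1` make the significance mask.
#'
#' @param table samples x genera count matrix.
#' @param strata stratum label per sample; strata with < 2 samples are
#'   excluded.
#' @param genera genera to test (default: all columns).
#' @return data.frame `genus`, `group1`, `group2`, `p`, `p_adj`, `entry`,
#'   `significant` (one row per genus x unordered pair).
#' @export
pairwise_differential <- function(table, strata, genera = colnames(table)) {
  m <- .check_table(table)[, genera, drop = FALSE]
  strata <- as.character(strata)
  sizes <- table(strata)
  keep <- strata %in% names(sizes)[sizes >= 2]
  m <- m[keep, , drop = FALSE]; strata <- strata[keep]
  lev <- sort(unique(strata))
  if (length(lev) < 2) stop("need at least 2 strata with >= 2 samples")
  lg <- log(m + 0.5)
  clr <- lg - rowMeans(lg)
  pairs <- utils::combn(lev, 2)
  out <- do.call(rbind, lapply(colnames(clr), function(g) {
    res <- apply(pairs, 2, function(pr) {
      a <- clr[strata == pr[1], g]; b <- clr[strata == pr[2], g]
      p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
      c(p = p, sgn = sign(stats::median(a) - stats::median(b)))
    })
    p_adj <- stats::p.adjust(res["p", ], "BH")
    data.frame(genus = g, group1 = pairs[1, ], group2 = pairs[2, ],
               p = res["p", ], p_adj = p_adj,
               entry = res["sgn", ] * -log10(p_adj))
  }))
  out$entry[is.na(out$entry)] <- 0
  out$significant <- abs(out$entry) > 1
  rownames(out) <- NULL
  out
}

#' Signed -log10 p matrix for one genus
#'
#' Antisymmetric square matrix view of [pairwise_differential()] rows.
#'
#' @param report data.frame from [pairwise_differential()].
#' @param genus genus name.
#' @return square antisymmetric matrix over the strata.
#' @export
pairwise_matrix <- function(report, genus) {
  r <- report[report$genus == genus, , drop = FALSE]
  if (nrow(r) == 0) stop("genus not in report: ", genus)
  lev <- sort(unique(c(r$group1, r$group2)))
  m <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_len(nrow(r))) {
    m[r$group1[i], r$group2[i]] <- r$entry[i]
    m[r$group2[i], r$group1[i]] <- -r$entry[i]
  }
  m
}

#' Filter a functional pathway abundance table
#'
#' Collapses duplicate pathway ids (first occurrence kept), removes pathways
#' whose cross-sample mean relative abundance is below `min_mean`, and
#' optionally z-scores each row for heatmap export (constant rows become 0).
#'
#' @param table pathways x samples matrix of relative abundances with
#'   pathway ids as row names.
#' @param min_mean mean-abundance floor (default 0.005, i.e. 0.5%).
#' @param zscore z-score rows (default FALSE).
#' @return filtered (optionally z-scored) matrix.
#' @export
filter_pathway_table <- function(table, min_mean = 0.005, zscore = FALSE) {
  m <- as.matrix(table)
  m <- m[!duplicated(rownames(m)), , drop = FALSE]
  m <- m[rowMeans(m) >= min_mean, , drop = FALSE]
  if (zscore) {
    m <- t(apply(m, 1, function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }))
  }
  m
}
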