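#' Optimal cluster number by four-index consensus
#'
#' For each candidate k the distance matrix is partitioned with
#' [pam_cluster()] and scored by four indices: the Calinski-Harabasz index
#' (computed on a principal-coordinate embedding of the distances), the mean
#' silhouette width, the within-cluster sum of squares elbow (the k with the
#' largest positive curvature of the WSS curve), and the Tibshirani-Walther
#' prediction strength over random halvings (the largest k whose minimum
#' cross-half co-membership stays at or above a threshold; k = 1 is the
#' fallback when no k qualifies). The consensus is the modal vote, ties
#' resolved toward the smaller k.
#'
#' @param dist square labeled distance matrix.
#' @param k_range candidate cluster numbers (default 2:10, truncated so that
#'   `n >= 2 * max(k_range)`).
#' @param n_halvings random halvings for prediction strength (default 10).
#' @param ps_threshold prediction-strength acceptance level (default 0.8).
#' @param n_axes principal coordinates for CH/WSS (default `min(10, n - 1)`).
#' @param seed seed for the halvings.
#' @return list with `k` (consensus), `votes` (named per-index votes) and
#'   `indices` (per-k table of CH, silhouette, WSS, prediction strength).
#' @export
optimal_k <- function(dist, k_range = 2:10, n_halvings = 10,
                      ps_threshold = 0.8, n_axes = NULL, seed = 1L) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (all(d == 0)) stop("degenerate distance matrix: all distances zero")
  k_range <- k_range[k_range >= 2 & 2 * k_range <= n]
  if (length(k_range) == 0) stop("no admissible k for n = ", n)
  if (is.null(n_axes)) n_axes <- min(10, n - 1)
  coords <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n_axes))

  wss_of <- function(assignment) {
    sum(vapply(split(seq_len(n), assignment), function(idx) {
      centroid <- colMeans(coords[idx, , drop = FALSE])
      sum(sweep(coords[idx, , drop = FALSE], 2, centroid)^2)
    }, numeric(1)))
  }
  ch_of <- function(assignment, k) {
    w <- wss_of(assignment)
    tot <- sum(sweep(coords, 2, colMeans(coords))^2)
    ((tot - w) / (k - 1)) / (w / (n - k))
  }

  sols <- lapply(k_range, function(k) pam_cluster(d, k))
  ch <- vapply(seq_along(k_range), function(i)
    ch_of(sols[[i]]$assignment, k_range[i]), numeric(1))
  sil <- vapply(sols, function(s) silhouette_widths(s$assignment, d)$mean,
                numeric(1))
  wss <- vapply(sols, function(s) wss_of(s$assignment), numeric(1))
  wss1 <- wss_of(rep(1L, n))
  ps <- vapply(k_range, function(k)
    prediction_strength(d, k, n_halvings = n_halvings, seed = seed),
    numeric(1))

  # elbow: largest curvature of the WSS curve including the k = 1 point
  wss_all <- c(wss1, wss)
  k_all <- c(1L, k_range)
  curv <- rep(NA_real_, length(k_all))
  for (i in 2:(length(k_all) - 1))
    curv[i] <- wss_all[i - 1] - 2 * wss_all[i] + wss_all[i + 1]
  vote_wss <- k_all[which.max(replace(curv, is.na(curv), -Inf))]

  ps_ok <- c(1L, k_range)[c(TRUE, !is.na(ps) & ps >= ps_threshold)]
  votes <- c(ch = k_range[which.max(ch)],
             silhouette = k_range[which.max(sil)],
             wss = vote_wss,
             prediction_strength = max(ps_ok))
  tab <- table(votes)  # numeric order, so the first modal entry is the smallest k
  consensus <- as.integer(names(tab)[tab == max(tab)][1])
  list(k = consensus, votes = votes,
       indices = data.frame(k = k_range, ch = ch, silhouette = sil,
                            wss = wss, prediction_strength = ps))
}

#' Prediction strength of a k-clustering
#'
#' Tibshirani-Walther statistic: the data are split into random halves, both
#' halves clustered with PAM; each test-half cluster is scored by the
#' fraction of its sample pairs that are co-assigned when test samples are
#' classified to the nearest training-half medoid, and the statistic is the
#' minimum over test clusters, averaged over halvings.
#'
#' @param dist square distance matrix.
#' @param k number of clusters.
#' @param n_halvings number of random halvings.
#' @param seed seed.
#' @return mean prediction strength in [0, 1].
#' @export
prediction_strength <- function(dist, k, n_halvings = 10, seed = 1L) {
  d <- as.matrix(dist)
  n <- nrow(d)
  stopifnot(k >= 2, 2 * k <= n)
  if (floor(n / 2) <= k) return(NA_real_)  # halves cannot support k clusters
  set.seed(seed)
  vals <- vapply(seq_len(n_halvings), function(h) {
    a <- sort(sample(n, floor(n / 2)))
    b <- setdiff(seq_len(n), a)
    train <- pam_cluster(d[a, a, drop = FALSE], k)
    test <- pam_cluster(d[b, b, drop = FALSE], k)
    train_medoids <- match(train$medoids, rownames(d))
    transfer <- apply(d[b, train_medoids, drop = FALSE], 1, which.min)
    per_cluster <- vapply(split(seq_along(b), test$assignment), function(idx) {
      if (length(idx) < 2) return(1)
      pairs <- utils::combn(idx, 2)
      mean(transfer[pairs[1, ]] == transfer[pairs[2, ]])
    }, numeric(1))
    min(per_cluster)
  }, numeric(1))
  mean(vals)
}

#' Divide-and-compare recursive subclustering
#'
#' Re-runs the optimal-k consensus within each top-level cluster and splits
#' it when (i) the consensus is k >= 2, (ii) the resulting split has a mean
#' silhouette of at least `s_min`, and (iii) the prediction strength at the
#' consensus k is at least `ps_min`. The prediction-strength gate is what
#' protects homogeneous clusters: the CH and silhouette indices cannot
#' express "no structure" (they are undefined at k = 1), whereas prediction
#' strength collapses on arbitrary splits of unstructured data. Samples with
#' a negative silhouette width at any accepted level are moved to the
#' unclassified set.
#'
#' @param dist square labeled distance matrix over all samples.
#' @param top_solution `cluster_solution` for the top level.
#' @param min_size smallest top cluster eligible for splitting (default 8).
#' @param s_min minimum mean silhouette to accept a split (default 0.25).
#' @param ps_min minimum prediction strength at the consensus k to accept a
#'   split (default 0.8).
#' @param k_range candidate subcluster numbers (default 2:10; truncated per
#'   cluster size).
#' @param seed seed for prediction-strength halvings.
#' @return list with `assignment` (named subcluster labels such as
#'   `"C1-sub2"`, or `NA` for unclassified), `hierarchy` (top cluster of each
#'   subcluster label), `unclassified` (sample labels), and `detail`
#'   (per-top-cluster vote tables).
#' @export
divcom_subcluster <- function(dist, top_solution, min_size = 8, s_min = 0.25,
                              ps_min = 0.8, k_range = 2:10, seed = 1L) {
  stopifnot(inherits(top_solution, "cluster_solution"), min_size >= 4)
  d <- as.matrix(dist)
  labels <- names(top_solution$assignment)
  out <- stats::setNames(rep(NA_character_, length(labels)), labels)
  hierarchy <- character(0)
  unclassified <- character(0)
  detail <- list()

  top_sil <- silhouette_widths(top_solution$assignment, d)
  for (cl in sort(unique(top_solution$assignment))) {
    members <- labels[top_solution$assignment == cl]
    top_name <- paste0("C", cl)
    neg_top <- members[top_sil$widths[members] < 0]
    keep <- setdiff(members, neg_top)
    unclassified <- c(unclassified, neg_top)
    sub_d <- d[keep, keep, drop = FALSE]
    split_done <- FALSE
    if (length(keep) >= min_size) {
      kr <- k_range[2 * k_range <= length(keep)]
      if (length(kr)) {
        ok <- optimal_k(sub_d, k_range = kr, seed = seed)
        detail[[top_name]] <- ok
        ps_at_k <- ok$indices$prediction_strength[match(ok$k, ok$indices$k)]
        if (ok$k >= 2 && !is.na(ps_at_k) && ps_at_k >= ps_min) {
          sub_sol <- pam_cluster(sub_d, ok$k)
          sub_sil <- silhouette_widths(sub_sol$assignment, sub_d)
          if (!is.na(sub_sil$mean) && sub_sil$mean >= s_min) {
            neg_sub <- keep[sub_sil$widths < 0]
            unclassified <- c(unclassified, neg_sub)
            for (s in seq_len(ok$k)) {
              lab <- paste0(top_name, "-sub", s)
              idx <- setdiff(keep[sub_sol$assignment == s], neg_sub)
              out[idx] <- lab
              hierarchy[lab] <- top_name
            }
            split_done <- TRUE
          }
        }
      }
    }
    if (!split_done) {
      out[keep] <- top_name
      hierarchy[top_name] <- top_name
    }
  }
  list(assignment = out, hierarchy = hierarchy,
       unclassified = sort(unique(unclassified)), detail = detail)
}
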