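#' Partitioning around medoids on a precomputed distance matrix
#'
#' Deterministic PAM: greedy BUILD initialisation followed by best-improvement
#' SWAP until no medoid exchange lowers the objective (total distance of
#' every sample to its nearest medoid). All ties break toward the lowest
#' sample index, so the solution is a pure function of the distance matrix.
#'
#' @param dist square labeled distance matrix (or `dist` object).
#' @param k number of clusters, `2 <= k < n`.
#' @return a `cluster_solution` list: `assignment` (named integer cluster
#'   ids 1..k), `medoids` (sample labels), `k`, `objective` (final value),
#'   `objective_trace` (value after BUILD and after each SWAP step).
#' @export
pam_cluster <- function(dist, k) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # BUILD: first medoid minimises total distance; each next maximises the
  # decrease of the objective
  medoids <- which.min(colSums(d))
  nearest <- d[, medoids]
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    gains <- vapply(cand, function(cc) sum(pmax(nearest - d[, cc], 0)),
                    numeric(1))
    pick <- cand[which.max(gains)]
    medoids <- c(medoids, pick)
    nearest <- pmin(nearest, d[, pick])
  }
  trace <- sum(nearest)

  # SWAP: best improving (medoid, candidate) exchange, scanned in index order
  repeat {
    obj <- sum(apply(d[, medoids, drop = FALSE], 1, min))
    best_obj <- obj; best <- NULL
    for (mi in seq_along(medoids)) {
      others <- medoids[-mi]
      min_without <- if (length(others))
        apply(d[, others, drop = FALSE], 1, min) else rep(Inf, n)
      cand <- setdiff(seq_len(n), medoids)
      objs <- colSums(pmin(d[, cand, drop = FALSE], min_without))
      w <- which(objs < best_obj - 1e-12)
      if (length(w)) {
        j <- w[which.min(objs[w])]
        best_obj <- objs[j]
        best <- c(medoids[mi], cand[j])
      }
    }
    if (is.null(best)) break
    medoids <- c(setdiff(medoids, best[1]), best[2])
    trace <- c(trace, best_obj)
  }

  medoids <- sort(medoids)
  assign_idx <- apply(d[, medoids, drop = FALSE], 1, which.min)
  structure(list(
    assignment = stats::setNames(as.integer(assign_idx), labels),
    medoids = labels[medoids],
    k = as.integer(k),
    objective = sum(d[cbind(seq_len(n), medoids[assign_idx])]),
    objective_trace = trace),
    class = "cluster_solution")
}

#' Mean silhouette width of a clustering
#'
#' @param assignment integer cluster ids (length n).
#' @param dist square distance matrix.
#' @return list with `widths` (per-sample silhouette) and `mean`.
#' @export
silhouette_widths <- function(assignment, dist) {
  d <- as.matrix(dist)
  if (length(unique(assignment)) < 2)
    return(list(widths = rep(NA_real_, length(assignment)), mean = NA_real_))
  sil <- cluster::silhouette(as.integer(assignment), stats::as.dist(d))
  list(widths = stats::setNames(sil[, "sil_width"], rownames(d)),
       mean = mean(sil[, "sil_width"]))
}
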