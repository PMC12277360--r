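#' Biophysical parameter integration
#'
#' Reduces a panel of repeated, site-specific skin measurements to six
#' representative metrics (oiliness, hydration, skin tone as ITA, elasticity
#' as R7, pore size, wrinkle roughness Ra), normalizes them onto a common
#' 0-10 cohort-relative scale, and merges them into the two composite criteria
#' (tone/elasticity and oil/moisture) used for cutotype assignment.
#'
#' @name biophys
NULL

#' Collapse replicate and site-specific measurements
#'
#' Arithmetic mean over replicates within each site, then over sites: e.g.
#' hydration and TEWL are measured in triplicate on forehead and cheek, and a
#' subject's overall value is the mean of the two site means; pore size is the
#' mean of the two cheeks. Columns are matched to a parameter/site scheme via
#' a schema table.
#'
#' @param raw data.frame of measurement columns, one row per subject.
#' @param schema data.frame with columns `column` (name in `raw`),
#'   `parameter` (collapsed output name) and `site` (site label; use one level
#'   for single-site parameters). Replicates are any columns sharing
#'   `parameter` + `site`.
#' @return data.frame of one column per `parameter`. A subject with no
#'   observed replicate for a parameter gets `NA` (flagged missing, never a
#'   silent zero).
#' @export
average_replicates <- function(raw, schema) {
  stopifnot(all(c("column", "parameter", "site") %in% names(schema)))
  missing_cols <- setdiff(schema$column, names(raw))
  if (length(missing_cols))
    stop("schema names absent from data: ", paste(missing_cols, collapse = ", "))
  out <- lapply(split(schema, schema$parameter), function(sc) {
    # mean within site over replicates, then across sites
    site_means <- lapply(split(sc$column, sc$site), function(cols) {
      rowMeans(as.matrix(raw[, cols, drop = FALSE]), na.rm = TRUE)
    })
    v <- rowMeans(matrix(unlist(site_means), nrow = nrow(raw)), na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  })
  as.data.frame(out, optional = TRUE)
}

#' Individual typology angle (ITA)
#'
#' Standard CIELAB skin-tone angle `atan((L* - 50) / b*) * 180 / pi` in
#' degrees. Higher values correspond to lighter skin. `a*` plays no role in
#' the accepted definition and is deliberately not an argument.
#'
#' @param L,b CIELAB lightness `L*` and yellowness `b*` (vectorized).
#' @return angle in degrees; when `b* = 0` the limit `+/-90` is returned by
#'   the sign of `L* - 50` (0 when both vanish).
#' @examples
#' compute_ita(65, 15) # 45
#' @export
compute_ita <- function(L, b) {
  out <- atan2(L - 50, b) * 180 / pi  # atan2 handles b = 0 limits
  # atan2 folds b < 0 beyond +/-90; standard ITA uses atan of the ratio
  neg <- !is.na(b) & b < 0
  out[neg] <- atan((L[neg] - 50) / b[neg]) * 180 / pi
  out
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations over numeric parameter columns.
#' Zero-variance columns yield `NA` entries (flagged, with a warning) rather
#' than failing.
#'
#' @param parameters numeric data.frame or matrix, subjects x parameters.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(parameters) {
  m <- as.matrix(parameters)
  if (nrow(m) < 3) stop("need at least 3 subjects")
  storage.mode(m) <- "double"
  suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs"))
  diag(r) <- 1
  if (anyNA(r)) warning("undefined correlations (zero-variance column?) flagged as NA")
  r
}

#' Pick one representative parameter per category
#'
#' Within each measurement category the representative is the member with the
#' largest mean absolute correlation to the other members of the same
#' category (ties broken lexicographically); singleton categories return their
#' only member. On the published elasticity correlations
#' (R7-R5 0.91, R7-R2 0.92, R2-R5 0.82) this rule selects R7.
#'
#' @param corr correlation matrix with dimnames.
#' @param category_map named character vector: parameter -> category.
#' @return named character vector: category -> selected parameter.
#' @export
select_representative <- function(corr, category_map) {
  stopifnot(!is.null(rownames(corr)))
  cats <- split(names(category_map), unname(category_map))
  vapply(cats, function(members) {
    members <- sort(intersect(members, rownames(corr)))
    if (length(members) == 0) stop("category with no parameters in matrix")
    if (length(members) == 1) return(members)
    score <- vapply(members, function(p) {
      r <- abs(corr[p, setdiff(members, p)])
      if (all(is.na(r))) stop("all correlations undefined for ", p)
      mean(r, na.rm = TRUE)
    }, numeric(1))
    members[which.max(score)]  # which.max keeps first = lexicographic tie-break
  }, character(1))
}

#' Normalize metrics to cohort-relative 0-10 scores
#'
#' Rank-based score `10 * (rank - 0.5) / n` with average ranks for ties, so
#' the cohort mean is always ~5 ("relative average") and the score is
#' invariant to monotone rescaling of the raw metric. Direction is preserved:
#' larger raw values score higher, including severity metrics (pores,
#' wrinkles). A constant metric scores 5 everywhere.
#'
#' @param panel data.frame of raw metric columns (subjects x metrics).
#' @return data.frame of the same shape with scores in [0, 10].
#' @export
normalize_metrics <- function(panel) {
  if (nrow(panel) < 2) stop("need at least 2 subjects for cohort-relative scores")
  out <- lapply(panel, function(v) {
    ok <- !is.na(v)
    s <- rep(NA_real_, length(v))
    s[ok] <- 10 * (rank(v[ok], ties.method = "average") - 0.5) / sum(ok)
    s
  })
  as.data.frame(out, optional = TRUE)
}

#' Composite tone/elasticity and oil/moisture criteria
#'
#' Unweighted means of the normalized member scores: tone/elasticity averages
#' the skin-tone (ITA) and elasticity (R7) scores; oil/moisture averages the
#' oiliness and hydration scores. A missing member propagates to a flagged
#' missing composite.
#'
#' @param scores data.frame of normalized scores containing columns `tone`,
#'   `elasticity`, `oiliness`, `hydration`.
#' @return data.frame with columns `tone_elasticity` and `oil_moisture`.
#' @export
composite_criteria <- function(scores) {
  need <- c("tone", "elasticity", "oiliness", "hydration")
  missing_cols <- setdiff(need, names(scores))
  if (length(missing_cols))
    stop("missing member scores: ", paste(missing_cols, collapse = ", "))
  data.frame(
    tone_elasticity = (scores$tone + scores$elasticity) / 2,
    oil_moisture = (scores$oiliness + scores$hydration) / 2)
}

#' Full measurement-to-metric-panel step
#'
#' Convenience wrapper: averages replicates per the schema, derives ITA from
#' the collapsed `L` and `b` parameters, normalizes the six metrics and
#' appends the composite criteria.
#'
#' @param raw measurement data.frame.
#' @param schema replicate schema, see [average_replicates()]; must collapse
#'   to parameters `hydration`, `sebum`, `L`, `b`, `R7`, `pore`, `Ra` (extra
#'   parameters are carried through unnormalized).
#' @return list with `raw_metrics` (six raw-scale metrics), `scores`
#'   (normalized 0-10) and `composites`.
#' @export
build_metric_panel <- function(raw, schema) {
  collapsed <- average_replicates(raw, schema)
  need <- c("hydration", "sebum", "L", "b", "R7", "pore", "Ra")
  missing_cols <- setdiff(need, names(collapsed))
  if (length(missing_cols))
    stop("schema must produce parameters: ", paste(missing_cols, collapse = ", "))
  raw_metrics <- data.frame(
    oiliness = collapsed$sebum,
    hydration = collapsed$hydration,
    tone = compute_ita(collapsed$L, collapsed$b),
    elasticity = collapsed$R7,
    pore = collapsed$pore,
    wrinkle = collapsed$Ra)
  scores <- normalize_metrics(raw_metrics)
  list(raw_metrics = raw_metrics, scores = scores,
       composites = composite_criteria(scores))
}
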