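#' Cutotype prediction from core-genus abundances
#'
#' One-vs-rest classification of the four cutotypes within each aging group
#' from the core-genus relative abundances, with a stratified 80/20 split,
#' SMOTE balancing of the training minority class, a pluggable
#' gradient-boosted tree model (default binding: xgboost), and micro/macro
#' ROC evaluation.
#'
#' @name typing_model
NULL

#' Synthetic minority oversampling (SMOTE)
#'
#' Each synthetic point is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)` and
#' `x_nn` one of the `k_neighbors` nearest minority neighbours (Euclidean).
#' `k_neighbors` is capped at size - 1; a single-sample minority falls back
#' to duplication with a warning.
#'
#' @param x minority-class feature matrix (rows = samples).
#' @param target_count desired minority size after oversampling.
#' @param k_neighbors neighbourhood size (default 5).
#' @param seed seed.
#' @return matrix of `target_count - nrow(x)` synthetic rows (0 rows if the
#'   class is already large enough).
#' @export
smote <- function(x, target_count, k_neighbors = 5, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  n_new <- target_count - n
  if (n_new <= 0) return(x[0, , drop = FALSE])
  set.seed(seed)
  if (n == 1) {
    warning("single-sample minority class: duplicating")
    return(x[rep(1, n_new), , drop = FALSE])
  }
  k <- min(k_neighbors, n - 1)
  d <- as.matrix(stats::dist(x))
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) nn[i, ] <- order(d[i, ])[2:(k + 1)]
  base <- sample(n, n_new, replace = TRUE)
  pick <- nn[cbind(base, sample(k, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  x[base, , drop = FALSE] + u * (x[pick, , drop = FALSE] - x[base, , drop = FALSE])
}

#' Stratified train/test split
#'
#' Per-class split preserving class ratios within one sample.
#'
#' @param y class labels.
#' @param split_fraction training fraction (default 0.8).
#' @param seed seed.
#' @return logical vector, TRUE = training row.
#' @export
stratified_split <- function(y, split_fraction = 0.8, seed = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  set.seed(seed)
  train <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_train <- round(split_fraction * length(idx))
    n_train <- max(min(n_train, length(idx) - 1), 1)
    train[sample(idx, n_train)] <- TRUE
  }
  train
}

#' Gradient-boosted tree model contract
#'
#' The classifier is pluggable: any list with `fit(x, y)` returning an
#' object usable by `predict_proba(model, x)` and `importance(model)`
#' satisfies the contract. The default binding wraps xgboost (binary
#' logistic or multiclass softprob).
#'
#' @param nrounds boosting rounds (default 150).
#' @param params list of booster parameters (default: depth 3, eta 0.1,
#'   subsample 0.8).
#' @param nthread threads (default 1, for reproducibility).
#' @return the contract list; `$label` records the binding for run metadata.
#' @export
boost_model_spec <- function(nrounds = 150,
                             params = list(max_depth = 3, eta = 0.1,
                                           subsample = 0.8),
                             nthread = 1) {
  list(
    label = sprintf("xgboost(nrounds=%d,depth=%s,eta=%s)", nrounds,
                    params$max_depth, params$eta),
    params = params,
    nrounds = nrounds,
    fit = function(x, y, seed = 1L) {
      classes <- sort(unique(y))
      multi <- length(classes) > 2
      yy <- match(y, classes) - 1L
      set.seed(seed)
      p <- c(params, nthread = nthread, seed = seed,
             if (multi) list(objective = "multi:softprob",
                             num_class = length(classes))
             else list(objective = "binary:logistic"))
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = yy)
      booster <- xgboost::xgb.train(params = p, data = dtrain,
                                    nrounds = nrounds, verbose = 0)
      list(booster = booster, classes = classes, multi = multi,
           features = colnames(x))
    },
    predict_proba = function(model, x) {
      pr <- stats::predict(model$booster, xgboost::xgb.DMatrix(as.matrix(x)))
      if (model$multi) {
        out <- if (is.matrix(pr)) pr
               else matrix(pr, ncol = length(model$classes), byrow = TRUE)
        dimnames(out) <- list(NULL, model$classes)
        out
      } else {
        out <- cbind(1 - pr, pr)
        colnames(out) <- as.character(model$classes)
        out
      }
    },
    importance = function(model) {
      imp <- xgboost::xgb.importance(model = model$booster)
      out <- stats::setNames(rep(0, length(model$features)), model$features)
      out[imp$Feature] <- imp$Gain
      out
    })
}

#' ROC curve and AUC by the rank statistic
#'
#' AUC equals the Mann-Whitney U statistic scaled by `n_pos * n_neg`, which
#' gives ties half credit.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1, logical, or two-level factor where the
#'   second sorted level is positive).
#' @return list with `auc` and `curve` (data.frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.logical(labels)) as.integer(labels)
       else if (is.numeric(labels)) as.integer(labels)
       else as.integer(factor(labels)) - 1L
  if (length(unique(y)) < 2) stop("both classes must be present")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord] == 1) / n_pos)
  fpr <- c(0, cumsum(y[ord] == 0) / n_neg)
  list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr))
}

#' Micro- and macro-averaged multiclass AUC
#'
#' @param class_scores list per class of `list(scores =, labels =)`
#'   one-vs-rest pairs.
#' @return list with `per_class` (named AUCs), `micro` (pooled pairs) and
#'   `macro` (unweighted mean of per-class AUCs).
#' @export
micro_macro <- function(class_scores) {
  per_class <- vapply(class_scores,
                      function(cs) roc_auc(cs$scores, cs$labels)$auc,
                      numeric(1))
  pooled_scores <- unlist(lapply(class_scores, `[[`, "scores"))
  pooled_labels <- unlist(lapply(class_scores, function(cs) as.integer(cs$labels)))
  list(per_class = per_class,
       micro = roc_auc(pooled_scores, pooled_labels)$auc,
       macro = mean(per_class))
}

#' Train one-vs-rest cutotype models per aging group
#'
#' Within each aging group, each cutotype with at least `min_positives`
#' samples gets a binary model: stratified 80/20 split, SMOTE balancing of
#' the training positives up to the training negatives, fit with the boost
#' contract, held-out ROC evaluation.
#'
#' @param features samples x genera abundance matrix (rows named by sample).
#' @param strata 12-level strata labels (`yHH` ... `oLL`) per sample.
#' @param model boost contract from [boost_model_spec()].
#' @param split_fraction training fraction (default 0.8).
#' @param min_positives minimum positives to train a type model (default 5).
#' @param seed seed.
#' @return list per aging group with per-type entries (`model`, `auc`,
#'   `scores`, `labels`, `importance`) plus `micro`/`macro` per group.
#' @export
train_type_models <- function(features, strata, model = boost_model_spec(),
                              split_fraction = 0.8, min_positives = 5,
                              seed = 1L) {
  x <- as.matrix(features)
  strata <- as.character(strata)
  stopifnot(length(strata) == nrow(x))
  group <- c(y = "Young", a = "AgingI", o = "Old")[substr(strata, 1, 1)]
  type <- substring(strata, 2)
  out <- list()
  for (g in unique(group)) {
    rows <- which(group == g)
    types_here <- unique(type[rows])
    if (length(types_here) < 2) {
      warning("aging group ", g, " has < 2 types; skipped")
      next
    }
    group_res <- list()
    for (tp in sort(types_here)) {
      y <- as.integer(type[rows] == tp)
      if (sum(y) < min_positives) {
        warning("type ", tp, " in group ", g, " has < ", min_positives,
                " samples; skipped")
        next
      }
      sseed <- seed + 131L * match(g, c("Young", "AgingI", "Old")) +
        match(tp, c("HH", "HL", "LH", "LL"))
      train <- stratified_split(y, split_fraction, seed = sseed)
      xtr <- x[rows[train], , drop = FALSE]; ytr <- y[train]
      n_min <- sum(ytr == 1); n_maj <- sum(ytr == 0)
      if (n_min < n_maj && n_min >= 1) {
        syn <- smote(xtr[ytr == 1, , drop = FALSE], target_count = n_maj,
                     seed = sseed)
        if (nrow(syn)) {
          xtr <- rbind(xtr, syn)
          ytr <- c(ytr, rep(1L, nrow(syn)))
        }
      }
      fit <- model$fit(xtr, ytr, seed = sseed)
      prob <- model$predict_proba(fit, x[rows[!train], , drop = FALSE])[, "1"]
      ytest <- y[!train]
      auc <- if (length(unique(ytest)) == 2) roc_auc(prob, ytest)$auc else NA_real_
      group_res[[tp]] <- list(model = fit, auc = auc, scores = prob,
                              labels = ytest,
                              importance = model$importance(fit))
    }
    evaluable <- Filter(function(r) !is.na(r$auc), group_res)
    mm <- if (length(evaluable) >= 1)
      micro_macro(lapply(evaluable, function(r)
        list(scores = r$scores, labels = r$labels))) else NULL
    out[[g]] <- c(group_res, list(.summary = mm))
  }
  attr(out, "model_label") <- model$label
  out
}

#' z-scored feature-importance matrix across models
#'
#' @param models nested result of [train_type_models()] (or any list of
#'   entries with an `importance` vector).
#' @return genera x model matrix of importances z-scored within each genus
#'   row (constant rows become 0).
#' @export
feature_importance_heatmap <- function(models) {
  flat <- list()
  for (g in names(models)) for (tp in setdiff(names(models[[g]]), ".summary"))
    flat[[paste0(substr(tolower(g), 1, 1), tp)]] <- models[[g]][[tp]]$importance
  if (length(flat) < 2) stop("need at least 2 models")
  m <- do.call(cbind, flat)
  colnames(m) <- names(flat)
  z <- t(apply(m, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  colnames(z) <- names(flat)
  z
}

#' Multiclass aging/decade prediction from a metric panel
#'
#' Stratified 80/20 split, multiclass boosted model, per-class one-vs-rest
#' AUC plus micro and macro averages on the held-out set.
#'
#' @param features samples x metrics matrix.
#' @param classes class label per sample (e.g. decade or aging group).
#' @param model boost contract.
#' @param split_fraction training fraction (default 0.8).
#' @param seed seed.
#' @return list with `per_class`, `micro`, `macro`, `importance`.
#' @export
evaluate_age_model <- function(features, classes, model = boost_model_spec(),
                               split_fraction = 0.8, seed = 1L) {
  x <- as.matrix(features)
  classes <- as.character(classes)
  stopifnot(length(classes) == nrow(x))
  if (length(unique(classes)) < 2) stop("need at least 2 classes")
  train <- stratified_split(classes, split_fraction, seed = seed)
  fit <- model$fit(x[train, , drop = FALSE], classes[train], seed = seed)
  prob <- model$predict_proba(fit, x[!train, , drop = FALSE])
  ytest <- classes[!train]
  cs <- lapply(fit$classes, function(cl)
    list(scores = prob[, cl], labels = as.integer(ytest == cl)))
  names(cs) <- fit$classes
  ok <- vapply(cs, function(e) length(unique(e$labels)) == 2, logical(1))
  mm <- micro_macro(cs[ok])
  c(mm, list(importance = model$importance(fit)))
}
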