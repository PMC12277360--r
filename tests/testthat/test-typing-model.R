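test_that("SMOTE interpolates strictly within the minority geometry", {
  two <- rbind(c(0, 0), c(1, 2))
  syn <- smote(two, target_count = 12, seed = 1)
  expect_equal(nrow(syn), 10)
  # points lie on the segment between the two parents
  expect_equal(syn[, 2], 2 * syn[, 1], tolerance = 1e-12)
  expect_true(all(syn[, 1] >= 0 & syn[, 1] <= 1))
  none <- smote(two, target_count = 2, seed = 1)
  expect_equal(nrow(none), 0)
  expect_warning(syn1 <- smote(rbind(c(3, 4)), 4, seed = 1), "duplicating")
  expect_equal(unique(as.vector(syn1[, 1])), 3)
})

test_that("SMOTE respects the per-feature minority bounding box", {
  set.seed(9)
  x <- matrix(rnorm(40), 20, 2)
  syn <- smote(x, target_count = 100, k_neighbors = 5, seed = 2)
  for (j in 1:2) {
    expect_gte(min(syn[, j]), min(x[, j]))
    expect_lte(max(syn[, j]), max(x[, j]))
  }
  # interpolation on 2-D toy data stays in the convex hull: each synthetic
  # point is on a segment between two sample points, so inside by convexity
  hull <- grDevices::chull(x)
  inside <- vapply(seq_len(nrow(syn)), function(i) {
    p <- syn[i, ]
    # point-in-polygon by winding of hull edges
    poly <- x[c(hull, hull[1]), ]
    s <- sign((poly[-1, 1] - poly[-nrow(poly), 1]) * (p[2] - poly[-nrow(poly), 2]) -
              (poly[-1, 2] - poly[-nrow(poly), 2]) * (p[1] - poly[-nrow(poly), 1]))
    all(s >= 0) || all(s <= 0)
  }, logical(1))
  expect_true(all(inside))
})

test_that("stratified splits preserve class ratios within one sample", {
  set.seed(4)
  y <- sample(c("a", "b", "c"), 97, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  tr <- stratified_split(y, 0.8, seed = 1)
  for (cl in unique(y)) {
    expect_lte(abs(sum(tr[y == cl]) - 0.8 * sum(y == cl)), 1)
    expect_gte(sum(!tr[y == cl]), 1)
  }
})

test_that("AUC equals the brute-force pairwise statistic", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4))$auc, 0.5)
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, auc_brute_force(scores, labels))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC matches pROC on a continuous example", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- rnorm(60)
  labels <- as.integer(scores + rnorm(60) > 0)
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores)))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("micro and macro averages follow their definitions", {
  cs <- list(a = list(scores = c(0.9, 0.1, 0.8, 0.2), labels = c(1, 0, 1, 0)),
             b = list(scores = c(0.4, 0.6, 0.3, 0.7), labels = c(1, 1, 0, 0)))
  mm <- micro_macro(cs)
  expect_equal(mm$macro, mean(mm$per_class))
  pooled <- roc_auc(c(cs$a$scores, cs$b$scores), c(cs$a$labels, cs$b$labels))
  expect_equal(mm$micro, pooled$auc)
})

test_that("a perfectly separating feature yields AUC 1 through the contract", {
  x <- cbind(f = c(rep(0, 10), rep(10, 10)), noise = rnorm(20))
  y <- c(rep(0L, 10), rep(1L, 10))
  spec <- boost_model_spec(nrounds = 20)
  fit <- spec$fit(x, y, seed = 1)
  pr <- spec$predict_proba(fit, x)[, "1"]
  expect_equal(roc_auc(pr, y)$auc, 1)
})

test_that("type models recover a planted genus-type signal", {
  co <- simulate_cohort(cohort_config(n_subjects = 240, seed = 31))
  rel <- relative_abundance(co$counts)[, co$truth$core_genera]
  # strata driven by the community truth itself: a perfect planted signal
  sub <- co$truth$subcluster[rownames(rel)]
  type <- c(`DC1-sub1` = "HH", `DC1-sub2` = "HL", DC2 = "LH")[sub]
  strata <- paste0("y", type)
  mods <- suppressWarnings(train_type_models(rel, strata, seed = 2))
  aucs <- vapply(setdiff(names(mods$Young), ".summary"),
                 function(tp) mods$Young[[tp]]$auc, numeric(1))
  expect_true(all(aucs > 0.9))
})

test_that("shuffled labels give chance-level held-out AUC", {
  co <- simulate_cohort(cohort_config(n_subjects = 240, seed = 32))
  rel <- relative_abundance(co$counts)[, co$truth$core_genera]
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    strata <- paste0("y", sample(rep(c("HH", "HL", "LH", "LL"), 60)))
    mods <- suppressWarnings(train_type_models(rel, strata, seed = s))
    mods$Young$.summary$micro
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("importance heatmap is z-scored by genus with planted maxima", {
  co <- simulate_cohort(cohort_config(n_subjects = 240, seed = 33))
  rel <- relative_abundance(co$counts)[, co$truth$core_genera]
  sub <- co$truth$subcluster[rownames(rel)]
  type <- c(`DC1-sub1` = "HH", `DC1-sub2` = "HL", DC2 = "LH")[sub]
  mods <- suppressWarnings(train_type_models(rel, paste0("y", type), seed = 3))
  hm <- feature_importance_heatmap(mods)
  nontrivial <- apply(hm, 1, function(v) any(v != 0))
  expect_equal(unname(rowMeans(hm[nontrivial, ])), rep(0, sum(nontrivial)),
               tolerance = 1e-12)
  expect_equal(unname(apply(hm[nontrivial, ], 1, sd)),
               rep(1, sum(nontrivial)), tolerance = 1e-12)
  # Cutibacterium discriminates the Cutibacterium-dominant type
  expect_equal(unname(which.max(hm["Cutibacterium", ])),
               unname(which(colnames(hm) == "yLH")))
})

test_that("age-group models exploit planted age signal and not noise", {
  co <- simulate_cohort(cohort_config(n_subjects = 500, seed = 34))
  panel <- build_metric_panel(co$measurements[, -1], co$schema)
  keep <- !is.na(panel$raw_metrics$wrinkle)
  x <- as.matrix(panel$raw_metrics[keep, ])
  groups <- assign_aging_group(co$subjects$age[keep], 35, 51)
  em <- evaluate_age_model(x, groups, seed = 1)
  expect_gt(em$micro, 0.8)
  set.seed(9)
  em_null <- evaluate_age_model(x, sample(groups), seed = 1)
  expect_lt(abs(em_null$micro - 0.5), 0.2)
  # a feature subset cannot beat the full panel by more than noise
  em_sub <- evaluate_age_model(x[, c("tone", "elasticity")], groups, seed = 1)
  expect_lte(em_sub$micro, em$micro + 0.05)
})
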