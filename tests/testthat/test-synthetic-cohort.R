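test_that("a fixed seed reproduces the cohort exactly", {
  a <- simulate_cohort(cohort_config(n_subjects = 10, seed = 1))
  b <- simulate_cohort(cohort_config(n_subjects = 10, seed = 1))
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$counts, b$counts)
  expect_identical(a$tree_newick, b$tree_newick)
  c2 <- simulate_cohort(cohort_config(n_subjects = 10, seed = 2))
  expect_false(identical(a$counts, c2$counts))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(n_genera = 16), ">= 17")
  expect_error(cohort_config(n_genera = 20), "smaller than the 30")
  bad <- default_genus_profiles()
  bad$profiles[1, 1] <- bad$profiles[1, 1] + 0.01
  expect_error(cohort_config(cluster_profiles = bad), "sum to 1")
  prof <- default_genus_profiles()$profiles
  expect_equal(unname(colSums(prof)), rep(1, 3), tolerance = 1e-9)
})

test_that("each planted cluster's dominant genus matches its profile argmax", {
  co <- simulate_cohort(cohort_config(n_subjects = 200, seed = 4))
  rel <- relative_abundance(co$counts)
  prof <- co$config$cluster_profiles$profiles
  for (sc in colnames(prof)) {
    members <- names(co$truth$subcluster)[co$truth$subcluster == sc]
    group_mean <- colMeans(rel[members, , drop = FALSE])
    expect_equal(names(which.max(group_mean)),
                 rownames(prof)[which.max(prof[, sc])])
  }
})

test_that("degenerate nesting collapses subcluster truth onto cluster truth", {
  co <- simulate_cohort(cohort_config(n_subjects = 40, seed = 2,
                                      subcluster_split = "none"))
  expect_identical(unname(co$truth$subcluster), unname(co$truth$cluster))
})

test_that("age-trend structure matches the generator contract", {
  co <- simulate_cohort(cohort_config(n_subjects = 4000, seed = 8))
  panel <- build_metric_panel(co$measurements[, -1], co$schema)
  dec <- pmin(co$subjects$age %/% 10, 8)
  tone_med <- tapply(panel$raw_metrics$tone, dec, median)
  elast_med <- tapply(panel$raw_metrics$elasticity, dec, median)
  expect_true(all(diff(tone_med) < 0))
  expect_true(all(diff(elast_med) < 0))
  oil_med <- tapply(panel$raw_metrics$oiliness, dec, median)
  expect_equal(unname(which.max(oil_med)), 4)  # peak in the 30s decade
  expect_true(oil_med[length(oil_med)] < oil_med[4])
  hyd_rng <- range(tapply(panel$raw_metrics$hydration, dec, median))
  expect_lt(diff(hyd_rng), 5)  # moisture essentially age-flat
})

test_that("relative abundances are proper compositions with planted separation", {
  co <- simulate_cohort(cohort_config(n_subjects = 120, seed = 3))
  rel <- relative_abundance(co$counts)
  expect_equal(unname(rowSums(rel)), rep(1, 120), tolerance = 1e-9)
  d <- bray_curtis(co$counts)
  cl <- co$truth$cluster[rownames(d)]
  same <- outer(cl, cl, "==")
  off <- upper.tri(d)
  expect_gt(mean(d[off & !same]), mean(d[off & same]))
})

test_that("questionnaire simulation respects missingness and coupling", {
  co <- simulate_cohort(cohort_config(n_subjects = 400, seed = 10))
  r0 <- simulate_responses(co, missing_rate = 0, seed = 1)
  items <- as.matrix(r0[, sprintf("q%02d", 1:59)])
  expect_false(anyNA(items))
  expect_true(all(items %in% 1:4))
  r5 <- simulate_responses(co, missing_rate = 0.5, seed = 1)
  frac <- mean(is.na(as.matrix(r5[, sprintf("q%02d", 1:59)])))
  expect_equal(frac, 0.5, tolerance = 0.05)
  expect_error(simulate_responses(co, missing_rate = 1), "missing_rate")
  # oiliness items track the sebum metric: top vs bottom decile
  sebum <- co$measurements$sebum
  omean <- rowMeans(as.matrix(r0[, sprintf("q%02d", 1:11)]))
  top <- sebum >= quantile(sebum, 0.9)
  bot <- sebum <= quantile(sebum, 0.1)
  expect_gt(mean(omean[top]), mean(omean[bot]))
  cmap <- attr(r0, "category_map")
  expect_equal(unname(table(cmap$category)[c("O", "S", "P", "W")]),
               c(11L, 18L, 10L, 20L), ignore_attr = TRUE)
})

test_that("crossover planting validates input and keeps books", {
  co <- simulate_cohort(cohort_config(n_subjects = 50, seed = 2))
  expect_error(plant_crossover(co, "sparkle", 35), "unknown criterion")
  expect_error(plant_crossover(co, "tone_elasticity", 200), "outside")
  co <- plant_crossover(co, "tone_elasticity", 35)
  co <- plant_crossover(co, "oil_moisture", 51)
  expect_equal(co$truth$planted_crossover$tone_elasticity, 35)
  expect_equal(co$truth$planted_crossover$oil_moisture, 51)
})

test_that("cohorts round-trip through the plain-text writers", {
  co <- simulate_cohort(cohort_config(n_subjects = 15, seed = 13))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  tab <- read_feature_table(paths[["counts"]])
  expect_identical(tab, co$counts)
  tree <- ape::read.tree(paths[["tree"]])
  expect_setequal(tree$tip.label, colnames(co$counts))
})
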