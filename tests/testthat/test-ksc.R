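test_that("tertile bands match a brute-force sort-and-cut oracle", {
  set.seed(21)
  for (n in c(3, 7, 9, 12, 23, 30)) {
    x <- sample(seq_len(n * 2), n)  # distinct and tied regimes below
    expect_identical(tertile_band(x), tertile_oracle(x))
    y <- sample(1:4, n, replace = TRUE)
    expect_identical(tertile_band(y), tertile_oracle(y))
  }
  expect_error(tertile_band(1:2), "at least 3")
})

test_that("strict typing uses both tertiles with a gray middle", {
  comp <- data.frame(tone_elasticity = 1:9, oil_moisture = 1:9)
  strict <- assign_type_strict(comp)
  expect_equal(strict, c(rep("LL", 3), rep("GRAY", 3), rep("HH", 3)))
  mixed <- data.frame(tone_elasticity = c(9, 9, 9, 1, 1, 1, 5, 5, 5),
                      oil_moisture = 1:9)
  s2 <- assign_type_strict(mixed)
  expect_equal(s2[1], "HL")  # top tone tertile, bottom oil tertile
  expect_equal(s2[7], "GRAY")
})

test_that("gray-zone subjects fall to the above-mean rule, at-mean is L", {
  comp <- data.frame(tone_elasticity = c(1, 2, 3, 4, 10, 10, 5, 5, 5),
                     oil_moisture = c(1, 2, 3, 4, 10, 10, 5, 5, 5))
  strict <- assign_type_strict(comp)
  final <- reassign_gray(strict, comp)
  expect_true(all(final != "GRAY"))
  expect_identical(final[strict != "GRAY"], strict[strict != "GRAY"])
  # mean is exactly 5: the gray at-mean subjects must go L
  expect_equal(mean(comp$tone_elasticity), 5)
  expect_true(all(final[comp$tone_elasticity == 5] %in% c("LL", "LH")))
})

test_that("proportion curves tabulate tertile bands per age", {
  # 5 subjects at one age: 4 upper, 1 lower, 0 middle (cohort-wide bands)
  comp <- c(10, 9, 8, 7, 1, rep(c(2, 3, 4, 5, 6), 3))
  ages <- c(rep(30, 5), rep(40, 15))
  cur <- proportion_curves(comp, ages, window = 1)
  row30 <- cur[cur$age == 30, ]
  expect_equal(row30$upper, 0.8)
  expect_equal(row30$lower, 0.2)
  expect_equal(row30$middle, 0)
  expect_equal(cur$upper_s, cur$upper)  # window 1 is the identity
})

test_that("smoothing is a centered moving average over observed ages", {
  comp <- c(rep(10, 6), rep(1, 6), rep(5, 6))
  ages <- rep(c(20, 21, 22), each = 6)[order(rep(1:6, 3))]
  ages <- c(rep(20, 6), rep(21, 6), rep(22, 6))
  cur <- proportion_curves(comp, ages, window = 3)
  expect_equal(cur$upper, c(1, 0, 0))
  expect_equal(cur$upper_s, c(0.5, 1 / 3, 0))
})

test_that("crossover detection finds planted reversals and nothing else", {
  co <- simulate_cohort(cohort_config(n_subjects = 2000, seed = 5))
  co <- plant_crossover(co, "tone_elasticity", 35)
  panel <- build_metric_panel(co$measurements[, -1], co$schema)
  cur <- proportion_curves(panel$composites$tone_elasticity,
                           co$subjects$age, window = 3)
  expect_equal(detect_crossovers(cur), 35)
  # all-upper curves never cross
  flat <- data.frame(age = 1:10, upper_s = rep(1, 10), lower_s = rep(0, 10))
  expect_length(detect_crossovers(flat), 0)
})

test_that("a crossover planted at the range floor leaves lower on top everywhere", {
  co <- simulate_cohort(cohort_config(n_subjects = 3000, seed = 6))
  co <- plant_crossover(co, "tone_elasticity", 0)
  panel <- build_metric_panel(co$measurements[, -1], co$schema)
  cur <- proportion_curves(panel$composites$tone_elasticity,
                           co$subjects$age, window = 3)
  # everyone draws from the low regime: no era where the upper band
  # systematically dominates the lower band
  expect_lt(abs(mean(cur$lower_s) - mean(cur$upper_s)), 0.15)
  expect_lt(max(cur$upper_s - cur$lower_s), 0.4)
})

test_that("planted crossovers are recovered across seeds (modal age)", {
  detected <- vapply(1:8, function(s) {
    co <- simulate_cohort(cohort_config(n_subjects = 2000, seed = s))
    co <- plant_crossover(co, "tone_elasticity", 35)
    panel <- build_metric_panel(co$measurements[, -1], co$schema)
    cur <- proportion_curves(panel$composites$tone_elasticity,
                             co$subjects$age, window = 3)
    hits <- detect_crossovers(cur)
    if (length(hits)) hits[1] else NA_integer_
  }, numeric(1))
  tab <- table(detected)
  expect_equal(as.integer(names(tab)[which.max(tab)]), 35)
})

test_that("cutpoint selection honours the oil-peak rule", {
  expect_equal(select_cutpoints(35, c(14, 51), 30), c(c1 = 35, c2 = 51))
  expect_equal(select_cutpoints(c(35, 60), 51, 30), c(c1 = 35, c2 = 51))
  expect_error(select_cutpoints(35, 14, 30), "after the oil peak")
  expect_error(select_cutpoints(integer(0), 51, 30), "no tone")
  expect_error(select_cutpoints(55, c(14, 51), 30), "not after")
})

test_that("aging groups split at the published boundaries", {
  expect_equal(assign_aging_group(34, 35, 51), "Young")
  expect_equal(assign_aging_group(35, 35, 51), "AgingI")
  expect_equal(assign_aging_group(50, 35, 51), "AgingI")
  expect_equal(assign_aging_group(51, 35, 51), "Old")
  expect_equal(stratify("LL", "Old"), "oLL")
  expect_error(assign_aging_group(-1, 35, 51), "negative")
})

test_that("every subject lands in exactly one of 12 strata", {
  co <- simulate_cohort(cohort_config(n_subjects = 400, seed = 12))
  panel <- build_metric_panel(co$measurements[, -1], co$schema)
  lab <- assign_ksc(panel$composites, co$subjects$age, c1 = 35, c2 = 51)
  expect_equal(nrow(lab), 400)
  expect_true(all(lab$strata %in%
    paste0(rep(c("y", "a", "o"), each = 4), c("HH", "HL", "LH", "LL"))))
  expect_equal(sum(table(lab$strata)), 400)
  expect_true(all(lab$final_type != "GRAY"))
  expect_equal(substr(lab$strata, 2, 3), lab$final_type)
})
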