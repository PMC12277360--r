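test_that("Kruskal-Wallis matches hand computation and is label-symmetric", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$H, 3.857, tolerance = 1e-3)
  r2 <- kruskal_wallis(list(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(r$H, r2$H)
  ref <- stats::kruskal.test(list(c(1, 3, 9), c(1, 3, 9), c(2, 5)))
  ours <- kruskal_wallis(list(c(1, 3, 9), c(1, 3, 9), c(2, 5)))
  expect_equal(ours$H, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  tied <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(tied$p, 1)
  expect_error(kruskal_wallis(list(1:3)), "groups")
})

test_that("prevalence threshold is an exact edge and core is nested", {
  # one genus present in 49 of 100 samples, one in 50, one everywhere
  m <- cbind(g49 = c(rep(1, 49), rep(0, 51)),
             g50 = c(rep(1, 50), rep(0, 50)),
             gAll = rep(5, 100))
  rownames(m) <- paste0("S", 1:100)
  labels <- rep(c("a", "b"), 50)
  rep1 <- core_genus_selection(m, labels)
  expect_setequal(rep1$prevalent, c("g50", "gAll"))
  expect_true(all(rep1$core %in% rep1$prevalent))
})

test_that("identical subcluster distributions give an empty core", {
  set.seed(3)
  m <- matrix(rpois(300, 30), 30, 10,
              dimnames = list(paste0("S", 1:30), paste0("g", 1:10)))
  labels <- rep(c("a", "b", "c"), 10)
  rep1 <- core_genus_selection(m, labels, alpha = 1e-6)
  expect_length(rep1$core, 0)
  expect_error(core_genus_selection(m, rep("a", 30)), "at least 2")
})

test_that("tightening alpha never grows the core set", {
  co <- simulate_cohort(cohort_config(n_subjects = 120, seed = 17))
  labels <- co$truth$subcluster
  loose <- core_genus_selection(co$counts, labels, alpha = 0.05)
  tight <- core_genus_selection(co$counts, labels, alpha = 0.001)
  expect_true(all(tight$core %in% loose$core))
  expect_true(all(loose$core %in% loose$prevalent))
})

test_that("cumulative-abundance mode takes the top genera to the mass threshold", {
  m <- cbind(big = rep(70L, 10), mid = rep(25L, 10), small = rep(5L, 10))
  rownames(m) <- paste0("S", 1:10)
  rep1 <- core_genus_selection(m, rep(c("a", "b"), 5),
                               mode = "cumulative-abundance",
                               prevalence_threshold = 0.5)
  expect_equal(rep1$prevalent, "big")
  rep2 <- core_genus_selection(m, rep(c("a", "b"), 5),
                               mode = "cumulative-abundance",
                               prevalence_threshold = 0.9)
  expect_equal(rep2$prevalent, c("big", "mid"))
})

test_that("PERMANOVA separates planted groups and is relabeling-invariant", {
  blob <- blob_distance(15, rbind(c(0, 0), c(8, 8)), seed = 2)
  r <- permanova(blob$d, blob$labels, n_perm = 999, seed = 1)
  expect_equal(r$p, 0.001)
  expect_gt(r$pseudo_F, 10)
  # permuting the sample order leaves the observed statistic unchanged
  perm <- sample(nrow(blob$d))
  r2 <- permanova(blob$d[perm, perm], blob$labels[perm], n_perm = 99, seed = 1)
  expect_equal(r2$pseudo_F, r$pseudo_F, tolerance = 1e-9)
  expect_warning(
    permanova(blob$d, c(rep("a", 29), "b"), n_perm = 99, seed = 1),
    "singleton")
})

test_that("PERMANOVA holds its type-I error under the null", {
  rejections <- vapply(1:40, function(seed) {
    set.seed(seed)
    pts <- matrix(rnorm(60), 30, 2)
    d <- as.matrix(dist(pts))
    labels <- sample(rep(c("a", "b"), 15))
    permanova(d, labels, n_perm = 199, seed = seed)$p < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.1)
})

test_that("LDA effect sizes flag planted enrichment and screen out null features", {
  set.seed(6)
  n <- 120
  # fixed per-sample total so only the planted swap moves relative abundances
  m <- matrix(rep(c(125L, 125L, 0L, 125L, 125L, 500L), each = n), n, 6,
              dimnames = list(paste0("S", 1:n), paste0("g", 1:6)))
  noise <- matrix(rpois(n * 6, 5), n, 6)
  classes <- rep(c("young", "old"), each = n / 2)
  m[classes == "young", 3] <- 5L    # g3 rare in young...
  m[classes == "old", 3] <- 495L    # ...~100-fold enriched in old
  m[classes == "old", 6] <- 10L     # filler genus absorbs the swap
  m <- m + noise
  res <- lda_effect_size(m, classes, seed = 1)
  expect_true("g3" %in% res$feature)
  expect_equal(res$class[res$feature == "g3"], "old")
  expect_gte(res$score[res$feature == "g3"], 2)
  # identical-across-classes feature never reported
  expect_false("g1" %in% res$feature)
  # swapping labels preserves scores and flips enrichment
  swapped <- lda_effect_size(m, ifelse(classes == "old", "young", "old"),
                             seed = 1)
  expect_equal(swapped$class[swapped$feature == "g3"], "young")
  expect_equal(swapped$score[swapped$feature == "g3"],
               res$score[res$feature == "g3"], tolerance = 1e-9)
})

test_that("pairwise differential abundance is calibrated and antisymmetric", {
  set.seed(8)
  n <- 60
  m <- matrix(rpois(n * 5, 40), n, 5,
              dimnames = list(paste0("S", 1:n), paste0("g", 1:5)))
  strata <- rep(c("yHH", "yLL", "oHH"), each = n / 3)
  null_rep <- pairwise_differential(m, strata)
  expect_false(any(null_rep$significant))
  m2 <- m
  m2[strata == "oHH", "g2"] <- rpois(n / 3, 400)  # strong planted shift
  rep2 <- pairwise_differential(m2, strata)
  hit <- rep2[rep2$genus == "g2" & rep2$group1 == "oHH" &
                rep2$group2 == "yHH", ]
  expect_true(hit$significant)
  expect_gt(hit$entry, 1)
  mat <- pairwise_matrix(rep2, "g2")
  expect_equal(mat, -t(mat))
})

test_that("pathway filtering applies the 0.5% floor, dedupe and z-scoring", {
  m <- rbind(p1 = rep(0.004, 4), p2 = rep(0.02, 4), p1 = rep(0.9, 4),
             p3 = c(0.1, 0.2, 0.3, 0.4))
  out <- filter_pathway_table(m)
  expect_setequal(rownames(out), c("p2", "p3"))  # p1 duplicate kept first, then floored
  z <- filter_pathway_table(m, zscore = TRUE)
  expect_equal(unname(z["p2", ]), rep(0, 4))     # constant row
  expect_equal(mean(z["p3", ]), 0, tolerance = 1e-12)
  expect_equal(sd(z["p3", ]), 1, tolerance = 1e-12)
})
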