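#' Synthetic cohort generation
#'
#' Generates cohorts with the statistical structure the downstream analysis
#' assumes, so every stage can be exercised and validated without
#' controlled-access subject data: age-dependent declines in skin tone and
#' elasticity, a sebum path peaking in the late 20s/30s then declining,
#' age-flat moisture, replicate/site measurement structure, a 59+1 item
#' questionnaire coupled to the biophysical traits, and a genus-level
#' microbial community drawn Dirichlet-multinomial from planted
#' (sub)cluster profiles with a known prevalent/core genus structure.
#'
#' @name synthetic_cohort
NULL

# draw one Dirichlet vector via independent gammas
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Default planted genus profiles
#'
#' Thirty genera and three community profiles: two nested subprofiles of a
#' Streptococcus-dominant top cluster (one Staphylococcus/Neisseria-enriched,
#' one Rothia/Corynebacterium-enriched) and a Cutibacterium-dominant top
#' cluster. Seventeen genera carry enough probability mass in every profile
#' to exceed 50% detection prevalence at the default rarefaction depth; 15 of
#' those differ between profiles (the planted core set) and two
#' (Veillonella, Granulicatella) are exactly homogeneous across profiles.
#' The remaining 13 genera are rare (2e-4 each) and stay below 50%
#' prevalence.
#'
#' @return list with `profiles` (genus x profile probability matrix, columns
#'   `DC1-sub1`, `DC1-sub2`, `DC2`), `top_cluster` (per-profile top-level
#'   cluster), `weights` (profile mixing weights), `prevalent` and `core`
#'   (planted genus name sets).
#' @export
default_genus_profiles <- function() {
  fixed <- rbind(
    # genus                sub1   sub2    DC2
    Cutibacterium   = c(0.060, 0.060,     NA),
    Streptococcus   = c(   NA,    NA,  0.080),
    Staphylococcus  = c(0.100, 0.030,  0.050),
    Rothia          = c(0.040, 0.160,  0.030),
    Corynebacterium = c(0.030, 0.120,  0.060),
    Neisseria       = c(0.080, 0.020,  0.012),
    Actinomyces     = c(0.025, 0.080,  0.020),
    Haemophilus     = c(0.040, 0.015,  0.012),
    Fusobacterium   = c(0.050, 0.012,  0.010),
    Gemella         = c(0.040, 0.010,  0.008),
    Prevotella      = c(0.050, 0.015,  0.012),
    Porphyromonas   = c(0.040, 0.010,  0.008),
    Leptotrichia    = c(0.030, 0.008,  0.006),
    Lactobacillus   = c(0.010, 0.050,  0.008),
    Lautropia       = c(0.006, 0.040,  0.006),
    Veillonella     = c(0.020, 0.020,  0.020),
    Granulicatella  = c(0.015, 0.015,  0.015))
  rare_names <- c("Micrococcus", "Moraxella", "Acinetobacter", "Pseudomonas",
                  "Enhydrobacter", "Paracoccus", "Kocuria", "Dermacoccus",
                  "Brevundimonas", "Sphingomonas", "Methylobacterium",
                  "Deinococcus", "Anaerococcus")
  rare_p <- 2e-4
  prevalent_mass <- 1 - rare_p * length(rare_names)
  # the dominant genus of each profile absorbs the balance so columns sum to 1
  profiles <- fixed
  profiles["Streptococcus", 1:2] <-
    prevalent_mass - colSums(fixed[, 1:2], na.rm = TRUE)
  profiles["Cutibacterium", 3] <-
    prevalent_mass - sum(fixed[, 3], na.rm = TRUE)
  profiles <- rbind(profiles,
                    matrix(rare_p, length(rare_names), 3,
                           dimnames = list(rare_names, NULL)))
  colnames(profiles) <- c("DC1-sub1", "DC1-sub2", "DC2")
  list(profiles = profiles,
       top_cluster = c(`DC1-sub1` = "DC1", `DC1-sub2` = "DC1", DC2 = "DC2"),
       weights = c(`DC1-sub1` = 0.34, `DC1-sub2` = 0.37, DC2 = 0.29),
       prevalent = rownames(fixed),
       core = setdiff(rownames(fixed), c("Veillonella", "Granulicatella")))
}

#' Cohort generator configuration
#'
#' @param n_subjects number of subjects (>= 1).
#' @param age_range inclusive integer age range in years.
#' @param sex_ratio fraction female in [0, 1].
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param oil_peak_age age (years) of the sebum median peak.
#' @param cluster_profiles planted community profiles as returned by
#'   [default_genus_profiles()].
#' @param subcluster_split `"DC1"` (default: the Streptococcus-dominant top
#'   cluster carries two nested subprofiles) or `"none"` (each top cluster is
#'   a single mixture-averaged profile; subcluster truth equals cluster
#'   truth).
#' @param depth_mean mean sequencing depth for the per-sample Poisson draw.
#' @param dirichlet_concentration total Dirichlet concentration controlling
#'   subject-to-subject community variability around the profile.
#' @param n_genera number of genera (>= 17 and >= rows of the profiles;
#'   extra genera beyond the profile rows are added as rare background taxa).
#' @return a `cohort_config` list, validated.
#' @export
cohort_config <- function(n_subjects = 300,
                          age_range = c(0L, 88L),
                          sex_ratio = 1,
                          seed = 1L,
                          oil_peak_age = 30,
                          cluster_profiles = default_genus_profiles(),
                          subcluster_split = "DC1",
                          depth_mean = 5000,
                          dirichlet_concentration = 200,
                          n_genera = nrow(cluster_profiles$profiles)) {
  stopifnot(n_subjects >= 1, length(age_range) == 2,
            age_range[1] <= age_range[2],
            sex_ratio >= 0, sex_ratio <= 1,
            depth_mean > 0, dirichlet_concentration > 0)
  if (n_genera < 17) stop("n_genera must be >= 17")
  if (n_genera < nrow(cluster_profiles$profiles))
    stop("n_genera (", n_genera, ") smaller than the ",
         nrow(cluster_profiles$profiles), " genera named in the profiles")
  if (!subcluster_split %in% c("DC1", "none"))
    stop("subcluster_split must be 'DC1' or 'none'")
  csums <- colSums(cluster_profiles$profiles)
  if (any(abs(csums - 1) > 1e-9))
    stop("profile probability vectors must sum to 1")
  if (abs(sum(cluster_profiles$weights) - 1) > 1e-9)
    stop("profile mixing weights must sum to 1")
  if (n_genera > nrow(cluster_profiles$profiles)) {
    extra <- n_genera - nrow(cluster_profiles$profiles)
    pad <- matrix(2e-4, extra, ncol(cluster_profiles$profiles),
                  dimnames = list(paste0("Genus", seq_len(extra)), NULL))
    prof <- rbind(cluster_profiles$profiles, pad)
    cluster_profiles$profiles <- sweep(prof, 2, colSums(prof), "/")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 age_range = as.integer(age_range), sex_ratio = sex_ratio,
                 seed = as.integer(seed), oil_peak_age = oil_peak_age,
                 cluster_profiles = cluster_profiles,
                 subcluster_split = subcluster_split,
                 depth_mean = depth_mean,
                 dirichlet_concentration = dirichlet_concentration,
                 n_genera = as.integer(n_genera)),
            class = "cohort_config")
}

# decade-median paths for the age-dependent traits; tone (ITA degrees) and
# elasticity (R7 x 100) decline strictly with age, interpolated at decade
# midpoints
.tone_path <- function(age) {
  stats::approx(x = seq(5, 85, by = 10),
                y = c(48.0, 46.2, 43.5, 40.6, 37.5, 35.8, 35.1, 33.1, 32.2),
                xout = age, rule = 2)$y
}

.elasticity_path <- function(age) {
  stats::approx(x = seq(5, 85, by = 10),
                y = c(68.0, 65.0, 60.2, 51.5, 47.3, 43.8, 41.2, 39.0, 38.0),
                xout = age, rule = 2)$y / 100
}

# unimodal sebum median path: linear rise to the peak, linear decline after
.oil_path <- function(age, peak) {
  ifelse(age <= peak,
         15 + 25 * age / pmax(peak, 1),
         pmax(40 - 34 * (age - peak) / 55, 2))
}

.trunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Replicate schema of the synthetic measurement table
#'
#' Maps the generated measurement columns to (parameter, site) pairs for
#' [average_replicates()].
#' @return schema data.frame.
#' @export
synthetic_schema <- function() {
  rbind(
    data.frame(column = sprintf("hydration_forehead_r%d", 1:3),
               parameter = "hydration", site = "forehead"),
    data.frame(column = sprintf("hydration_cheek_r%d", 1:3),
               parameter = "hydration", site = "cheek"),
    data.frame(column = sprintf("tewl_forehead_r%d", 1:3),
               parameter = "tewl", site = "forehead"),
    data.frame(column = sprintf("tewl_cheek_r%d", 1:3),
               parameter = "tewl", site = "cheek"),
    data.frame(column = "sebum", parameter = "sebum", site = "face"),
    data.frame(column = c("L_star"), parameter = "L", site = "face"),
    data.frame(column = c("a_star"), parameter = "a", site = "face"),
    data.frame(column = c("b_star"), parameter = "b", site = "face"),
    data.frame(column = c("R2", "R5", "R7", "R_fold"),
               parameter = c("R2", "R5", "R7", "R_fold"), site = "face"),
    data.frame(column = c("pore_left", "pore_right"),
               parameter = "pore", site = c("left_cheek", "right_cheek")),
    data.frame(column = c("Ra_nasolabial", "Ra_canthal"),
               parameter = c("Ra", "Ra_canthal"), site = "face"))
}

# generate raw biophysical measurement columns from latent trait values
.measurements_from_latents <- function(ita, r7, sebum, hydration, age) {
  n <- length(age)
  rep3 <- function(base, sd) sapply(1:3, function(i) stats::rnorm(n, base, sd))
  b_star <- .trunc_norm(n, 16, 2, lo = 6)
  L_star <- 50 + b_star * tan(ita * pi / 180)
  hyd_f <- rep3(hydration + stats::rnorm(n, 0, 2), 1.5)
  hyd_c <- rep3(hydration + stats::rnorm(n, 0, 2), 1.5)
  tewl_base <- .trunc_norm(n, 10, 2.5, lo = 1)
  tewl_f <- rep3(tewl_base, 1)
  tewl_c <- rep3(tewl_base + stats::rnorm(n, 0, 1), 1)
  pore_lat <- 20 + 0.25 * age + stats::rnorm(n, 0, 5)
  ra <- ifelse(age <= 9, NA_real_, 10 + 0.30 * age + stats::rnorm(n, 0, 5))
  ra_canthal <- ifelse(is.na(ra), NA_real_, 0.6 * ra + stats::rnorm(n, 4, 4))
  m <- data.frame(
    hyd_f, hyd_c, tewl_f, tewl_c,
    sebum = sebum,
    L_star = L_star, a_star = stats::rnorm(n, 12, 2), b_star = b_star,
    R2 = .trunc_norm(n, r7 + 0.02, 0.04, 0, 1.5),
    R5 = .trunc_norm(n, r7 - 0.02, 0.04, 0, 1.5),
    R7 = r7,
    R_fold = .trunc_norm(n, 1.2 + 0.004 * age, 0.15, lo = 0.3),
    pore_left = pore_lat + stats::rnorm(n, 0, 2),
    pore_right = pore_lat + stats::rnorm(n, 0, 2),
    Ra_nasolabial = ra, Ra_canthal = ra_canthal)
  names(m)[1:12] <- c(sprintf("hydration_forehead_r%d", 1:3),
                      sprintf("hydration_cheek_r%d", 1:3),
                      sprintf("tewl_forehead_r%d", 1:3),
                      sprintf("tewl_cheek_r%d", 1:3))
  m
}

#' Simulate a full cohort
#'
#' Draws subjects (age uniform over the configured range, sex by the
#' configured ratio), their raw biophysical measurement table (with replicate
#' and site structure), a genus-level microbiome count table drawn
#' Dirichlet-multinomial from each subject's planted (sub)cluster profile at
#' Poisson-distributed depth, a random coalescent genus tree, and the planted
#' truth (cluster, subcluster, prevalent/core genus sets).
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort` list: `subjects`, `measurements`, `schema`,
#'   `counts` (samples x genera integer matrix), `tree` (`phylo`),
#'   `tree_newick`, `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  ids <- sprintf("S%04d", seq_len(n))
  age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")

  ita <- .tone_path(age) + stats::rnorm(n, 0, 5)
  r7 <- .trunc_norm(n, .elasticity_path(age), 0.06, 0, 1.5)
  sebum <- .trunc_norm(n, .oil_path(age, config$oil_peak_age), 8, lo = 0)
  hydration <- .trunc_norm(n, 55, 8, lo = 10)  # age-flat by design
  measurements <- .measurements_from_latents(ita, r7, sebum, hydration, age)
  measurements <- cbind(subject_id = ids, measurements)

  cp <- config$cluster_profiles
  if (config$subcluster_split == "none") {
    tops <- unique(cp$top_cluster)
    prof <- sapply(tops, function(tc) {
      idx <- cp$top_cluster == tc
      w <- cp$weights[idx] / sum(cp$weights[idx])
      as.vector(cp$profiles[, idx, drop = FALSE] %*% w)
    })
    rownames(prof) <- rownames(cp$profiles)
    weights <- vapply(tops, function(tc) sum(cp$weights[cp$top_cluster == tc]),
                      numeric(1))
    top_of <- stats::setNames(tops, tops)
  } else {
    prof <- cp$profiles
    weights <- cp$weights
    top_of <- cp$top_cluster
  }
  subcl <- sample(colnames(prof), n, replace = TRUE, prob = weights)
  depth <- stats::rpois(n, config$depth_mean)
  theta <- config$dirichlet_concentration
  counts <- t(vapply(seq_len(n), function(i) {
    p <- .rdirichlet(theta * prof[, subcl[i]])
    as.integer(stats::rmultinom(1, depth[i], p))
  }, integer(nrow(prof))))
  dimnames(counts) <- list(ids, rownames(prof))

  tree <- ape::rcoal(nrow(prof), tip.label = sample(rownames(prof)))

  list(subjects = data.frame(subject_id = ids, age = age, sex = sex,
                             stringsAsFactors = FALSE),
       measurements = measurements,
       schema = synthetic_schema(),
       counts = counts,
       tree = tree,
       tree_newick = ape::write.tree(tree),
       truth = list(cluster = stats::setNames(unname(top_of[subcl]), ids),
                    subcluster = stats::setNames(subcl, ids),
                    prevalent_genera = cp$prevalent,
                    core_genera = cp$core,
                    planted_crossover = list()),
       config = config) |>
    structure(class = "synthetic_cohort")
}

#' Simulate questionnaire responses coupled to the biophysical traits
#'
#' Emits 59 scored items (`q01`..`q59`, ordered O 11, S 18, P 10, W 20) plus
#' one unscored control item (`q60`), values 1-4 with missingness at the
#' requested rate. Each category's latent trait is the standardized
#' corresponding biophysical metric (O: sebum; S: TEWL; P: darker tone, i.e.
#' negative ITA; W: wrinkle roughness), so item scores correlate with the
#' planted skin state.
#'
#' @param cohort a `synthetic_cohort`.
#' @param missing_rate fraction of scored cells set missing, in [0, 1).
#' @param seed integer seed.
#' @return data.frame `subject_id`, `q01`..`q60`,
#'   `has_listed_skin_condition`, `sun_aggravates_moles`, `age`; the item ->
#'   category map is attached as attribute `category_map`.
#' @export
simulate_responses <- function(cohort, missing_rate = 0.02, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  set.seed(seed)
  collapsed <- average_replicates(cohort$measurements[, -1], cohort$schema)
  latents <- data.frame(
    O = collapsed$sebum,
    S = collapsed$tewl,
    P = -compute_ita(collapsed$L, collapsed$b),
    W = collapsed$Ra)
  z <- lapply(latents, function(v) {
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    z[is.na(z)] <- 0
    z
  })
  n <- nrow(latents)
  sizes <- c(O = 11L, S = 18L, P = 10L, W = 20L)
  items <- do.call(cbind, lapply(names(sizes), function(cat) {
    sapply(seq_len(sizes[[cat]]), function(j) {
      raw <- 2.5 + 1.1 * z[[cat]] + stats::rnorm(n, 0, 0.8)
      pmin(pmax(round(raw), 1), 4)
    })
  }))
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(length(items)) < missing_rate, nrow = n)
    items[miss] <- NA_integer_
  }
  q60 <- sample(1:4, n, replace = TRUE)  # unscored control item
  out <- data.frame(subject_id = cohort$subjects$subject_id, items, q60)
  names(out) <- c("subject_id", sprintf("q%02d", 1:60))
  out$has_listed_skin_condition <- stats::runif(n) < 0.15
  out$sun_aggravates_moles <- stats::runif(n) < 0.10
  out$age <- cohort$subjects$age
  attr(out, "category_map") <-
    data.frame(item = sprintf("q%02d", 1:60),
               category = c(rep(names(sizes), sizes), "unscored"))
  out
}

#' Plant an upper/lower proportion crossover at a given age
#'
#' Rewrites the raw measurements driving one composite criterion as a
#' two-regime process: subjects strictly younger than `age` draw from a high
#' distribution, subjects at or above `age` from a well-separated low
#' distribution, so the proportion above the cohort median reverses exactly
#' at `age` in expectation. The plant is recorded in
#' `truth$planted_crossover`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param criterion `"tone_elasticity"` or `"oil_moisture"`.
#' @param age crossover age within the cohort age range.
#' @return the modified cohort.
#' @export
plant_crossover <- function(cohort, criterion, age) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!criterion %in% c("tone_elasticity", "oil_moisture"))
    stop("unknown criterion: ", criterion)
  rng <- range(cohort$subjects$age)
  if (age < rng[1] || age > rng[2] + 1)
    stop("crossover age outside the cohort age range")
  set.seed(cohort$config$seed + 7919L * (length(cohort$truth$planted_crossover) + 1L)
           + match(criterion, c("tone_elasticity", "oil_moisture")))
  n <- nrow(cohort$subjects)
  high <- cohort$subjects$age < age
  if (criterion == "tone_elasticity") {
    ita <- ifelse(high, stats::rnorm(n, 45, 4), stats::rnorm(n, 30, 4))
    r7 <- ifelse(high, .trunc_norm(n, 0.62, 0.05, 0, 1.5),
                 .trunc_norm(n, 0.42, 0.05, 0, 1.5))
    b_star <- cohort$measurements$b_star
    cohort$measurements$L_star <- 50 + b_star * tan(ita * pi / 180)
    cohort$measurements$R7 <- r7
    cohort$measurements$R2 <- .trunc_norm(n, r7 + 0.02, 0.04, 0, 1.5)
    cohort$measurements$R5 <- .trunc_norm(n, r7 - 0.02, 0.04, 0, 1.5)
  } else {
    sebum <- ifelse(high, .trunc_norm(n, 40, 6, lo = 0),
                    .trunc_norm(n, 15, 6, lo = 0))
    hydration <- ifelse(high, .trunc_norm(n, 62, 5, lo = 10),
                        .trunc_norm(n, 48, 5, lo = 10))
    cohort$measurements$sebum <- sebum
    for (s in c("forehead", "cheek")) for (r in 1:3)
      cohort$measurements[[sprintf("hydration_%s_r%d", s, r)]] <-
        hydration + stats::rnorm(n, 0, 1.5)
  }
  cohort$truth$planted_crossover[[criterion]] <-
    c(cohort$truth$planted_crossover[[criterion]], age)
  cohort
}

#' Write a cohort to plain-text files
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             measurements = file.path(dir, "measurements.csv"),
             counts = file.path(dir, "feature_table.tsv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(cohort$subjects, paths["subjects"], row.names = FALSE)
  utils::write.csv(cohort$measurements, paths["measurements"], row.names = FALSE)
  write_feature_table(cohort$counts, paths["counts"])
  writeLines(cohort$tree_newick, paths["tree"])
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
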