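#' End-to-end pipeline orchestration
#'
#' Runs simulate -> questionnaire scoring -> metric panel -> cutotype/aging
#' stratification -> microbiome clustering -> core-genus selection -> type
#' prediction from a single configuration, writing stage outputs and a
#' reproducibility manifest (parameters, derived per-stage seeds, file
#' hashes) to a run directory. Re-running an identical configuration
#' reproduces identical outputs.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param out_dir run directory.
#' @param seed global seed; per-stage seeds are derived deterministically as
#'   `seed + 10007 * stage_index`.
#' @param n_subjects cohort size.
#' @param rarefaction_depth rarefaction depth (default 1391).
#' @param unifrac_alpha generalized UniFrac exponent (default 0.5).
#' @param prevalence_threshold core-genus detection threshold (default 0.5).
#' @param kw_alpha core-genus Kruskal-Wallis level (default 0.05).
#' @param lda_threshold LDA score threshold (default 2.0).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param split_fraction training fraction (default 0.8).
#' @param cutpoints `c(c1, c2)` aging cutpoints, or `NULL` to detect them
#'   from the proportion-crossover procedure.
#' @param stages character vector of stages to run (dependency order is
#'   enforced; later stages require their inputs' stages).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            n_subjects = 300,
                            rarefaction_depth = 1391,
                            unifrac_alpha = 0.5,
                            prevalence_threshold = 0.5,
                            kw_alpha = 0.05,
                            lda_threshold = 2.0,
                            n_perm = 999,
                            split_fraction = 0.8,
                            cutpoints = c(35, 51),
                            stages = c("simulate", "bsti", "metrics", "ksc",
                                       "cluster", "core", "classify")) {
  stopifnot(rarefaction_depth >= 1, unifrac_alpha >= 0, unifrac_alpha <= 1,
            prevalence_threshold > 0, prevalence_threshold <= 1,
            kw_alpha > 0, kw_alpha < 1,
            split_fraction > 0, split_fraction < 1, n_perm >= 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = n_subjects,
                 rarefaction_depth = rarefaction_depth,
                 unifrac_alpha = unifrac_alpha,
                 prevalence_threshold = prevalence_threshold,
                 kw_alpha = kw_alpha, lda_threshold = lda_threshold,
                 n_perm = n_perm, split_fraction = split_fraction,
                 cutpoints = cutpoints, stages = stages),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the [pipeline_config()] arguments; unknown keys are
#' rejected rather than silently ignored.
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$cutpoints)) raw$cutpoints <- as.numeric(raw$cutpoints)
  do.call(pipeline_config, raw)
}

.stage_seed <- function(config, stage) {
  all_stages <- c("simulate", "bsti", "metrics", "ksc", "cluster", "core",
                  "classify")
  config$seed + 10007L * match(stage, all_stages)
}

#' Run the pipeline
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of stage results; outputs and `manifest.json`
#'   are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  manifest <- list(package_version = as.character(utils::packageVersion("kscutotype")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config), "out_dir")],
                   stages = list())
  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[stage]] <<- list(
      seed = .stage_seed(config, stage),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  res$cohort <- run_stage("simulate", function() {
    cohort <- simulate_cohort(cohort_config(
      n_subjects = config$n_subjects, seed = .stage_seed(config, "simulate")))
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
    cohort
  })

  res$bsti <- run_stage("bsti", function() {
    responses <- simulate_responses(res$cohort, missing_rate = 0.02,
                                    seed = .stage_seed(config, "bsti"))
    scored <- score_questionnaire(responses)
    utils::write.csv(scored, file.path(config$out_dir, "bsti_types.csv"),
                     row.names = FALSE)
    utils::write.csv(type_distribution(scored$label),
                     file.path(config$out_dir, "bsti_distribution.csv"),
                     row.names = FALSE)
    scored
  })

  res$metrics <- run_stage("metrics", function() {
    panel <- build_metric_panel(res$cohort$measurements[, -1],
                                res$cohort$schema)
    out <- cbind(subject_id = res$cohort$subjects$subject_id,
                 panel$raw_metrics,
                 stats::setNames(panel$scores, paste0("score_", names(panel$scores))),
                 panel$composites)
    utils::write.csv(out, file.path(config$out_dir, "metric_panel.csv"),
                     row.names = FALSE)
    panel
  })

  res$ksc <- run_stage("ksc", function() {
    cp <- config$cutpoints
    labels <- assign_ksc(res$metrics$composites, res$cohort$subjects$age,
                         c1 = cp[1], c2 = cp[2])
    out <- cbind(subject_id = res$cohort$subjects$subject_id, labels)
    utils::write.csv(out, file.path(config$out_dir, "ksc_labels.csv"),
                     row.names = FALSE)
    labels
  })

  res$cluster <- run_stage("cluster", function() {
    seed <- .stage_seed(config, "cluster")
    rare <- rarefy(res$cohort$counts, config$rarefaction_depth, seed = seed)
    d <- generalized_unifrac(rare, res$cohort$tree, config$unifrac_alpha)
    write_distance_matrix(d, file.path(config$out_dir, "gunifrac.tsv"))
    ok <- optimal_k(d, seed = seed)
    top <- pam_cluster(d, max(ok$k, 2))
    sub <- divcom_subcluster(d, top, seed = seed)
    utils::write.csv(
      data.frame(sample_id = names(sub$assignment),
                 cluster = paste0("C", top$assignment),
                 subcluster = unname(sub$assignment)),
      file.path(config$out_dir, "clusters.csv"), row.names = FALSE)
    list(rarefied = rare, dist = d, optimal = ok, top = top, sub = sub)
  })

  res$core <- run_stage("core", function() {
    cl <- res$cluster
    keep <- !is.na(cl$sub$assignment)
    report <- core_genus_selection(cl$rarefied[keep, , drop = FALSE],
                                   cl$sub$assignment[keep],
                                   config$prevalence_threshold,
                                   config$kw_alpha)
    jsonlite::write_json(report, file.path(config$out_dir, "core_genera.json"),
                         auto_unbox = TRUE, digits = NA)
    report
  })

  res$classify <- run_stage("classify", function() {
    cl <- res$cluster
    rel <- relative_abundance(cl$rarefied)[, res$core$core, drop = FALSE]
    ids <- rownames(rel)
    strata <- res$ksc$strata[match(ids, res$cohort$subjects$subject_id)]
    models <- train_type_models(rel, strata,
                                split_fraction = config$split_fraction,
                                seed = .stage_seed(config, "classify"))
    aucs <- do.call(rbind, lapply(names(models), function(g) {
      tps <- setdiff(names(models[[g]]), ".summary")
      data.frame(group = g, type = tps,
                 auc = vapply(tps, function(tp) models[[g]][[tp]]$auc,
                              numeric(1)))
    }))
    utils::write.csv(aucs, file.path(config$out_dir, "type_model_auc.csv"),
                     row.names = FALSE)
    models
  })

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  manifest$file_hashes <- as.list(tools::md5sum(files))
  names(manifest$file_hashes) <- basename(files)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
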