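#' Pipeline configuration
#'
#' A single declarative configuration for the end-to-end demonstration
#' pipeline: simulate a two-group cohort, extract turning features from the
#' marker trials, select features, cross-validate classifiers on the
#' all-features and selected-features cases, and run clinical association
#' models. All randomness is funnelled through `seed`.
#'
#' @param n_per_group Subjects per group.
#' @param archetypes Two archetype names (see [group_archetype()]).
#' @param n_trials Trials per subject.
#' @param seed Master seed.
#' @param filter A [filter_spec()].
#' @param compact_grids Use compact hyperparameter grids (quick runs).
#' @param cv_folds Folds for cross-validation.
#' @param clinical_dependents Clinical score columns for association models.
#' @param out_dir Output directory (`NULL` = do not write files).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_group = 15,
                            archetypes = c("control", "pd"),
                            n_trials = 2, seed = 1,
                            filter = filter_spec(),
                            compact_grids = TRUE, cv_folds = 5,
                            clinical_dependents = c("updrs_total", "nfogq"),
                            out_dir = NULL) {
  cfg <- list(n_per_group = n_per_group, archetypes = archetypes,
              n_trials = n_trials, seed = as.integer(seed), filter = filter,
              compact_grids = compact_grids, cv_folds = cv_folds,
              clinical_dependents = clinical_dependents, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full demonstration pipeline
#'
#' Stages: (1) cohort simulation; (2) marker-level feature extraction,
#' averaged over each subject's trials; (3) feature selection (univariable
#' screen, VIF filter, stepwise logistic with forced covariates, ROC
#' cutoffs); (4) cross-validated classification with all features and with
#' the selected subset; (5) blockwise stepwise association models for the
#' clinical dependents. Outputs embed the seed and a configuration hash;
#' a rerun with the same configuration is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return List with `features`, `selection`, `cv_all`, `cv_selected`,
#'   `association`, `cohort`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  cohort <- simulate_cohort(config$n_per_group, config$archetypes,
                            n_trials = config$n_trials, seed = config$seed)
  feats <- cohort_features(cohort, filter = config$filter)
  labels <- as.integer(feats$group == config$archetypes[2])
  fcols <- setdiff(names(feats), c("subject_id", "group"))
  usable <- fcols[vapply(feats[fcols], function(v)
    all(is.finite(v)) && stats::sd(v) > 0, logical(1))]
  ftab <- feats[usable]

  covar <- cohort$subjects[c("age", "height", "bmi")]
  covar$sex <- as.integer(cohort$subjects$sex == "M")
  seltab <- cbind(ftab, covar)
  selection <- select_features(seltab, labels,
                               covariates = c("age", "sex", "height", "bmi"))

  specs <- lapply(c("LR", "KNN", "NB", "LDA", "QDA", "SVM", "RF"),
                  function(nm) classifier_spec(
                    nm, default_grids(config$compact_grids)[[nm]]))
  k <- min(config$cv_folds, min(table(labels)))
  cv_all <- run_cv(ftab, labels, specs, k = k, seed = config$seed)
  sel_feats <- selection$selection$selected
  cv_selected <- if (length(sel_feats) >= 1L)
    run_cv(ftab[sel_feats], labels, specs, k = k, seed = config$seed)
  else NULL

  assoc <- list()
  atab <- cbind(seltab, cohort$subjects[config$clinical_dependents])
  cand <- if (length(sel_feats)) sel_feats else usable[seq_len(min(5, length(usable)))]
  for (dep in config$clinical_dependents) {
    assoc[[dep]] <- tryCatch(
      stepwise_linear_blocks(atab, dep, candidates = cand),
      error = function(e) e)
  }

  res <- list(features = feats, selection = selection, cv_all = cv_all,
              cv_selected = cv_selected, association = assoc,
              cohort = cohort, config_hash = hash, seed = config$seed)
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config)
  res
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  utils::write.csv(res$features, pth("features.csv"), row.names = FALSE)
  utils::write.csv(res$selection$selection$coefficients,
                   pth("selection.csv"), row.names = FALSE)
  cv_df <- function(cv) do.call(rbind, lapply(names(cv$classifiers),
    function(nm) {
      m <- cv$classifiers[[nm]]
      data.frame(classifier = nm, t(m$mean), t(stats::setNames(
        m$sd, paste0(names(m$sd), "_sd"))))
    }))
  utils::write.csv(cv_df(res$cv_all), pth("cv_all.csv"), row.names = FALSE)
  if (!is.null(res$cv_selected))
    utils::write.csv(cv_df(res$cv_selected), pth("cv_selected.csv"),
                     row.names = FALSE)
  meta <- list(seed = res$seed, config_hash = res$config_hash,
               selected = res$selection$selection$selected)
  jsonlite::write_json(meta, pth("run.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
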