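pipeline_defaults <- function() {
  list(
    simulate = list(),          # sim_config() overrides; NULL disables simulation
    input_dir = NULL,           # read a cohort from files instead of simulating
    train_fraction = 0.7,
    correlation_threshold = 0.75,
    go_components = 2,
    weight_multiset = c(4, 2, 1, 3),
    tune_folds = 5,
    cv_folds = 0,               # >0: per-member cross-validation report
    n_perm = 1000,
    null_baseline = FALSE,      # also fit on permuted training labels
    decile_fraction = 0.10,
    seed = 20240101
  )
}

#' Validate a pipeline configuration
#'
#' Applies defaults, rejects unknown keys (strict mode) and reports every
#' violation at once.
#'
#' @param config A named list of settings, or a path to a YAML file holding
#'   one.
#' @return The completed configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- pipeline_defaults()
  errs <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown config keys: ",
                           paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, config[intersect(names(config), names(defaults))],
                    keep.null = TRUE)
  if (!is.null(cfg$simulate)) {
    sim_try <- tryCatch(do.call(sim_config, c(cfg$simulate,
                                              list(seed = cfg$seed))),
                        error = function(e) conditionMessage(e))
    if (is.character(sim_try)) errs <- c(errs, sim_try)
  }
  if (is.null(cfg$simulate) && is.null(cfg$input_dir)) {
    errs <- c(errs, "either simulate or input_dir must be provided")
  }
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir)) {
    errs <- c(errs, paste0("input_dir does not exist: ", cfg$input_dir))
  }
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    errs <- c(errs, "train_fraction must be in (0, 1)")
  }
  if (cfg$correlation_threshold <= 0 || cfg$correlation_threshold > 1) {
    errs <- c(errs, "correlation_threshold must be in (0, 1]")
  }
  if (cfg$decile_fraction <= 0 || cfg$decile_fraction > 0.5) {
    errs <- c(errs, "decile_fraction must be in (0, 0.5]")
  }
  if (cfg$n_perm < 1) errs <- c(errs, "n_perm must be >= 1")
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  structure(cfg, class = c("pipeline_config", "list"))
}

with_stage <- function(stage, outdir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(outdir)) {
      writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
                 file.path(outdir, "FAILED"))
    }
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full prioritization pipeline
#'
#' Simulate (or load) a cohort, compute topology features, assemble and
#' scale the feature matrix (all transforms fitted on the training split
#' only), train the weighted soft-voting ensemble, score every gene, and
#' validate the ranking with leakage-removed enrichment and decile
#' over-representation.
#'
#' @param config A configuration list or YAML path (see [validate_config()]).
#' @param seed Optional seed overriding the configured one; all randomness
#'   in the run flows from it.
#' @param outdir Optional output directory. When given, writes
#'   `pain_scores.tsv`, `model_card.json`, `enrichment.tsv`,
#'   `feature_importance.tsv`, `ora_top.tsv`, `ora_bottom.tsv`,
#'   optionally `cv_report.tsv`, and `run_log.json`; a failed stage leaves a
#'   `FAILED` marker naming the stage.
#' @return Invisibly, a list with the cohort, fitted ensemble, ranking,
#'   held-out metrics, enrichment results and run log.
#' @export
run_pipeline <- function(config = list(), seed = NULL, outdir = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  cohort <- with_stage("simulate", outdir, {
    if (!is.null(cfg$input_dir)) {
      read_cohort(cfg$input_dir)
    } else {
      generate_cohort(do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed))))
    }
  })

  topo <- with_stage("topology", outdir, compute_topology(cohort$graph))

  split <- with_stage("split", outdir,
    split_stratified(cohort$labels, cfg$train_fraction, seed = cfg$seed + 10L))

  fm <- with_stage("featurize", outdir, {
    fm <- assemble_features(cohort$tab, cohort$meta, cohort$annotations,
                            topo, cohort$labels, fit_genes = split$train,
                            go_components = cfg$go_components)
    tr_rows <- match(intersect(split$train, fm$gene_id), fm$gene_id)
    sc <- scale_minmax(fm$x, fit_rows = tr_rows)
    cf <- correlation_filter(sc$x, threshold = cfg$correlation_threshold,
                             fit_rows = tr_rows)
    fm$x <- cf$x
    fm$provenance$correlation_dropped <- cf$dropped
    fm$provenance$scale_min <- sc$min
    fm$provenance$scale_max <- sc$max
    fm
  })

  tr <- match(intersect(split$train, fm$gene_id), fm$gene_id)
  va <- match(intersect(split$validation, fm$gene_id), fm$gene_id)
  x_tr <- fm$x[tr, , drop = FALSE]
  y_tr <- fm$labels[tr]
  x_va <- fm$x[va, , drop = FALSE]
  y_va <- fm$labels[va]

  voting <- with_stage("train", outdir,
    fit_voting(x_tr, y_tr, default_learner_specs(seed = cfg$seed),
               weight_multiset = cfg$weight_multiset,
               tune_folds = cfg$tune_folds, seed = cfg$seed + 20L))

  holdout <- with_stage("evaluate", outdir, {
    p <- predict_proba(voting, x_va)
    metric_set(confusion_from_predictions(y_va, as.integer(p >= 0.5)))
  })

  null_metrics <- NULL
  if (isTRUE(cfg$null_baseline)) {
    null_metrics <- with_stage("null_baseline", outdir, {
      set.seed(cfg$seed + 30L)
      y_perm <- sample(y_tr)
      nv <- fit_voting(x_tr, y_perm, default_learner_specs(seed = cfg$seed),
                       weight_multiset = cfg$weight_multiset,
                       tune_folds = cfg$tune_folds, seed = cfg$seed + 20L)
      p <- predict_proba(nv, x_va)
      metric_set(confusion_from_predictions(y_va, as.integer(p >= 0.5)))
    })
  }

  cv_report <- NULL
  if (cfg$cv_folds > 0) {
    cv_report <- with_stage("cross_validate", outdir, {
      specs <- default_learner_specs(seed = cfg$seed)
      lapply(specs, function(s) {
        cross_validate(x_tr, y_tr, function(xx, yy) fit_learner(xx, yy, s),
                       folds = cfg$cv_folds, seed = cfg$seed + 40L)
      })
    })
  }

  ranking <- with_stage("score", outdir, {
    p_all <- predict_proba(voting, fm$x)
    rank_genes(setNames(p_all, fm$gene_id))
  })

  importance <- with_stage("explain", outdir, {
    shaps <- lapply(voting$learners, function(l) shap_matrix(l, x_va))
    shap_weighted(shaps, voting$weights)$importance
  })

  training_positives <- split$train[cohort$labels[split$train] == 1]

  enrichment <- with_stage("validate", outdir, {
    sets <- list(cohort$validation_set)
    if (!is.null(cohort$truth)) {
      sets <- c(sets, list(gene_set("planted_positives",
                                    cohort$truth$positives,
                                    "genes planted as pain-labelled")))
    }
    validate_against_sets(ranking, sets, training_positives,
                          n_perm = cfg$n_perm, seed = cfg$seed + 50L)
  })

  ora <- with_stage("enrich", outdir, {
    list(top = ora_decile(ranking, cohort$annotations, "top",
                          cfg$decile_fraction),
         bottom = ora_decile(ranking, cohort$annotations, "bottom",
                             cfg$decile_fraction))
  })

  run_log <- list(
    config = unclass(cfg),
    seeds = list(master = cfg$seed, split = cfg$seed + 10L,
                 weight_tuning = cfg$seed + 20L, null_baseline = cfg$seed + 30L,
                 cross_validation = cfg$seed + 40L, enrichment = cfg$seed + 50L),
    interpretation_notes = c(
      "composite LFC: entries with FDR >= 0.05 (non-significant) are zeroed before averaging",
      "correlation filter: |r| >= threshold triggers removal of the smaller-variance member"),
    n_genes = length(fm$gene_id),
    n_features = ncol(fm$x),
    n_train = length(tr), n_validation = length(va),
    n_train_positives = length(training_positives),
    dropped_features = fm$provenance[c("zero_variance_dropped",
                                       "correlation_dropped")]
  )

  if (!is.null(outdir)) {
    with_stage("write", outdir, {
      write_pain_scores(ranking, file.path(outdir, "pain_scores.tsv"))
      write_model_card(voting, metrics = unclass(holdout),
                       path = file.path(outdir, "model_card.json"))
      write_enrichment_report(enrichment, file.path(outdir, "enrichment.tsv"))
      data.table::fwrite(data.frame(feature = names(importance),
                                    mean_abs_shap = unname(importance)),
                         file.path(outdir, "feature_importance.tsv"), sep = "\t")
      data.table::fwrite(ora$top, file.path(outdir, "ora_top.tsv"), sep = "\t")
      data.table::fwrite(ora$bottom, file.path(outdir, "ora_bottom.tsv"),
                         sep = "\t")
      if (!is.null(cv_report)) {
        cvdf <- do.call(rbind, lapply(names(cv_report), function(nm) {
          data.frame(member = nm, metric = names(cv_report[[nm]]$mean),
                     mean = unname(cv_report[[nm]]$mean),
                     sd = unname(cv_report[[nm]]$sd))
        }))
        data.table::fwrite(cvdf, file.path(outdir, "cv_report.tsv"), sep = "\t")
      }
      jsonlite::write_json(run_log, file.path(outdir, "run_log.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }

  invisible(list(cohort = cohort, features = fm, split = split,
                 ensemble = voting, holdout = holdout,
                 null_holdout = null_metrics, cv = cv_report,
                 ranking = ranking, importance = importance,
                 enrichment = enrichment, ora = ora, run_log = run_log))
}
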