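#' Specification of a base learner
#'
#' The four voting members are tree ensembles trained with xgboost:
#' \describe{
#'   \item{`xgbm`}{regularized gradient-boosted trees (the default engine).}
#'   \item{`gb`}{classic gradient boosting: no L1/L2 regularization, no
#'     column subsampling.}
#'   \item{`ada`}{adaptive boosting formulated as stagewise additive
#'     modeling with exponential loss over depth-1 stumps; probabilities are
#'     recovered as `1 / (1 + exp(-2 f))` from the additive margin `f`.}
#'   \item{`rf`}{random forest: a single boosting round of many bagged
#'     trees with per-node feature subsampling.}
#' }
#' All members share a per-class weighting (`scale_pos_weight`, default
#' `N_neg / N_pos`) so the 0.5 probability threshold remains meaningful at
#' severe class imbalance.
#'
#' @param family One of `"xgbm"`, `"gb"`, `"ada"`, `"rf"`.
#' @param params Named list of xgboost parameter overrides.
#' @param nrounds Number of boosting rounds (ignored for `rf`, which uses 1).
#' @param seed Integer seed for the learner's own randomness.
#' @return An object of class `base_learner_spec`.
#' @export
base_learner_spec <- function(family = c("xgbm", "gb", "ada", "rf"),
                              params = list(), nrounds = NULL, seed = 20240101) {
  family <- match.arg(family)
  defaults <- switch(family,
    xgbm = list(params = list(objective = "binary:logistic", eta = 0.1,
                              max_depth = 4, lambda = 1, subsample = 0.8,
                              colsample_bytree = 0.8),
                nrounds = 150),
    gb = list(params = list(objective = "binary:logistic", eta = 0.1,
                            max_depth = 3, lambda = 0, alpha = 0,
                            subsample = 1, colsample_bytree = 1),
              nrounds = 150),
    ada = list(params = list(eta = 0.5, max_depth = 1, lambda = 0,
                             base_score = 0.0),
               nrounds = 100),
    rf = list(params = list(objective = "binary:logistic", eta = 1,
                            max_depth = 10, lambda = 0, subsample = 0.632,
                            num_parallel_tree = 400, min_child_weight = 1),
              nrounds = 1)
  )
  structure(list(family = family,
                 params = modifyList(defaults$params, params),
                 nrounds = if (is.null(nrounds)) defaults$nrounds else nrounds,
                 seed = seed),
            class = "base_learner_spec")
}

#' Default specifications for the four voting members
#'
#' Member order is fixed: `xgbm`, `gb`, `ada`, `rf` — the order the voting
#' weights refer to.
#'
#' @param seed Integer seed shared by all members.
#' @return Named list of [base_learner_spec()] objects.
#' @export
default_learner_specs <- function(seed = 20240101) {
  list(xgbm = base_learner_spec("xgbm", seed = seed),
       gb = base_learner_spec("gb", seed = seed),
       ada = base_learner_spec("ada", seed = seed),
       rf = base_learner_spec("rf", seed = seed))
}

# exponential-loss objective (y in {-1, 1}); instance weights applied here
# because xgboost leaves weighting to custom objectives
exp_loss_objective <- function(preds, dtrain) {
  y <- 2 * xgboost::getinfo(dtrain, "label") - 1
  w <- xgboost::getinfo(dtrain, "weight")
  if (length(w) == 0) w <- rep(1, length(y))
  e <- exp(-y * preds)
  list(grad = -w * y * e, hess = w * e)
}

#' Fit one base learner
#'
#' @param x Numeric feature matrix (rows = genes).
#' @param y Binary label vector (1 = pain class).
#' @param spec A [base_learner_spec()].
#' @param scale_pos_weight Class weight for positives; `NULL` (default) uses
#'   `N_neg / N_pos`.
#' @return An object of class `pain_learner`.
#' @export
fit_learner <- function(x, y, spec, scale_pos_weight = NULL) {
  if (length(unique(y)) < 2) stop("training data contains a single class")
  if (is.null(scale_pos_weight)) scale_pos_weight <- sum(y == 0) / sum(y == 1)
  params <- spec$params
  params$nthread <- 1
  params$seed <- spec$seed
  if (spec$family == "ada") {
    w <- ifelse(y == 1, scale_pos_weight, 1)
    dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w)
    booster <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = spec$nrounds,
                                  obj = exp_loss_objective, verbose = 0)
  } else {
    params$scale_pos_weight <- scale_pos_weight
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    booster <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = spec$nrounds, verbose = 0)
  }
  structure(list(booster = booster, spec = spec,
                 feature_names = colnames(x)),
            class = "pain_learner")
}

#' Fit the full set of base learners
#'
#' @inheritParams fit_learner
#' @param specs Non-empty list of [base_learner_spec()] objects.
#' @return Named list of `pain_learner` objects, in spec order.
#' @export
fit_base_learners <- function(x, y, specs = default_learner_specs()) {
  if (length(specs) == 0) stop("specs must be non-empty")
  lapply(specs, function(s) fit_learner(x, y, s))
}

#' Class-1 probability predictions
#'
#' @param object A fitted `pain_learner`, `pain_voting` or `pain_stacking`
#'   model.
#' @param x Feature matrix with the same columns as at fit time.
#' @param ... Unused.
#' @return Numeric vector of class-1 probabilities in `[0, 1]`.
#' @export
predict_proba <- function(object, x, ...) UseMethod("predict_proba")

#' @export
predict_proba.pain_learner <- function(object, x, ...) {
  x <- x[, object$feature_names, drop = FALSE]
  if (object$spec$family == "ada") {
    f <- predict(object$booster, xgboost::xgb.DMatrix(x), outputmargin = TRUE)
    plogis(2 * f)
  } else {
    predict(object$booster, xgboost::xgb.DMatrix(x))
  }
}

#' Weighted soft vote over per-learner probabilities
#'
#' `combined_i = sum_k w_k p_ki / sum_k w_k`; the hard class label is the
#' argmax over the two class probabilities (i.e. combined >= 0.5).
#'
#' @param probas Matrix of class-1 probabilities, one column per learner, or
#'   a list of equal-length probability vectors.
#' @param weights Non-negative weights, one per learner; at least one must
#'   be positive.
#' @return Combined class-1 probability vector.
#' @export
soft_vote <- function(probas, weights) {
  if (is.list(probas)) probas <- do.call(cbind, probas)
  if (ncol(probas) != length(weights)) {
    stop("need exactly one weight per learner")
  }
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative with a positive sum")
  }
  as.vector(probas %*% weights) / sum(weights)
}

# distinct permutations of a multiset, in lexicographic order
distinct_permutations <- function(values) {
  values <- sort(values)
  out <- list()
  recurse <- function(prefix, rest) {
    if (length(rest) == 0) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in unique(rest)) {
      i <- match(v, rest)
      recurse(c(prefix, v), rest[-i])
    }
  }
  recurse(numeric(0), values)
  out
}

#' Exhaustive weight permutation search
#'
#' Evaluates the G-mean of the soft-vote prediction (hard labels at
#' threshold 0.5) for every distinct permutation of the weight multiset and
#' returns the best one. Ties break in favour of the first permutation in
#' lexicographic enumeration order.
#'
#' @param probas Matrix (rows = genes, columns = learners) of class-1
#'   probabilities on tuning rows.
#' @param truth Binary labels of the tuning rows.
#' @param weight_multiset Numeric multiset, one weight slot per learner
#'   (default `c(4, 2, 1, 3)`).
#' @return List with `weights` (best permutation, in learner order), `gm`
#'   (its G-mean) and `trace` (data frame of every permutation and score).
#' @export
weight_search <- function(probas, truth, weight_multiset = c(4, 2, 1, 3)) {
  if (is.list(probas)) probas <- do.call(cbind, probas)
  if (length(weight_multiset) != ncol(probas)) {
    stop("weight multiset length must equal the learner count")
  }
  perms <- distinct_permutations(weight_multiset)
  scores <- vapply(perms, function(w) {
    pred <- as.integer(soft_vote(probas, w) >= 0.5)
    gm(confusion_from_predictions(truth, pred))
  }, numeric(1))
  best <- which.max(scores)   # first maximum in enumeration order
  list(weights = perms[[best]], gm = scores[best],
       trace = data.frame(permutation = vapply(perms, paste, "", collapse = ","),
                          gm = scores))
}

# stratified fold assignment; every fold gets >= 1 positive when possible
stratified_folds <- function(y, folds, seed) {
  if (sum(y == 1) < folds) stop("fewer positives than folds")
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    fold[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  fold
}

# out-of-fold class-1 probabilities for each spec
oof_probas <- function(x, y, specs, folds, seed) {
  fold <- stratified_folds(y, folds, seed)
  p <- matrix(NA_real_, nrow(x), length(specs),
              dimnames = list(NULL, names(specs)))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fits <- lapply(specs, function(s) fit_learner(x[tr, , drop = FALSE], y[tr], s))
    for (k in seq_along(fits)) {
      p[!tr, k] <- predict_proba(fits[[k]], x[!tr, , drop = FALSE])
    }
  }
  p
}

#' Fit the weighted soft-voting ensemble
#'
#' Fits the base learners on the full training data, derives their
#' out-of-fold probabilities, and selects voting weights by exhaustive
#' permutation search maximizing the G-mean on those out-of-fold
#' predictions.
#'
#' @inheritParams fit_base_learners
#' @param weight_multiset Weight multiset to permute (default `c(4, 2, 1, 3)`).
#' @param tune_folds Folds used to produce out-of-fold tuning probabilities
#'   (default 5).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `pain_voting` with the fitted members, the
#'   selected `weights` and the tuning trace.
#' @export
fit_voting <- function(x, y, specs = default_learner_specs(),
                       weight_multiset = c(4, 2, 1, 3), tune_folds = 5,
                       seed = 20240101) {
  oof <- oof_probas(x, y, specs, tune_folds, seed)
  ws <- weight_search(oof, y, weight_multiset)
  learners <- fit_base_learners(x, y, specs)
  structure(list(learners = learners, weights = ws$weights,
                 tuning_gm = ws$gm, member_names = names(specs),
                 seed = seed),
            class = "pain_voting")
}

#' @export
predict_proba.pain_voting <- function(object, x, ...) {
  p <- vapply(object$learners, function(l) predict_proba(l, x),
              numeric(nrow(x)))
  soft_vote(p, object$weights)
}

#' Fit the stacking ensemble
#'
#' Base learners feed a logistic-regression meta-model fitted on their
#' out-of-fold probabilities (out-of-fold, so the meta-model never sees a
#' base learner's training predictions).
#'
#' @inheritParams fit_voting
#' @param meta_folds Folds for the out-of-fold meta-training probabilities.
#' @return An object of class `pain_stacking`.
#' @export
fit_stacking <- function(x, y, specs = default_learner_specs(),
                         meta_folds = 5, seed = 20240101) {
  oof <- oof_probas(x, y, specs, meta_folds, seed)
  df <- as.data.frame(oof)
  df$..y <- y
  meta <- suppressWarnings(glm(..y ~ ., data = df, family = binomial()))
  learners <- fit_base_learners(x, y, specs)
  structure(list(learners = learners, meta = meta,
                 member_names = names(specs), seed = seed),
            class = "pain_stacking")
}

#' @export
predict_proba.pain_stacking <- function(object, x, ...) {
  p <- vapply(object$learners, function(l) predict_proba(l, x),
              numeric(nrow(x)))
  colnames(p) <- object$member_names
  # collinear member probabilities make the meta-fit rank-deficient on
  # separable data; predictions remain well-defined
  as.vector(suppressWarnings(predict(object$meta, newdata = as.data.frame(p),
                                     type = "response")))
}

#' Stratified k-fold cross-validation
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param model_factory Function `(x, y) -> model` where the model supports
#'   [predict_proba()].
#' @param folds Number of folds (default 10).
#' @param seed Seed for the stratified fold assignment.
#' @param threshold Probability cutoff for hard labels (default 0.5).
#' @return An object of class `cv_result`: per-fold [metric_set()]s, fold
#'   membership, held-out predictions, and per-metric mean and SD.
#' @export
cross_validate <- function(x, y, model_factory, folds = 10, seed = 20240101,
                           threshold = 0.5) {
  fold <- stratified_folds(y, folds, seed)
  preds <- rep(NA_real_, length(y))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- model_factory(x[tr, , drop = FALSE], y[tr])
    p <- predict_proba(model, x[!tr, , drop = FALSE])
    preds[!tr] <- p
    per_fold[[f]] <- metric_set(
      confusion_from_predictions(y[!tr], as.integer(p >= threshold)))
  }
  m <- sapply(per_fold, function(ms) unlist(ms))
  structure(list(per_fold = per_fold, fold = fold, predictions = preds,
                 mean = rowMeans(m), sd = apply(m, 1, sd),
                 threshold = threshold),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV:  %s\n", length(x$per_fold),
              paste(sprintf("%s=%.4f+/-%.4f", toupper(names(x$mean)),
                            x$mean, x$sd), collapse = "  ")))
  invisible(x)
}

#' SHAP attribution matrix of a tree learner
#'
#' Exact tree-path (TreeSHAP) attributions on the margin scale, one row per
#' gene and one column per feature (the bias column is dropped).
#'
#' @param learner A fitted `pain_learner`.
#' @param x Feature matrix to explain.
#' @return Numeric matrix, `nrow(x)` by `length(feature_names)`.
#' @export
shap_matrix <- function(learner, x) {
  x <- x[, learner$feature_names, drop = FALSE]
  s <- predict(learner$booster, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
  s <- s[, seq_along(learner$feature_names), drop = FALSE]
  colnames(s) <- learner$feature_names
  s
}

#' Weight-normalized combination of per-learner SHAP matrices
#'
#' `combined = sum_k (w_k / sum(w)) S_k`. Feature importance is ranked by the
#' mean absolute combined attribution.
#'
#' @param shap_list List of SHAP matrices sharing shape and column order.
#' @param weights One non-negative weight per matrix.
#' @return List with `combined` (matrix) and `importance` (named numeric
#'   vector, decreasing).
#' @export
shap_weighted <- function(shap_list, weights) {
  dims <- lapply(shap_list, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop("SHAP matrices must share the same shape")
  }
  if (length(weights) != length(shap_list)) stop("one weight per matrix")
  w <- weights / sum(weights)
  combined <- Reduce(`+`, Map(function(s, wk) s * wk, shap_list, w))
  imp <- sort(colMeans(abs(combined)), decreasing = TRUE)
  list(combined = combined, importance = imp)
}

#' SHAP-guided backward feature elimination
#'
#' Starting from the full feature set, repeatedly: evaluate the
#' cross-validated objective, rank features by mean absolute SHAP of a model
#' fitted on the current set, and drop the least important feature — down to
#' a single feature. The selected subset maximizes the G-mean, with MCC as
#' tie-break.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param spec Learner used for evaluation and SHAP ranking (default the
#'   regularized gradient-boosted trees member).
#' @param folds CV folds per step (default 5).
#' @param seed Seed.
#' @param min_features Stop after reaching this many features (default 1).
#' @param order `"shap"` (default) drops the feature with the lowest mean
#'   absolute SHAP at each step; `"refit"` instead re-evaluates every
#'   leave-one-out candidate and drops the feature whose removal gives the
#'   best CV G-mean (much more expensive).
#' @return List with `selected` (feature names), `trajectory` (data frame of
#'   step, n_features, gm, mcc, dropped feature).
#' @export
backward_eliminate <- function(x, y, spec = base_learner_spec("xgbm"),
                               folds = 5, seed = 20240101, min_features = 1,
                               order = c("shap", "refit")) {
  order <- match.arg(order)
  if (ncol(x) < 2) stop("need at least two features")
  current <- colnames(x)
  steps <- list()
  subsets <- list()
  step <- 0
  while (length(current) >= max(1, min_features)) {
    step <- step + 1
    xs <- x[, current, drop = FALSE]
    res <- tryCatch({
      cv <- cross_validate(xs, y, function(xx, yy) fit_learner(xx, yy, spec),
                           folds = folds, seed = seed)
      c(gm = unname(cv$mean["gm"]), mcc = unname(cv$mean["mcc"]))
    }, error = function(e) c(gm = NA_real_, mcc = NA_real_))
    subsets[[step]] <- current
    drop_next <- NA_character_
    if (length(current) > max(1, min_features)) {
      if (order == "shap") {
        fit <- fit_learner(xs, y, spec)
        imp <- colMeans(abs(shap_matrix(fit, xs)))
        drop_next <- names(which.min(imp))
      } else {
        loo <- vapply(current, function(f) {
          tryCatch({
            cv <- cross_validate(xs[, setdiff(current, f), drop = FALSE], y,
                                 function(xx, yy) fit_learner(xx, yy, spec),
                                 folds = folds, seed = seed)
            unname(cv$mean["gm"])
          }, error = function(e) -Inf)
        }, numeric(1))
        drop_next <- names(which.max(loo))
      }
    }
    steps[[step]] <- data.frame(step = step, n_features = length(current),
                                gm = res["gm"], mcc = res["mcc"],
                                dropped_next = drop_next,
                                stringsAsFactors = FALSE)
    if (is.na(drop_next)) break
    current <- setdiff(current, drop_next)
  }
  traj <- do.call(rbind, steps)
  rownames(traj) <- NULL
  ok <- which(!is.na(traj$gm))
  if (length(ok) == 0) stop("objective undefined at every step")
  best <- ok[order(-traj$gm[ok], -traj$mcc[ok])][1]
  list(selected = subsets[[best]], trajectory = traj)
}

#' Seeded random-search hyperparameter tuner
#'
#' Draws parameter settings uniformly from the supplied ranges and keeps the
#' one maximizing the summed cross-validated GM + MCC + BA + F1.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param spec Base [base_learner_spec()] to perturb.
#' @param space Named list; each element is `c(lower, upper)` for a numeric
#'   parameter or a vector of candidate values for a discrete one (named with
#'   an `i_` prefix to force integer sampling).
#' @param budget Number of evaluated settings (default 20).
#' @param folds CV folds per evaluation (default 5).
#' @param seed Seed.
#' @return List with `spec` (tuned spec), `score`, and `trace`.
#' @export
tune_learner <- function(x, y, spec, space, budget = 20, folds = 5,
                         seed = 20240101) {
  set.seed(seed)
  draws <- lapply(seq_len(budget), function(i) {
    vals <- lapply(names(space), function(nm) {
      rg <- space[[nm]]
      v <- runif(1, min(rg), max(rg))
      if (startsWith(nm, "i_")) v <- round(v)
      v
    })
    names(vals) <- sub("^i_", "", names(space))
    vals
  })
  scores <- vapply(draws, function(p) {
    s <- spec
    s$params <- modifyList(s$params, p)
    cv <- cross_validate(x, y, function(xx, yy) fit_learner(xx, yy, s),
                         folds = folds, seed = seed)
    sum(cv$mean)
  }, numeric(1))
  best <- which.max(scores)
  tuned <- spec
  tuned$params <- modifyList(tuned$params, draws[[best]])
  list(spec = tuned, score = scores[best],
       trace = data.frame(draw = seq_len(budget), score = scores))
}

#' Write a model card JSON
#'
#' Records the member specifications, voting weights, seeds, feature names
#' and evaluation metrics of a fitted ensemble in a stable, reproducible
#' layout (no timestamps).
#'
#' @param model A `pain_voting` model.
#' @param metrics Optional named list of evaluation numbers to embed.
#' @param path Output JSON path.
#' @export
write_model_card <- function(model, metrics = NULL, path) {
  card <- list(
    model = "weighted soft-voting ensemble",
    members = lapply(model$learners, function(l) {
      list(family = l$spec$family, nrounds = l$spec$nrounds,
           seed = l$spec$seed, params = l$spec$params)
    }),
    weights = model$weights,
    member_order = model$member_names,
    tuning_gm = model$tuning_gm,
    seed = model$seed,
    features = model$learners[[1]]$feature_names,
    metrics = metrics
  )
  jsonlite::write_json(card, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
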