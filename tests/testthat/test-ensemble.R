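# small separable fixture: one informative feature plus noise
separable_data <- function(n = 120, seed = 5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(signal = y * 2 - 1 + 0, noise1 = rnorm(n), noise2 = rnorm(n))
  list(x = x, y = y)
}

test_that("every base learner separates a separable training set", {
  d <- separable_data()
  for (fam in c("xgbm", "gb", "ada", "rf")) {
    fit <- fit_learner(d$x, d$y, base_learner_spec(fam, seed = 1))
    p <- predict_proba(fit, d$x)
    expect_true(all(p >= 0 & p <= 1))
    m <- metric_set(confusion_from_predictions(d$y, as.integer(p >= 0.5)))
    expect_equal(m$gm, 1, info = fam)
  }
  expect_error(fit_learner(d$x, rep(1L, nrow(d$x)), base_learner_spec("xgbm")),
               "single class")
})

test_that("learners are deterministic under a fixed seed", {
  d <- separable_data(seed = 77)
  for (fam in c("xgbm", "ada", "rf")) {
    s <- base_learner_spec(fam, seed = 42)
    p1 <- predict_proba(fit_learner(d$x, d$y, s), d$x)
    p2 <- predict_proba(fit_learner(d$x, d$y, s), d$x)
    expect_identical(p1, p2, info = fam)
  }
})

test_that("null features give chance-level cross-validated performance", {
  set.seed(33)
  n <- 410
  y <- as.integer(seq_len(n) %in% sample(n, 10))
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  cv <- cross_validate(x, y, function(xx, yy)
    fit_learner(xx, yy, base_learner_spec("xgbm", nrounds = 30, seed = 2)),
    folds = 5, seed = 3)
  expect_lt(abs(cv$mean["ba"] - 0.5), 0.15)
})

test_that("soft voting is a weighted probability average", {
  p <- cbind(a = c(0.2, 0.9), b = c(0.8, 0.1))
  expect_equal(soft_vote(p, c(1, 3)), c(0.65, 0.3))
  # identical learners: any weights reproduce the input
  q <- cbind(x = c(0.3, 0.6), y = c(0.3, 0.6))
  expect_equal(soft_vote(q, c(5, 2)), c(0.3, 0.6))
  # the published configuration [4,2,1,3] as a hand-computed weighted mean
  probs <- cbind(c(0.9, 0.2), c(0.5, 0.5), c(0.1, 0.9), c(0.7, 0.4))
  w <- c(4, 2, 1, 3)
  expect_equal(soft_vote(probs, w), as.vector(probs %*% w) / 10)
  # invariance under positive rescaling
  expect_equal(soft_vote(probs, w * 7.3), soft_vote(probs, w))
  expect_error(soft_vote(probs, c(0, 0, 0, 0)), "positive sum")
  expect_error(soft_vote(probs, c(1, 2)), "one weight per learner")
})

test_that("weight search equals exhaustive brute force on random fixtures", {
  set.seed(64)
  for (rep in 1:20) {
    n <- 60
    truth <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
    probas <- matrix(runif(n * 4), n, 4)
    got <- weight_search(probas, truth, c(4, 2, 1, 3))
    want <- oracle_weight_search(probas, truth, c(4, 2, 1, 3))
    expect_equal(got$gm, want$gm, tolerance = 1e-12)
    expect_equal(nrow(got$trace), 24)
    # output GM dominates every tested permutation
    expect_true(all(got$gm >= got$trace$gm - 1e-12))
  }
})

test_that("weight search assigns the large weight to the better learner", {
  truth <- rep(c(1, 0), each = 10)
  perfect <- c(rep(0.9, 10), rep(0.1, 10))
  anti <- 1 - perfect
  got <- weight_search(cbind(perfect, anti), truth, c(4, 1))
  expect_equal(got$weights, c(4, 1))
  expect_equal(got$gm, 1)
  # single learner: the single weight, trivially
  one <- weight_search(cbind(perfect), truth, 4)
  expect_equal(one$weights, 4)
})

test_that("stacking handles constant and complementary base learners", {
  d <- separable_data(seed = 13)
  st <- fit_stacking(d$x, d$y, default_learner_specs(seed = 1),
                     meta_folds = 3, seed = 2)
  p <- predict_proba(st, d$x)
  m <- metric_set(confusion_from_predictions(d$y, as.integer(p >= 0.5)))
  expect_equal(m$gm, 1)

  # XOR-style planted interaction: single stumps fail, stacking of the four
  # members (which include deep learners) recovers it
  set.seed(71)
  n <- 300
  a <- sample(0:1, n, TRUE)
  b <- sample(0:1, n, TRUE)
  y <- as.integer(xor(a, b))
  x <- cbind(a = a + rnorm(n, sd = 0.05), b = b + rnorm(n, sd = 0.05))
  st2 <- fit_stacking(x, y, default_learner_specs(seed = 3), meta_folds = 3,
                      seed = 4)
  p2 <- predict_proba(st2, x)
  m2 <- metric_set(confusion_from_predictions(y, as.integer(p2 >= 0.5)))
  expect_gt(m2$gm, 0.9)
})

test_that("cross-validation metrics recompute exactly from stored predictions", {
  d <- separable_data(n = 200, seed = 6)
  cv <- cross_validate(d$x, d$y, function(xx, yy)
    fit_learner(xx, yy, base_learner_spec("xgbm", nrounds = 20, seed = 5)),
    folds = 10, seed = 11)
  expect_length(cv$per_fold, 10)
  for (f in seq_len(10)) {
    held <- cv$fold == f
    rec <- metric_set(confusion_from_predictions(
      d$y[held], as.integer(cv$predictions[held] >= cv$threshold)))
    expect_identical(unclass(rec), unclass(cv$per_fold[[f]]))
  }
  # mean/SD recompute from the fold list
  gms <- vapply(cv$per_fold, function(m) m$gm, 0)
  expect_equal(unname(cv$mean["gm"]), mean(gms))
  expect_equal(unname(cv$sd["gm"]), sd(gms))
  # reproducible fold assignment
  cv2 <- cross_validate(d$x, d$y, function(xx, yy)
    fit_learner(xx, yy, base_learner_spec("xgbm", nrounds = 20, seed = 5)),
    folds = 10, seed = 11)
  expect_identical(cv$fold, cv2$fold)
  expect_error(cross_validate(d$x, rep(c(0L, 1L), c(195, 5)),
                              function(xx, yy) NULL, folds = 10, seed = 1),
               "fewer positives than folds")
})

test_that("weighted SHAP combination is the weight-normalized sum", {
  s1 <- matrix(1:6, 3, 2, dimnames = list(NULL, c("a", "b")))
  s2 <- matrix(c(2, 0, 4, 0, 6, 0), 3, 2, dimnames = list(NULL, c("a", "b")))
  # equal matrices: combination reproduces them
  eq <- shap_weighted(list(s1, s1), c(3, 9))
  expect_equal(eq$combined, s1)
  # weight (1, 0): first matrix only
  first <- shap_weighted(list(s1, s2), c(1, 0))
  expect_equal(first$combined, s1)
  # hand-computed weighted mean at weights (4, 2)
  got <- shap_weighted(list(s1, s2), c(4, 2))
  expect_equal(got$combined, (4 / 6) * s1 + (2 / 6) * s2)
  expect_equal(names(got$importance),
               names(sort(colMeans(abs(got$combined)), decreasing = TRUE)))
  expect_error(shap_weighted(list(s1, s2[1:2, ]), c(1, 1)), "shape")
})

test_that("SHAP attributions sum to the margin prediction", {
  d <- separable_data(seed = 23)
  fit <- fit_learner(d$x, d$y, base_learner_spec("xgbm", nrounds = 20, seed = 1))
  s <- shap_matrix(fit, d$x)
  expect_equal(dim(s), dim(d$x))
  full <- predict(fit$booster, xgboost::xgb.DMatrix(d$x), predcontrib = TRUE)
  margin <- predict(fit$booster, xgboost::xgb.DMatrix(d$x), outputmargin = TRUE)
  expect_equal(unname(rowSums(full)), unname(margin), tolerance = 1e-5)
})

test_that("backward elimination keeps the planted informative feature", {
  set.seed(17)
  n <- 240
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(informative = y + rnorm(n, sd = 0.3),
             junk1 = rnorm(n), junk2 = rnorm(n), junk3 = rnorm(n))
  be <- backward_eliminate(x, y,
                           base_learner_spec("xgbm", nrounds = 30, seed = 2),
                           folds = 3, seed = 7)
  expect_true("informative" %in% be$selected)
  # trajectory is monotone in feature count and covers every step
  expect_equal(be$trajectory$n_features, seq(ncol(x), 1))
  # the returned subset attains the trajectory maximum (GM, tie-break MCC)
  best_gm <- max(be$trajectory$gm, na.rm = TRUE)
  sel_row <- be$trajectory[be$trajectory$n_features == length(be$selected), ]
  expect_equal(sel_row$gm, best_gm)

  # the leave-one-out refit variant also keeps the informative feature
  be2 <- backward_eliminate(x[, 1:3], y,
                            base_learner_spec("xgbm", nrounds = 20, seed = 2),
                            folds = 3, seed = 7, order = "refit")
  expect_true("informative" %in% be2$selected)
})

test_that("random-search tuner improves the summed objective deterministically", {
  d <- separable_data(n = 160, seed = 31)
  spec <- base_learner_spec("xgbm", nrounds = 15, seed = 1)
  t1 <- tune_learner(d$x, d$y, spec,
                     space = list(eta = c(0.05, 0.5), i_max_depth = c(2, 5)),
                     budget = 4, folds = 3, seed = 19)
  t2 <- tune_learner(d$x, d$y, spec,
                     space = list(eta = c(0.05, 0.5), i_max_depth = c(2, 5)),
                     budget = 4, folds = 3, seed = 19)
  expect_equal(t1$trace, t2$trace)
  expect_true(all(t1$score >= t1$trace$score - 1e-12))
  expect_true(t1$spec$params$max_depth %in% 2:5)
})

test_that("voting ensemble: fitted weights and model card round-trip", {
  d <- separable_data(n = 200, seed = 55)
  v <- fit_voting(d$x, d$y, default_learner_specs(seed = 9), tune_folds = 3,
                  seed = 10)
  expect_setequal(v$weights, c(4, 2, 1, 3))
  p <- predict_proba(v, d$x)
  expect_true(all(p >= 0 & p <= 1))
  tf <- tempfile(fileext = ".json")
  write_model_card(v, metrics = list(gm = 1), path = tf)
  card <- jsonlite::read_json(tf)
  expect_equal(unlist(card$weights), v$weights)
  expect_equal(card$member_order, list("xgbm", "gb", "ada", "rf"))
})
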