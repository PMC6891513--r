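test_that("2:1 split gives round(2N/3) calibration records, reproducibly", {
  s <- split_dataset(26, seed = 1)
  expect_length(s$calibration, 17L)
  expect_length(s$prediction, 9L)
  expect_setequal(c(s$calibration, s$prediction), 1:26)
  expect_identical(split_dataset(26, seed = 1), split_dataset(26, seed = 1))
  expect_false(identical(split_dataset(26, seed = 1)$calibration,
                         split_dataset(26, seed = 2)$calibration))
  s3 <- split_dataset(3, seed = 5)
  expect_length(s3$calibration, 2L)
  expect_length(s3$prediction, 1L)
  expect_error(split_dataset(2, seed = 1), "at least 3")
})

test_that("PLS fits a noiseless rank-1 relation exactly", {
  x <- matrix(seq(-3, 3, length.out = 12), ncol = 1)
  y <- as.numeric(2 * x)
  m <- fit_pls(x, y, 1)
  expect_equal(predict(m, x), y, tolerance = 1e-10)
  expect_equal(m$coefficients, 2, tolerance = 1e-10)
})

test_that("PLS at full rank equals ordinary least squares", {
  set.seed(101)
  for (i in 1:10) {
    X <- matrix(rnorm(8 * 3), 8, 3)
    y <- rnorm(8)
    m <- fit_pls(X, y, 3)
    ols <- unname(coef(lm(y ~ X)))
    expect_equal(m$intercept, ols[1], tolerance = 1e-8)
    expect_equal(unname(m$coefficients), ols[-1], tolerance = 1e-8)
  }
})

test_that("PLS scores are orthogonal and coefficients reproduce the deflation path", {
  set.seed(7)
  X <- matrix(rnorm(15 * 6), 15, 6)
  y <- rnorm(15)
  m <- fit_pls(X, y, 4)
  G <- crossprod(m$scores)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  # prediction through the score-space recursion: accumulate t_a * q_a
  Xs <- sweep(sweep(X, 2, m$x_center), 2, m$x_scale, "/")
  Xd <- Xs
  yhat_s <- numeric(nrow(X))
  for (a in seq_len(m$ncomp)) {
    tt <- Xd %*% m$weights[, a]
    yhat_s <- yhat_s + as.numeric(tt) * m$y_loadings[a]
    Xd <- Xd - tt %*% t(m$x_loadings[, a])
  }
  yhat <- m$y_center + m$y_scale * yhat_s
  expect_equal(predict(m, X), yhat, tolerance = 1e-10)
})

test_that("degenerate fits are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(X, rep(1, 10), 1), "zero variance")
  expect_error(fit_pls(X, rnorm(10), 3), "ncomp")
  m <- fit_pls(X, rnorm(10), 2)
  expect_error(predict(m, matrix(0, 1, 3)), "columns")
})

test_that("prediction at the column means returns the response mean", {
  set.seed(13)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  m <- fit_pls(X, y, 2)
  expect_equal(predict(m, m$x_center), mean(y), tolerance = 1e-10)
  expect_equal(predict(m, X), m$fitted, tolerance = 1e-12)
})

test_that("LOO Q2 equals the literal delete-one-refit loop", {
  set.seed(19)
  X <- matrix(rnorm(10 * 4), 10, 4)
  y <- rnorm(10)
  for (A in 1:3) {
    got <- loo_q2(X, y, A)
    yhat <- vapply(1:10, function(i) {
      predict(fit_pls(X[-i, ], y[-i], A), X[i, , drop = FALSE])
    }, numeric(1))
    press <- sum((y - yhat)^2)
    expect_equal(got$yhat_loo, yhat, tolerance = 1e-12)
    expect_equal(got$press, press, tolerance = 1e-12)
    expect_equal(got$q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-12)
    expect_lte(got$q2, 1)
  }
})

test_that("Q2 reaches 1 on noiseless linear data and stays <= 1 on noise", {
  set.seed(29)
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- as.numeric(X %*% c(1, -2, 0.5)) + 3
  expect_equal(loo_q2(X, y, 3)$q2, 1, tolerance = 1e-8)
  # pure noise: Q2 typically negative, never above 1
  yn <- rnorm(12)
  q2n <- loo_q2(X, yn, 2)$q2
  expect_lte(q2n, 1)
})

test_that("calibration R2 is non-decreasing in the number of components", {
  set.seed(37)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- rnorm(20)
  r2 <- vapply(1:8, function(a) {
    f <- fit_pls(X, y, a)
    1 - sum((y - f$fitted)^2) / sum((y - mean(y))^2)
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("component selection maximizes LOO Q2 and respects feasibility caps", {
  x <- matrix(seq_len(12) + 0, ncol = 1)
  y <- as.numeric(3 * x) - 1
  expect_equal(select_components(cbind(x, x[, 1] * 2), y)$ncomp, 1L)
  set.seed(41)
  X <- matrix(rnorm(10 * 4), 10, 4)
  yy <- rnorm(10)
  sel <- select_components(X, yy, a_max = 20)
  expect_length(sel$q2, 4L)  # capped at min(a_max, n - 2, p)
  expect_equal(sel$q2, vapply(1:4, function(a) loo_q2(X, yy, a)$q2, numeric(1)))
  expect_equal(sel$ncomp, which.max(sel$q2))
})

test_that("evaluate_qsar reports exact fits on noiseless synthetic data", {
  # p = 10 features so the feasible component range reaches full rank
  d <- gen_peptide_dataset(n = 30, length_range = c(4, 12),
                           spec = encoding_spec(1, 1), noise_sd = 0, seed = 3)
  rep <- evaluate_qsar(d$records, spec = encoding_spec(1, 1), seed = 9,
                       a_max = 10)
  expect_gt(rep$r2_calibration, 0.999)
  expect_gt(rep$q2_loo, 0.99)
  expect_lt(rep$rmse_prediction, 0.05 * sd(d$records$activity))
  expect_true(rep$pass_flag)
})

test_that("prediction-set RMSE matches direct recomputation of held-out residuals", {
  recs <- orac_peptides()
  rep <- evaluate_qsar(recs, seed = 4)
  hold <- rep$predictions[rep$predictions$set == "prediction", ]
  expect_equal(rep$rmse_prediction,
               sqrt(mean((hold$observed - hold$predicted)^2)),
               tolerance = 1e-12)
  cal <- rep$predictions[rep$predictions$set == "calibration", ]
  expect_equal(rep$r2_calibration,
               1 - sum((cal$observed - cal$predicted)^2) /
                 sum((cal$observed - mean(cal$observed))^2),
               tolerance = 1e-12)
})

test_that("the full pipeline is bit-reproducible for a fixed seed", {
  recs <- orac_peptides()
  r1 <- evaluate_qsar(recs, seed = 8)
  r2 <- evaluate_qsar(recs, seed = 8)
  expect_identical(r1$split, r2$split)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$r2_calibration, r2$r2_calibration)
  expect_identical(r1$q2_loo, r2$q2_loo)
})

test_that("PLS predictions agree with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  recs <- orac_peptides()
  X <- encode_set(recs$sequence, encoding_spec(), load_scale())
  colnames(X) <- paste0("v", seq_len(ncol(X)))
  y <- recs$activity
  m <- fit_pls(X, y, 3)
  ref <- mixOmics::pls(as.data.frame(X), y, ncomp = 3, mode = "regression",
                       scale = TRUE)
  ref_pred <- predict(ref, as.data.frame(X))$predict[, 1, 3]
  expect_equal(unname(predict(m, X)), unname(ref_pred), tolerance = 1e-10)
})

test_that("ranking sorts by predicted activity with deterministic tie-breaks", {
  recs <- orac_peptides()
  rep <- evaluate_qsar(recs, seed = 1)
  cand <- c("AGYSPIGFVR", "VLDELTLAR", "LFDPVYLFDQG")
  rk <- rank_peptides(rep$model, encoding_spec(), load_scale(), cand)
  expect_equal(rk$rank, 1:3)
  expect_true(all(diff(rk$predicted_activity) <= 0))
  # invariant to input order
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_identical(rank_peptides(rep$model, encoding_spec(), load_scale(),
                                   cand[perm]), rk)
  }
  one <- rank_peptides(rep$model, encoding_spec(), load_scale(), "WY")
  expect_equal(one$rank, 1L)
  # exact ties break lexicographically
  tie <- rank_peptides(rep$model, encoding_spec(), load_scale(),
                       c("WY", "WY"))
  expect_equal(tie$sequence, c("WY", "WY"))
  expect_error(rank_peptides(rep$model, encoding_spec(), load_scale(),
                             character(0)), "no sequences")
})
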