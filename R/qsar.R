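#' Random 2:1 calibration/prediction split
#'
#' Randomly assigns records to a calibration set and a prediction (hold-out)
#' set. Under the default 2:1 ratio the calibration set holds `round(2N/3)`
#' records. The assignment is a pure function of `seed`.
#'
#' @param n Number of records, or a data frame of records (its row count is
#'   used).
#' @param ratio Calibration proportion (default 2/3 for a 2:1 split).
#' @param seed Integer RNG seed; required so the split is reproducible.
#' @return List with integer index vectors `calibration` and `prediction`,
#'   plus `seed` and `ratio`.
#' @export
split_dataset <- function(n, ratio = 2 / 3, seed) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n)
  if (n < 3L) stop("need at least 3 records to split")
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be in (0, 1)")
  n_cal <- round(n * ratio)
  n_cal <- max(1L, min(n - 1L, as.integer(n_cal)))
  idx <- with_seed(seed, sample.int(n, n_cal))
  list(calibration = sort(idx),
       prediction = setdiff(seq_len(n), idx),
       seed = as.integer(seed), ratio = ratio)
}

#' Fit a PLS1 regression model by NIPALS
#'
#' Partial least squares with a single response, fitted by the NIPALS
#' algorithm: X and y are autoscaled (centered, unit variance; columns with
#' zero variance get scale 1 and hence zero weight), then for each latent
#' component a weight vector `w` proportional to `X'y` is extracted, scores
#' `t = Xw` computed, and X and y deflated by the rank-one approximations
#' `t p'` and `t q`. Regression coefficients are back-transformed to the
#' original units.
#'
#' @param X Numeric n x p design matrix.
#' @param y Numeric response of length n.
#' @param ncomp Number of latent components A, `1 <= A <= min(n - 1, p)`.
#' @return A `pls_model` with autoscaling parameters, `weights` W (p x A),
#'   `x_loadings` P, `y_loadings` q, `scores` T, `coefficients` (original
#'   units) and `intercept`.
#' @export
fit_pls <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, p)) {
    stop(sprintf("ncomp must be in 1..min(n-1, p) = %d", min(n - 1L, p)))
  }
  if (stats::sd(y) == 0) stop("response has zero variance")

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  y_center <- mean(y); y_scale <- stats::sd(y)
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale

  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  Xd <- Xs; yd <- ys
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.75) {
      # residual X carries no covariance with y; truncate
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1L), drop = FALSE]
      q <- q[seq_len(a - 1L)]
      ncomp <- a - 1L
      break
    }
    w <- w / nw
    tt <- Xd %*% w
    tt2 <- sum(tt^2)
    pp <- crossprod(Xd, tt) / tt2
    qq <- sum(tt * yd) / tt2
    Xd <- Xd - tt %*% t(pp)
    yd <- yd - qq * tt
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; q[a] <- qq
  }
  if (ncomp == 0L) stop("no usable PLS component: X carries no covariance with y")

  # b_scaled = W (P'W)^-1 q ; back-transform to original units
  b_scaled <- W %*% solve(crossprod(P, W), q)
  coefficients <- as.numeric(b_scaled) * y_scale / x_scale
  intercept <- y_center - sum(coefficients * x_center)

  model <- structure(
    list(ncomp = ncomp, x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale,
         weights = W, x_loadings = P, y_loadings = q, scores = Tm,
         coefficients = coefficients, intercept = intercept),
    class = "pls_model"
  )
  model$fitted <- predict(model, X)
  model
}

#' Predict activities from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Numeric matrix (or vector for a single observation) with
#'   the same number of columns the model was fit on.
#' @param ... Unused.
#' @return Numeric vector of predicted activities.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != length(object$coefficients)) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(X), length(object$coefficients)))
  }
  as.numeric(object$intercept + X %*% object$coefficients)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d component(s), %d predictors>\n",
              x$ncomp, length(x$coefficients)))
  invisible(x)
}

#' Leave-one-out cross-validation Q2
#'
#' For each record i the model is refit without it (autoscaling recomputed on
#' the reduced data) and record i is predicted; `Q2 = 1 - PRESS / SS_tot`
#' where `PRESS = sum((y_i - yhat_(-i))^2)` and `SS_tot = sum((y_i - mean(y))^2)`.
#'
#' @inheritParams fit_pls
#' @return List with `q2`, `press`, and the LOO predictions `yhat_loo`.
#' @export
loo_q2 <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 records for leave-one-out validation")
  if (ncomp > min(n - 2L, ncol(X))) {
    stop(sprintf("ncomp = %d infeasible for leave-one-out on %d records", ncomp, n))
  }
  yhat <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], ncomp)
    yhat[i] <- predict(fit, X[i, , drop = FALSE])
  }
  press <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(q2 = 1 - press / ss_tot, press = press, yhat_loo = yhat)
}

#' Select the number of PLS components by leave-one-out Q2
#'
#' Scans `A = 1..A_max` and returns the component count maximizing Q2, with
#' ties broken toward the smaller model. `A_max` is capped at
#' `min(a_max, n - 2, p)`.
#'
#' @inheritParams fit_pls
#' @param a_max Largest component count to consider (default 10).
#' @return List with `ncomp` (selected A) and `q2` (per-A Q2 values).
#' @export
select_components <- function(X, y, a_max = 10L) {
  X <- as.matrix(X)
  cap <- min(as.integer(a_max), nrow(X) - 2L, ncol(X))
  if (cap < 1L) stop("no feasible component count")
  q2 <- vapply(seq_len(cap), function(a) loo_q2(X, y, a)$q2, numeric(1))
  list(ncomp = which.max(q2), q2 = q2)
}

#' Calibrate and validate a QSAR model on a peptide activity table
#'
#' Runs the full QSAR protocol: encode the sequences, split calibration vs
#' prediction, select the component count by leave-one-out Q2 on the
#' calibration set (unless `ncomp` is given), fit PLS, and report calibration
#' R2, LOO Q2, and root mean square errors on both sets. The pass flag
#' follows the correlation-coefficient criterion R > 0.6 and Q > 0.5, i.e.
#' `sqrt(R2) > 0.6` and `sqrt(Q2) > 0.5` (Q2 must be positive); R2 and Q2 are
#' reported so the stricter bounds R2 > 0.9, Q2 > 0.5 can be read directly.
#'
#' @param records Data frame with columns `sequence` and `activity`.
#' @param spec An [encoding_spec()].
#' @param scale A [load_scale()] descriptor scale.
#' @param seed Integer seed controlling the random split.
#' @param ratio Calibration proportion (default 2:1, i.e. 2/3).
#' @param ncomp `"auto"` (LOO-Q2 maximizing) or a fixed integer.
#' @param a_max Cap on components scanned when `ncomp = "auto"`.
#' @return A `validation_report`: r2_calibration, q2_loo, rmse_calibration,
#'   rmse_prediction, n_components, pass_flag, the split, the fitted
#'   `pls_model`, and a per-record table of observed vs predicted values.
#' @export
evaluate_qsar <- function(records, spec = encoding_spec(), scale = load_scale(),
                          seed, ratio = 2 / 3, ncomp = "auto", a_max = 10L) {
  stopifnot(is.data.frame(records), all(c("sequence", "activity") %in% names(records)))
  X <- encode_set(records$sequence, spec, scale)
  y <- as.numeric(records$activity)
  split <- split_dataset(nrow(records), ratio = ratio, seed = seed)
  Xc <- X[split$calibration, , drop = FALSE]
  yc <- y[split$calibration]
  Xp <- X[split$prediction, , drop = FALSE]
  yp <- y[split$prediction]
  if (stats::sd(yc) == 0) stop("degenerate calibration set: constant activity")

  if (identical(ncomp, "auto")) {
    sel <- select_components(Xc, yc, a_max = a_max)
    A <- sel$ncomp
  } else {
    A <- as.integer(ncomp)
  }
  model <- fit_pls(Xc, yc, A)
  fit_c <- predict(model, Xc)
  fit_p <- predict(model, Xp)
  loo <- loo_q2(Xc, yc, A)

  r2 <- 1 - sum((yc - fit_c)^2) / sum((yc - mean(yc))^2)
  q2 <- loo$q2
  rmsec <- sqrt(mean((yc - fit_c)^2))
  rmsep <- sqrt(mean((yp - fit_p)^2))
  pass <- (r2 > 0) && (q2 > 0) && (sqrt(r2) > 0.6) && (sqrt(q2) > 0.5)

  pred_tab <- data.frame(
    sequence = c(records$sequence[split$calibration],
                 records$sequence[split$prediction]),
    set = rep(c("calibration", "prediction"),
              c(length(split$calibration), length(split$prediction))),
    observed = c(yc, yp),
    predicted = c(fit_c, fit_p),
    stringsAsFactors = FALSE
  )
  structure(
    list(r2_calibration = r2, q2_loo = q2,
         rmse_calibration = rmsec, rmse_prediction = rmsep,
         n_components = model$ncomp, pass_flag = pass,
         seed = as.integer(seed), split = split, model = model,
         predictions = pred_tab),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    paste0("QSAR validation (seed %d, %d components)\n",
           "  R2 (calibration)  %.4f\n  Q2 (LOO)          %.4f\n",
           "  RMSE calibration  %.4f\n  RMSE prediction   %.4f\n",
           "  criterion R > 0.6 & Q > 0.5: %s\n"),
    x$seed, x$n_components, x$r2_calibration, x$q2_loo,
    x$rmse_calibration, x$rmse_prediction,
    if (x$pass_flag) "pass" else "fail"))
  invisible(x)
}

#' Rank candidate peptides by predicted activity
#'
#' @param model A fitted `pls_model`.
#' @param spec,scale Encoding specification and descriptor scale; must match
#'   those used to fit the model.
#' @param sequences Character vector of candidate peptides.
#' @return Data frame (sequence, predicted_activity, rank) sorted by
#'   decreasing predicted activity; ties break lexicographically by sequence.
#' @export
rank_peptides <- function(model, spec, scale, sequences) {
  if (length(sequences) == 0L) stop("no sequences to rank")
  seqs <- vapply(sequences, validate_sequence, character(1), USE.NAMES = FALSE)
  X <- encode_set(seqs, spec, scale)
  pred <- predict(model, X)
  ord <- order(-pred, seqs)
  data.frame(sequence = seqs[ord],
             predicted_activity = pred[ord],
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

# run expr under a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
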