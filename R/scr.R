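#' Configuration for self-consistent regression
#'
#' @param t_threshold Significance threshold on |coefficient|/SE below
#'   which a variable is eliminated (default 2.0).
#' @param lambda_grid Ridge values searched by leave-one-out Q2 on the
#'   standardised design (default a log grid 1e-6..1e2).
#' @param rbf_ridge Ridge added to the RBF kernel system.  NULL (the
#'   default) selects it by leave-one-out PRESS over a log grid
#'   1e-8..10; a numeric value (e.g. a negligible 1e-12, under which
#'   the interpolant reproduces the training responses) is used as
#'   given.
#' @return List of class `scr_config`.
#' @export
scr_config <- function(t_threshold = 2.0,
                       lambda_grid = 10^seq(-6, 2, by = 1),
                       rbf_ridge = NULL) {
  structure(list(t_threshold = t_threshold, lambda_grid = lambda_grid,
                 rbf_ridge = rbf_ridge), class = "scr_config")
}

standardise_design <- function(X, y) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sdx <- sqrt(colMeans(Xc^2))
  keep <- which(sdx > 1e-12)
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, sdx[keep], "/")
  list(Xs = Xs, yc = y - mean(y), ybar = mean(y),
       ctr = ctr[keep], sdx = sdx[keep], keep = keep,
       dropped_constant = colnames(X)[setdiff(seq_len(ncol(X)), keep)])
}

# Ridge fit of one candidate subset with leave-one-out lambda selection.
# One economy SVD yields, for every lambda in the grid, the coefficients,
# hat diagonal (hence LOO residuals) and the diagonal of the sandwich
# (X'X+lI)^-1 X'X (X'X+lI)^-1 needed for coefficient SEs.  The error
# variance is estimated from the LOO PRESS, which stays honest when the
# candidate count approaches or exceeds the sample size.
ridge_loo_fit <- function(Xs, yc, lambdas) {
  n <- nrow(Xs)
  sv <- svd(Xs)
  pos <- sv$d > max(sv$d) * 1e-12
  u <- sv$u[, pos, drop = FALSE]
  v <- sv$v[, pos, drop = FALSE]
  d <- sv$d[pos]
  uy <- as.numeric(crossprod(u, yc))
  ss_tot <- sum(yc^2)
  best <- NULL
  fallback <- NULL
  for (lam in lambdas) {
    shrink <- d^2 / (d^2 + lam)
    fitted <- as.numeric(u %*% (shrink * uy))
    h <- rowSums(sweep(u^2, 2, shrink, "*"))
    loo <- (yc - fitted) / pmax(1 - h, 1e-8)
    press <- sum(loo^2)
    cand <- list(lam = lam, press = press, shrink = shrink, fitted = fitted)
    # keep at least 10% residual degrees of freedom: near-interpolating
    # fits make the LOO shortcut arbitrarily optimistic
    if (sum(shrink) <= 0.9 * n) {
      if (is.null(best) || press < best$press) best <- cand
    }
    if (is.null(fallback) || press < fallback$press) fallback <- cand
  }
  if (is.null(best)) best <- fallback
  lam <- best$lam
  b <- as.numeric(v %*% (d / (d^2 + lam) * uy))
  rss <- max(0, sum((yc - best$fitted)^2))
  sigma2 <- best$press / max(n - 1, 1)
  var_b <- sigma2 * rowSums(sweep(v^2, 2, d^2 / (d^2 + lam)^2, "*"))
  tval <- b / sqrt(pmax(var_b, 0))
  bad <- !is.finite(tval)
  tval[bad] <- ifelse(abs(b[bad]) > 1e-10, Inf, 0)
  list(b = b, rss = rss, t = tval, lam = lam,
       q2_loo = 1 - best$press / ss_tot)
}

#' Fit one partial model by self-consistent regression
#'
#' Ridge-regularised least squares with iterative elimination: the ridge
#' value is chosen once by maximising leave-one-out Q2 over
#' `config$lambda_grid` on the standardised candidate design, then the
#' variable whose |coefficient|/SE is smallest and below
#' `config$t_threshold` is dropped and the model refitted, until every
#' retained variable is significant (the self-consistency condition).
#' Deterministic given its inputs.
#'
#' @param X Numeric matrix with named columns (candidate descriptors).
#' @param y Response vector, length = nrow(X) >= 5.
#' @param config An [scr_config()].
#' @return Object of class `scr_model`: selected `variables`, `coef` and
#'   `intercept` on the original descriptor scale, `t_values`, `lambda`,
#'   training `r2`, and a `degenerate` flag when every variable was
#'   eliminated (intercept-only model).
#' @export
fit_scr <- function(X, y, config = scr_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have named columns")
  n <- nrow(X)
  if (n != length(y)) stop("rows(X) != length(y)")
  if (n < 5L) stop("need at least 5 observations")
  sd0 <- standardise_design(X, y)
  Xs <- sd0$Xs; yc <- sd0$yc
  p <- ncol(Xs)
  if (p == 0L) {
    return(structure(list(method = "SCR", variables = character(0),
                          coef = numeric(0), intercept = sd0$ybar,
                          t_values = numeric(0), lambda = NA_real_,
                          r2 = 0, degenerate = TRUE), class = "scr_model"))
  }
  yty <- sum(yc^2)
  S <- seq_len(p)
  fit <- ridge_loo_fit(Xs, yc, config$lambda_grid)
  repeat {
    below <- which(abs(fit$t) < config$t_threshold)
    if (!length(below) || !length(S)) break
    # clearly insignificant variables (below half the threshold) are
    # removed together; near the threshold the least significant one is
    # removed at a time, so the retained set is the same as a strict
    # one-by-one elimination would give in all but pathological ties
    hopeless <- below[abs(fit$t)[below] < config$t_threshold / 2]
    drop_k <- if (length(hopeless) > 1L) hopeless
              else below[which.min(abs(fit$t)[below])]
    S <- S[-drop_k]
    if (!length(S)) break
    fit <- ridge_loo_fit(Xs[, S, drop = FALSE], yc, config$lambda_grid)
  }
  if (!length(S)) {
    return(structure(list(method = "SCR", variables = character(0),
                          coef = numeric(0), intercept = sd0$ybar,
                          t_values = numeric(0), lambda = NA_real_,
                          r2 = 0, degenerate = TRUE), class = "scr_model"))
  }
  vars <- colnames(Xs)[S]
  coef_orig <- fit$b / sd0$sdx[S]
  names(coef_orig) <- vars
  intercept <- sd0$ybar - sum(coef_orig * sd0$ctr[S])
  r2 <- 1 - fit$rss / yty
  structure(list(method = "SCR", variables = vars, coef = coef_orig,
                 intercept = intercept,
                 t_values = stats::setNames(fit$t, vars),
                 lambda = fit$lam, r2 = r2, degenerate = FALSE),
            class = "scr_model")
}

#' @export
predict.scr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!length(object$variables)) {
    return(rep(object$intercept, nrow(newdata)))
  }
  missing <- setdiff(object$variables, colnames(newdata))
  if (length(missing)) stop("newdata lacks columns: ",
                            paste(missing, collapse = ", "))
  as.numeric(newdata[, object$variables, drop = FALSE] %*% object$coef) +
    object$intercept
}

#' Fit one partial model by RBF-SCR
#'
#' The variable-selection stage is exactly [fit_scr()]; a Gaussian
#' radial-basis interpolant is then fitted to the response in the
#' selected-variable subspace (standardised by the training SDs):
#' centres are the training points, the kernel width is the median
#' pairwise distance (falling back to the mean distance, flagged, if the
#' median is zero), and the linear system is ridge-stabilised by
#' `config$rbf_ridge`.
#'
#' @inheritParams fit_scr
#' @return Object of class `rbf_scr_model`: the SCR-selected
#'   `variables`, `centers`, `weights`, `width`, standardisation info,
#'   and training `r2`.
#' @export
fit_rbf_scr <- function(X, y, config = scr_config()) {
  sel <- fit_scr(X, y, config)
  vars <- sel$variables
  n <- nrow(X)
  if (!length(vars)) {
    return(structure(list(method = "RBF-SCR", variables = character(0),
                          ybar = mean(y), r2 = 0, degenerate = TRUE,
                          selection = sel), class = "rbf_scr_model"))
  }
  Z <- as.matrix(X[, vars, drop = FALSE])
  ctr <- colMeans(Z); sdz <- apply(Z, 2, stats::sd)
  sdz[sdz < 1e-12] <- 1
  Zs <- sweep(sweep(Z, 2, ctr), 2, sdz, "/")
  D <- as.matrix(stats::dist(Zs))
  dvals <- D[upper.tri(D)]
  width <- stats::median(dvals)
  width_fallback <- FALSE
  if (!is.finite(width) || width <= 0) {
    width <- mean(dvals)
    width_fallback <- TRUE
    if (!is.finite(width) || width <= 0) width <- 1
  }
  K <- exp(-D^2 / (2 * width^2))
  ybar <- mean(y)
  ridge <- config$rbf_ridge
  if (is.null(ridge)) ridge <- rbf_loo_ridge(K, y - ybar)
  w <- solve(K + diag(ridge, n), y - ybar)
  fitted <- as.numeric(K %*% w) + ybar
  r2 <- 1 - sum((y - fitted)^2) / sum((y - ybar)^2)
  structure(list(method = "RBF-SCR", variables = vars, centers = Zs,
                 weights = as.numeric(w), width = width, ybar = ybar,
                 ctr = ctr, sdz = sdz, r2 = r2,
                 width_fallback = width_fallback, degenerate = FALSE,
                 lambda = ridge, selection = sel),
            class = "rbf_scr_model")
}

# LOO-PRESS choice of the kernel ridge, via one eigendecomposition
rbf_loo_ridge <- function(K, y0, grid = 10^seq(-8, 1, by = 1)) {
  eig <- eigen(K, symmetric = TRUE)
  qy <- as.numeric(crossprod(eig$vectors, y0))
  best <- grid[1]; best_press <- Inf
  for (lam in grid) {
    shrink <- eig$values / (eig$values + lam)
    fitted <- as.numeric(eig$vectors %*% (shrink * qy))
    h <- rowSums(sweep(eig$vectors^2, 2, shrink, "*"))
    press <- sum(((y0 - fitted) / pmax(1 - h, 1e-8))^2)
    if (press < best_press) { best <- lam; best_press <- press }
  }
  best
}

#' @export
predict.rbf_scr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$degenerate) return(rep(object$ybar, nrow(newdata)))
  Z <- newdata[, object$variables, drop = FALSE]
  Zs <- sweep(sweep(Z, 2, object$ctr), 2, object$sdz, "/")
  # squared distances to every centre
  d2 <- outer(rowSums(Zs^2), rowSums(object$centers^2), "+") -
    2 * Zs %*% t(object$centers)
  K <- exp(-pmax(d2, 0) / (2 * object$width^2))
  as.numeric(K %*% object$weights) + object$ybar
}

#' Leave-many-out cross-validation
#'
#' For each of `n_rounds` seeded random holdouts of
#' `leave_fraction * n` observations, the fitter is re-run on the
#' remainder and the held-out responses predicted;
#' Q2 = 1 - PRESS / sum((y_out - mean(y_in))^2) per round, and the mean
#' over rounds is returned (per-round values in attribute `rounds`).
#'
#' @param X Descriptor matrix with named columns.
#' @param y Response vector (not constant).
#' @param fitter Function `(X, y, config) -> model` with a `predict`
#'   method, e.g. [fit_scr()] or [fit_rbf_scr()].
#' @param n_rounds Number of holdout rounds (default 20).
#' @param leave_fraction Fraction left out per round (default 0.2).
#' @param seed Integer seed; identical seeds give identical folds.
#' @param config Passed to the fitter.
#' @return Mean Q2 across rounds.
#' @export
lmo_cross_validation <- function(X, y, fitter = fit_scr, n_rounds = 20L,
                                 leave_fraction = 0.2, seed = 1L,
                                 config = scr_config()) {
  if (stats::sd(y) == 0) stop("constant response")
  n <- nrow(X)
  n_out <- max(2L, floor(leave_fraction * n))
  if (n - n_out < 5L) stop("training folds too small")
  rounds <- numeric(n_rounds)
  set.seed(seed)
  for (r in seq_len(n_rounds)) {
    out <- sample.int(n, n_out)
    fit <- fitter(X[-out, , drop = FALSE], y[-out], config)
    pred <- predict(fit, X[out, , drop = FALSE])
    rounds[r] <- 1 - sum((y[out] - pred)^2) /
      sum((y[out] - mean(y[-out]))^2)
  }
  structure(mean(rounds), rounds = rounds)
}

#' Model stability index
#'
#' A = mean training R2 - mean leave-many-out Q2.  Models with A < 0.1
#' are classed as highly stable, A <= 0.2 acceptable, A <= 0.3 low, and
#' A > 0.3 unstable (beyond the commonly accepted limit).
#'
#' @param r2_mean Mean training R2 over partial models, in [-1, 1].
#' @param q2_lmo_mean Mean LMO Q2, in [-1, 1].
#' @return The value A, with attribute `class` holding the stability
#'   label.
#' @export
stability <- function(r2_mean, q2_lmo_mean) {
  stopifnot(abs(r2_mean) <= 1, abs(q2_lmo_mean) <= 1)
  a <- r2_mean - q2_lmo_mean
  label <- if (a < 0.1) "high" else if (a <= 0.2) "acceptable"
           else if (a <= 0.3) "low" else "unstable"
  structure(a, class = c("stability", "numeric"), label = label)
}

#' @export
print.stability <- function(x, ...) {
  cat(sprintf("A = %.3f (%s stability)\n", unclass(x), attr(x, "label")))
  invisible(x)
}
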