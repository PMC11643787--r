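#' Build a consensus QSAR model
#'
#' Fits `n_partials` partial regression models and averages them.  Each
#' partial model sees a seeded random 80% subsample (without
#' replacement) of the training compounds and a seeded random subset of
#' 50-90% of its descriptor family's columns, capped below the
#' subsample size so every partial fit is well-posed (the three
#' whole-molecule descriptors are always candidates).  This provides
#' reproducible diversity across partials.
#' With `families = "both"` the partials alternate between the QNA and
#' MNA families (half each); with `method = "Both"` they alternate
#' between SCR and RBF-SCR.  Default pool sizes are 20 for a
#' single-family model and 320 for a mixed-family model.
#'
#' Summary statistics are arithmetic means over the partials: training
#' R2 and the Fisher criterion and residual SD evaluated on the full
#' training set, Q2 from 20 rounds of 20% leave-many-out refits of each
#' partial's regression stage (selected variables and ridge held
#' fixed), and V the mean number of selected variables.
#'
#' @param train An `activity_dataset` with structures; must satisfy
#'   [check_modeling_precondition()] unless `check_range = FALSE`.
#' @param method `"SCR"`, `"RBF-SCR"`, or `"Both"`.
#' @param families `"QNA"`, `"MNA"`, or `"both"`.
#' @param n_partials Pool size; default 20 (single family) or 320 (both).
#' @param seed Integer seed; all partial-level randomness derives from it.
#' @param config An [scr_config()].
#' @param desc_config Optional pre-fitted [fit_descriptor_config()]
#'   (fitted from the training structures when NULL).
#' @param lmo_rounds,lmo_fraction Leave-many-out settings for the
#'   per-partial Q2 (defaults 20 rounds, 20%).
#' @param check_range Enforce the activity-range precondition.
#' @return Object of class `consensus_model`.
#' @export
build_consensus <- function(train, method = c("SCR", "RBF-SCR", "Both"),
                            families = c("QNA", "MNA", "both"),
                            n_partials = NULL, seed = 1L,
                            config = scr_config(), desc_config = NULL,
                            lmo_rounds = 20L, lmo_fraction = 0.2,
                            check_range = TRUE) {
  method <- match.arg(method)
  families <- match.arg(families)
  if (is.null(train$structures)) stop("training set has no structures")
  if (check_range && !check_modeling_precondition(train)) {
    stop("activity range too narrow: delta pIC50 must exceed 3")
  }
  if (is.null(n_partials)) n_partials <- if (families == "both") 320L else 20L
  n <- nrow(train$records)
  if (n < 10L) stop("insufficient data for consensus modelling")
  if (is.null(desc_config)) desc_config <- fit_descriptor_config(train$structures)
  X <- descriptor_matrix(train$structures, desc_config)
  y <- train$records$pic50
  wm <- c("topological_length", "topological_volume", "lipophilicity")

  set.seed(seed)
  partials <- vector("list", n_partials)
  stats_pm <- matrix(NA_real_, n_partials, 5,
                     dimnames = list(NULL, c("r2", "q2_lmo", "f", "sd", "v")))
  for (i in seq_len(n_partials)) {
    fam_i <- if (families == "both") {
      if (i %% 2L == 1L) "QNA" else "MNA"
    } else families
    meth_i <- if (method == "Both") {
      if ((if (families == "both") (i + 1L) %/% 2L else i) %% 2L == 1L)
        "SCR" else "RBF-SCR"
    } else method
    rows <- sort(sample.int(n, max(5L, round(0.8 * n))))
    fam_cols <- setdiff(family_columns(X, fam_i), wm)
    # count-like columns nearly constant within the subsample cannot be
    # estimated there; keep those with >= 3 non-zero entries
    if (fam_i == "MNA") {
      fam_cols <- fam_cols[colSums(X[rows, fam_cols, drop = FALSE] != 0) >= 3]
    }
    frac <- stats::runif(1, 0.5, 0.9)
    # cap the candidate count below the subsample size so each partial
    # fit is well-posed; the pool as a whole still covers every column
    n_cand <- min(max(1L, round(frac * length(fam_cols))),
                  max(5L, floor(0.6 * length(rows))))
    take <- sort(sample.int(length(fam_cols), n_cand))
    cols <- c(fam_cols[take], wm)
    fit <- if (meth_i == "SCR") {
      fit_scr(X[rows, cols, drop = FALSE], y[rows], config)
    } else {
      fit_rbf_scr(X[rows, cols, drop = FALSE], y[rows], config)
    }
    fit$family <- fam_i
    partials[[i]] <- fit
    # descriptive statistics on the full training set
    pred <- predict(fit, X)
    rss <- sum((y - pred)^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    k <- max(1L, length(fit$variables))
    dfr <- max(n - k - 1L, 1L)
    stats_pm[i, "r2"] <- r2
    stats_pm[i, "f"] <- if (r2 < 1) (r2 / k) / ((1 - r2) / dfr) else Inf
    stats_pm[i, "sd"] <- sqrt(rss / dfr)
    stats_pm[i, "v"] <- length(fit$variables)
    stats_pm[i, "q2_lmo"] <- partial_lmo_q2(X, y, fit, config,
                                            lmo_rounds, lmo_fraction)
  }

  multisets <- attr(X, "multisets")
  wm_range <- apply(X[, wm, drop = FALSE], 2, range)
  structure(list(
    method = method, families = families, n_partials = n_partials,
    seed = seed, partials = partials,
    desc_config = desc_config,
    ad = list(train_multisets = multisets, wm_range = wm_range,
              tanimoto_min = 0.3, range_expand = 0.1),
    summary = list(
      r2_mean = mean(stats_pm[, "r2"]),
      q2_lmo_mean = mean(stats_pm[, "q2_lmo"]),
      f_mean = mean(stats_pm[is.finite(stats_pm[, "f"]), "f"]),
      sd_mean = mean(stats_pm[, "sd"]),
      v_mean = mean(stats_pm[, "v"]),
      stability = stability(
        max(-1, min(1, mean(stats_pm[, "r2"]))),
        max(-1, min(1, mean(stats_pm[, "q2_lmo"]))))),
    per_partial = as.data.frame(stats_pm),
    train_ids = train$records$id,
    train_mean = mean(y), train_range = diff(range(y)),
    rmsep = NULL
  ), class = "consensus_model")
}

# Q2_LMO of one partial with its selection and regularisation fixed:
# 20%-holdout refits of the regression stage only.
partial_lmo_q2 <- function(X, y, fit, config, n_rounds, fraction) {
  n <- nrow(X)
  n_out <- max(2L, floor(fraction * n))
  vars <- fit$variables
  rounds <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    out <- sample.int(n, n_out)
    if (!length(vars)) {
      pred <- rep(mean(y[-out]), n_out)
    } else if (inherits(fit, "scr_model")) {
      sub <- refit_ridge(X[-out, vars, drop = FALSE], y[-out], fit$lambda)
      pred <- as.numeric(X[out, vars, drop = FALSE] %*% sub$coef) + sub$intercept
    } else {
      sub <- refit_rbf(X[-out, vars, drop = FALSE], y[-out],
                       fit$width, fit$lambda)
      pred <- predict_refit_rbf(sub, X[out, vars, drop = FALSE])
    }
    rounds[r] <- 1 - sum((y[out] - pred)^2) / sum((y[out] - mean(y[-out]))^2)
  }
  mean(rounds)
}

refit_ridge <- function(X, y, lam) {
  sd0 <- standardise_design(as.matrix(X), y)
  if (ncol(sd0$Xs) == 0L) return(list(coef = rep(0, ncol(X)), intercept = sd0$ybar))
  G <- crossprod(sd0$Xs)
  b <- solve(G + diag(lam, ncol(G)), crossprod(sd0$Xs, sd0$yc))
  coef_orig <- numeric(ncol(X))
  coef_orig[sd0$keep] <- b / sd0$sdx
  intercept <- sd0$ybar - sum(coef_orig[sd0$keep] * sd0$ctr)
  list(coef = coef_orig, intercept = intercept)
}

refit_rbf <- function(X, y, width, ridge) {
  ctr <- colMeans(X); sdz <- apply(X, 2, stats::sd); sdz[sdz < 1e-12] <- 1
  Zs <- sweep(sweep(as.matrix(X), 2, ctr), 2, sdz, "/")
  D <- as.matrix(stats::dist(Zs))
  K <- exp(-D^2 / (2 * width^2))
  ybar <- mean(y)
  list(centers = Zs, ctr = ctr, sdz = sdz, width = width, ybar = ybar,
       weights = as.numeric(solve(K + diag(ridge, nrow(K)), y - ybar)))
}

predict_refit_rbf <- function(m, X) {
  Zs <- sweep(sweep(as.matrix(X), 2, m$ctr), 2, m$sdz, "/")
  d2 <- outer(rowSums(Zs^2), rowSums(m$centers^2), "+") -
    2 * Zs %*% t(m$centers)
  as.numeric(exp(-pmax(d2, 0) / (2 * m$width^2)) %*% m$weights) + m$ybar
}

#' @export
print.consensus_model <- function(x, ...) {
  s <- x$summary
  cat(sprintf("consensus_model: %s / %s, %d partials\n",
              x$method, x$families, x$n_partials))
  cat(sprintf("  R2=%.3f  Q2_LMO=%.3f  F=%.3f  SD=%.3f  V=%.1f  A=%.3f (%s)\n",
              s$r2_mean, s$q2_lmo_mean, s$f_mean, s$sd_mean, s$v_mean,
              unclass(s$stability), attr(s$stability, "label")))
  invisible(x)
}

#' Predict activities with a consensus model
#'
#' The consensus prediction of a compound is the unweighted mean of the
#' partial-model predictions; the per-partial spread is reported as SD.
#' The applicability domain requires (a) Tanimoto similarity of the
#' compound's MNA descriptor set to its nearest training compound of at
#' least 0.3 and (b) all three whole-molecule descriptors inside the
#' training min/max expanded by 10%.  Out-of-domain compounds (including
#' structures whose descriptors cannot be computed, e.g. unseen
#' elements) get NA predictions unless `force = TRUE`.
#'
#' @param object A `consensus_model`.
#' @param structures List of `molgraph` (or a single graph).
#' @param force Keep numeric predictions outside the domain (flagged).
#' @param ... Unused.
#' @return Data frame: id, predicted, sd, in_ad, n_partials_used.
#' @export
predict.consensus_model <- function(object, structures, force = FALSE, ...) {
  if (inherits(structures, "molgraph")) structures <- list(structures)
  ids <- vapply(seq_along(structures), function(i) name_or(structures, i), "")
  out <- data.frame(id = ids, predicted = NA_real_, sd = NA_real_,
                    in_ad = FALSE, n_partials_used = 0L)
  for (j in seq_along(structures)) {
    g <- structures[[j]]
    Xj <- tryCatch(descriptor_matrix(structures[j], object$desc_config),
                   error = function(e) NULL)
    if (is.null(Xj)) next  # descriptors not computable: out of domain
    ms <- attr(Xj, "multisets")[[1]]
    sim <- max(vapply(object$ad$train_multisets, mna_tanimoto, 0, b = ms))
    wm <- Xj[1, colnames(object$ad$wm_range), drop = TRUE]
    lo <- object$ad$wm_range[1, ]; hi <- object$ad$wm_range[2, ]
    pad <- object$ad$range_expand * (hi - lo)
    in_box <- all(wm >= lo - pad & wm <= hi + pad)
    in_ad <- sim >= object$ad$tanimoto_min && in_box
    preds <- vapply(object$partials, function(pm) predict(pm, Xj)[1], 0)
    out$in_ad[j] <- in_ad
    if (in_ad || force) {
      out$predicted[j] <- mean(preds)
      out$sd[j] <- stats::sd(preds)
      out$n_partials_used[j] <- length(preds)
    }
  }
  out
}
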