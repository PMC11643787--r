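#' External-validation metric report
#'
#' Computes the full statistic suite used to judge descriptive and
#' predictive ability from one (observed, predicted) pairing:
#' \itemize{
#'   \item r2: squared Pearson correlation;
#'   \item r0_2 / r0p_2: determination coefficients of the least-squares
#'     fits through the origin, observed-against-predicted and
#'     predicted-against-observed respectively;
#'   \item rm2 = r2 * (1 - sqrt(|r2 - r0_2|)) and its reverse rm2p, with
#'     the mean rm2_bar and difference delta_rm2 (the absolute-value
#'     convention keeps the root real when r0 exceeds r2);
#'   \item CCC, the concordance correlation coefficient
#'     2*s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2) with population
#'     (1/n) moments;
#'   \item QF1_2 = 1 - sum(err^2)/sum((y_obs - train_mean)^2) and
#'     QF2_2 = 1 - sum(err^2)/sum((y_obs - mean(y_obs))^2);
#'   \item RMSE, MAE, SD of absolute errors (population form), and the
#'     B criterion = MAE + 3*SD.
#' }
#'
#' @param y_obs Observed responses (length >= 3, not constant).
#' @param y_pred Predicted responses, same length.
#' @param train_mean Training-set mean response (used by QF1_2; when
#'   NULL, QF1_2 is reported as NA).
#' @return List of class `metric_report`.
#' @export
external_metrics <- function(y_obs, y_pred, train_mean = NULL) {
  n <- length(y_obs)
  if (n < 3L) stop("need at least 3 observations")
  if (length(y_pred) != n) stop("length mismatch")
  if (stats::sd(y_obs) == 0) stop("constant observed response")
  err <- y_pred - y_obs
  r2 <- stats::cor(y_obs, y_pred)^2
  # through-origin fits: slope k = sum(xy)/sum(x^2) for y ~ k x
  k_op <- sum(y_obs * y_pred) / sum(y_pred^2)       # obs ~ k * pred
  r0_2 <- 1 - sum((y_obs - k_op * y_pred)^2) / sum((y_obs - mean(y_obs))^2)
  k_po <- sum(y_obs * y_pred) / sum(y_obs^2)        # pred ~ k * obs
  r0p_2 <- 1 - sum((y_pred - k_po * y_obs)^2) / sum((y_pred - mean(y_pred))^2)
  rm2 <- r2 * (1 - sqrt(abs(r2 - r0_2)))
  rm2p <- r2 * (1 - sqrt(abs(r2 - r0p_2)))
  sxy <- mean((y_obs - mean(y_obs)) * (y_pred - mean(y_pred)))
  ccc <- 2 * sxy / (mean((y_obs - mean(y_obs))^2) +
                    mean((y_pred - mean(y_pred))^2) +
                    (mean(y_obs) - mean(y_pred))^2)
  qf1_2 <- if (is.null(train_mean)) NA_real_ else
    1 - sum(err^2) / sum((y_obs - train_mean)^2)
  qf2_2 <- 1 - sum(err^2) / sum((y_obs - mean(y_obs))^2)
  mae <- mean(abs(err))
  sd_abs <- sqrt(mean((abs(err) - mae)^2))   # population form
  structure(list(
    n = n, r2 = r2, r0_2 = r0_2, r0p_2 = r0p_2,
    rm2 = rm2, rm2p = rm2p, rm2_bar = (rm2 + rm2p) / 2,
    delta_rm2 = abs(rm2 - rm2p),
    ccc = ccc, qf1_2 = qf1_2, qf2_2 = qf2_2,
    rmse = sqrt(mean(err^2)), mae = mae, sd_abs = sd_abs,
    b = mae + 3 * sd_abs
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("n=%d  r2=%.3f  r0_2=%.3f  r0'_2=%.3f  rm2bar=%.3f  ",
                     "d_rm2=%.3f\nCCC=%.3f  QF1_2=%s  QF2_2=%.3f  ",
                     "RMSE=%.3f  MAE=%.3f  SD=%.3f  B=%.3f\n"),
              x$n, x$r2, x$r0_2, x$r0p_2, x$rm2_bar, x$delta_rm2, x$ccc,
              ifelse(is.na(x$qf1_2), "NA", sprintf("%.3f", x$qf1_2)),
              x$qf2_2, x$rmse, x$mae, x$sd_abs, x$b))
  invisible(x)
}

#' Trim the worst-predicted fraction of a pairing
#'
#' Removes `round(fraction * n)` pairs (minimum 1 when fraction > 0)
#' with the largest absolute errors; ties are broken by observation
#' order.  Used to report metrics at 95% of the data alongside 100%.
#'
#' @param y_obs,y_pred Paired vectors.
#' @param fraction Fraction to remove, in [0, 0.5) (default 0.05).
#' @return List: `y_obs`, `y_pred` (reduced), `removed` (indices into
#'   the original vectors).
#' @export
trim_worst <- function(y_obs, y_pred, fraction = 0.05) {
  if (fraction < 0 || fraction >= 0.5) stop("fraction must be in [0, 0.5)")
  n <- length(y_obs)
  if (fraction == 0) {
    return(list(y_obs = y_obs, y_pred = y_pred, removed = integer(0)))
  }
  k <- max(1L, round(fraction * n))
  ord <- order(-abs(y_pred - y_obs), seq_len(n))  # ties: earlier obs first
  removed <- sort(ord[seq_len(k)])
  list(y_obs = y_obs[-removed], y_pred = y_pred[-removed], removed = removed)
}

#' Classify descriptive/predictive ability against banded thresholds
#'
#' MAE is banded at 0.10 and 0.15 of the training activity range and the
#' B criterion (MAE + 3*SD) at 0.20 and 0.25 of it, with inclusive upper
#' bounds: MAE <= 0.10*Delta is high, (0.10*Delta, 0.15*Delta] moderate,
#' beyond that low (and analogously for B at 0.20/0.25).  The
#' correlation-based criteria require r2 > 0.8, CCC > 0.8 and the
#' available Q2 statistics > 0.7 for the high class, and flag low
#' ability when r2 <= 0.6, CCC <= 0.7 or a Q2 <= 0.6.  The overall
#' level is the worst triggered band.
#'
#' @param report A `metric_report`.
#' @param train_range Training-set Delta pIC50 (> 0).
#' @param q2_lmo Optional mean LMO Q2 to include in the r2-family check.
#' @return List of class `ability_class`: `level` in
#'   high/moderate/low and `criteria`, the per-band classifications.
#' @export
classify_ability <- function(report, train_range, q2_lmo = NULL) {
  if (train_range <= 0) stop("train_range must be positive")
  band <- function(x, lo, hi) {
    if (x <= lo) "high" else if (x <= hi) "moderate" else "low"
  }
  mae_band <- band(report$mae, 0.10 * train_range, 0.15 * train_range)
  b_band <- band(report$b, 0.20 * train_range, 0.25 * train_range)
  q2s <- c(QF1 = report$qf1_2, QF2 = report$qf2_2, QLMO = q2_lmo)
  q2s <- q2s[!is.na(q2s)]
  r_band <- if (report$r2 > 0.8 && report$ccc > 0.8 &&
                (!length(q2s) || all(q2s > 0.7))) "high"
            else if (report$r2 <= 0.6 || report$ccc <= 0.7 ||
                     (length(q2s) && any(q2s <= 0.6))) "low"
            else "moderate"
  levels <- c(high = 1L, moderate = 2L, low = 3L)
  overall <- names(levels)[max(levels[c(mae_band, b_band, r_band)])]
  structure(list(level = overall,
                 criteria = c(mae = mae_band, b = b_band, r2_family = r_band)),
            class = "ability_class")
}

#' @export
print.ability_class <- function(x, ...) {
  cat(sprintf("ability: %s (MAE %s, B %s, r2-family %s)\n", x$level,
              x$criteria[["mae"]], x$criteria[["b"]],
              x$criteria[["r2_family"]]))
  invisible(x)
}

#' Prediction-window report against the 2*RMSEP confidence band
#'
#' Flags each compound whose absolute prediction error lies within the
#' 95% confidence window +/- 2*RMSEP (inclusive at the boundary).
#'
#' @param rmsep Root-mean-square error of prediction (> 0) of the model
#'   on its reference test set.
#' @param predictions,experimentals Paired numeric vectors.
#' @param ids Optional compound identifiers.
#' @return Data frame: id, predicted, experimental, delta
#'   (= |pred - exp|), window (echoes 2*rmsep), within.
#' @export
prediction_window_report <- function(rmsep, predictions, experimentals,
                                     ids = NULL) {
  if (rmsep <= 0) stop("rmsep must be positive")
  if (length(predictions) != length(experimentals)) stop("length mismatch")
  if (is.null(ids)) ids <- as.character(seq_along(predictions))
  delta <- abs(predictions - experimentals)
  data.frame(id = ids, predicted = predictions,
             experimental = experimentals, delta = delta,
             window = 2 * rmsep, within = delta <= 2 * rmsep)
}

#' Systematic-error diagnostics of a prediction set
#'
#' Reports the mean signed error and the fraction of positive residuals
#' (residual = predicted - observed), and flags systematic bias when
#' |mean signed error| > 0.5 * MAE or when more than 80% of residuals
#' share a sign.
#'
#' @param y_obs,y_pred Paired vectors, n >= 5.
#' @return List: mean_signed_error, frac_positive, mae, flagged,
#'   reasons.
#' @export
systematic_error_check <- function(y_obs, y_pred) {
  n <- length(y_obs)
  if (n < 5L) stop("need at least 5 observations")
  res <- y_pred - y_obs
  mse_signed <- mean(res)
  mae <- mean(abs(res))
  frac_pos <- mean(res > 0)
  reasons <- character(0)
  if (mae > 0 && abs(mse_signed) > 0.5 * mae) {
    reasons <- c(reasons, "mean signed error exceeds half the MAE")
  }
  if (max(frac_pos, 1 - frac_pos) > 0.8) {
    reasons <- c(reasons, "more than 80% of residuals share a sign")
  }
  list(mean_signed_error = mse_signed, frac_positive = frac_pos,
       mae = mae, flagged = length(reasons) > 0, reasons = reasons)
}

#' Side-by-side 100% / 95% metric report
#'
#' @param y_obs,y_pred Paired vectors.
#' @param train_mean Training mean for QF1_2.
#' @param trim_fraction Fraction trimmed for the reduced block.
#' @return List with `full` and `trimmed` metric reports and the
#'   `removed` indices.
#' @export
metric_report_pair <- function(y_obs, y_pred, train_mean = NULL,
                               trim_fraction = 0.05) {
  full <- external_metrics(y_obs, y_pred, train_mean)
  tr <- trim_worst(y_obs, y_pred, trim_fraction)
  trimmed <- external_metrics(tr$y_obs, tr$y_pred, train_mean)
  list(full = full, trimmed = trimmed, removed = tr$removed)
}

#' Write a pair of metric reports as delimited text
#'
#' @param pair Result of [metric_report_pair()].
#' @param path Output TSV path; the 100% and 95% blocks sit side by side.
#' @return Invisibly, `path`.
#' @export
write_metric_report <- function(pair, path) {
  fields <- setdiff(names(pair$full), "n")
  df <- data.frame(
    criterion = c("n", fields),
    data_100 = c(pair$full$n, unlist(pair$full[fields])),
    data_95 = c(pair$trimmed$n, unlist(pair$trimmed[fields])))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
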