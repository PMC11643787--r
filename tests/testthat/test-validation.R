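test_that("perfect predictions give the identity report", {
  y <- c(4.1, 5.3, 6.2, 7.0, 5.8)
  r <- external_metrics(y, y, train_mean = mean(y))
  expect_equal(r$r2, 1); expect_equal(r$r0_2, 1)
  expect_equal(r$ccc, 1); expect_equal(r$qf2_2, 1)
  expect_equal(r$rmse, 0); expect_equal(r$mae, 0)
  expect_equal(r$sd_abs, 0); expect_equal(r$b, 0)
})

test_that("the B criterion combines MAE and the SD of absolute errors", {
  # errors alternating 0.142 / 0.016: MAE 0.079, SD 0.063, B 0.268
  y <- c(1, 2, 3, 4)
  pred <- y + c(0.142, 0.016, 0.142, 0.016)
  r <- external_metrics(y, pred)
  expect_equal(round(r$mae, 3), 0.079)
  expect_equal(round(r$sd_abs, 3), 0.063)
  expect_equal(round(r$b, 3), 0.268)
})

test_that("a constant shift keeps r2 at 1 but degrades CCC", {
  y <- c(1, 2, 3, 4)
  r <- external_metrics(y, y + 0.5)
  expect_equal(r$r2, 1)
  # closed form: 2*1.25 / (1.25 + 1.25 + 0.25)
  expect_equal(r$ccc, 2.5 / 2.75, tolerance = 1e-12)
  expect_equal(r$mae, 0.5)
})

test_that("every statistic matches the brute-force oracle to 1e-10", {
  set.seed(14)
  for (n in c(5, 10, 50)) {
    for (i in 1:10) {
      obs <- rnorm(n, 5, 1)
      pred <- obs + rnorm(n, 0.1, 0.4)
      tm <- 5.2
      got <- external_metrics(obs, pred, tm)
      want <- oracle_metrics(obs, pred, tm)
      for (f in names(want)) {
        expect_equal(got[[f]], want[[f]], tolerance = 1e-10,
                     info = paste(f, "n =", n))
      }
    }
  }
  expect_error(external_metrics(c(1, 2), c(1, 2)), "at least 3")
  expect_error(external_metrics(rep(1, 5), rnorm(5)), "constant")
})

test_that("worst-case trimming removes the documented count and pairs", {
  set.seed(6)
  obs <- rnorm(16, 5); pred <- obs + rnorm(16, 0, 0.3)
  tr <- trim_worst(obs, pred)
  expect_length(tr$removed, 1L)              # round(0.8) with minimum 1
  expect_equal(tr$removed, which.max(abs(pred - obs)))
  expect_length(tr$y_obs, 15L)
  id <- trim_worst(obs, pred, fraction = 0)
  expect_identical(id$y_obs, obs)
  expect_length(id$removed, 0L)
  expect_error(trim_worst(obs, pred, 0.5), "fraction")
  # trimming never increases RMSE or MAE
  for (i in 1:10) {
    o <- rnorm(30, 5); p <- o + rnorm(30, 0, 0.5)
    full <- external_metrics(o, p)
    t5 <- trim_worst(o, p, 0.05)
    red <- external_metrics(t5$y_obs, t5$y_pred)
    expect_lte(red$rmse, full$rmse)
    expect_lte(red$mae, full$mae)
  }
})

test_that("QF1 and QF2 coincide when the reference means coincide", {
  set.seed(16)
  for (i in 1:10) {
    obs <- rnorm(12, 5); pred <- obs + rnorm(12, 0, 0.3)
    r <- external_metrics(obs, pred, train_mean = mean(obs))
    expect_equal(r$qf1_2, r$qf2_2, tolerance = 1e-12)
  }
})

test_that("ability bands follow the published range-scaled thresholds", {
  delta <- 3.873
  mk_report <- function(mae_target) {
    # alternating +/- errors of fixed magnitude over a wide range keep
    # r2 and the Q2 statistics high while pinning MAE exactly
    obs <- seq(1, 12, length.out = 10)
    pred <- obs + rep(c(mae_target, -mae_target), 5)
    external_metrics(obs, pred, train_mean = mean(obs))
  }
  high <- classify_ability(mk_report(0.30), delta)
  expect_equal(unname(high$criteria[["mae"]]), "high")   # 0.30 <= 0.387
  expect_equal(unname(high$criteria[["b"]]), "high")     # 0.30 <= 0.775
  mod <- classify_ability(mk_report(0.50), delta)
  expect_equal(unname(mod$criteria[["mae"]]), "moderate") # (0.387, 0.581]
  expect_equal(mod$level, "moderate")
  low <- classify_ability(mk_report(0.60), delta)
  expect_equal(unname(low$criteria[["mae"]]), "low")      # > 0.581
  expect_equal(low$level, "low")
  # boundary is inclusive at the band edge
  edge <- classify_ability(mk_report(0.387), delta)
  expect_equal(unname(edge$criteria[["mae"]]), "high")
  expect_error(classify_ability(mk_report(0.3), 0), "positive")
})

test_that("the prediction window echoes 2*RMSEP and is inclusive", {
  rep1 <- prediction_window_report(0.437, 4.318, 4.324, ids = "cmp8")
  expect_equal(rep1$window, 0.874)
  expect_equal(round(rep1$delta, 3), 0.006)
  expect_true(rep1$within)
  # boundary: delta exactly 2*rmsep counts as within
  rep2 <- prediction_window_report(0.25, 5.5, 5.0)
  expect_equal(rep2$delta, 0.5)
  expect_true(rep2$within)
  rep3 <- prediction_window_report(0.2, 5.5, 5.0)
  expect_false(rep3$within)
  expect_error(prediction_window_report(0, 1, 1), "positive")
})

test_that("systematic-error rules flag one-sided and biased residuals", {
  obs <- 1:6
  ok <- systematic_error_check(obs, obs + c(0.2, -0.2, 0.2, -0.2, 0.2, -0.2))
  expect_false(ok$flagged)
  bias <- systematic_error_check(obs, obs + 0.3)
  expect_true(bias$flagged)
  expect_equal(bias$frac_positive, 1)
  # mean signed error above half the MAE on a mixed-sign vector
  res <- c(0.5, 0.5, 0.5, 0.5, -0.1, -0.1)
  mixed <- systematic_error_check(obs, obs + res)
  expect_gt(abs(mixed$mean_signed_error), 0.5 * mixed$mae)
  expect_true(mixed$flagged)
  expect_error(systematic_error_check(1:4, 1:4), "at least 5")
})

test_that("paired 100%/95% reports write as side-by-side text", {
  set.seed(19)
  obs <- rnorm(20, 5); pred <- obs + rnorm(20, 0, 0.3)
  pair <- metric_report_pair(obs, pred, train_mean = 5)
  expect_equal(pair$full$n, 20L)
  expect_equal(pair$trimmed$n, 19L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_metric_report(pair, tf)
  tab <- read.delim(tf)
  expect_equal(names(tab), c("criterion", "data_100", "data_95"))
  expect_true("b" %in% tab$criterion)
})
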