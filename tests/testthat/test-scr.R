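planted_design <- function(n, p_noise = 20L, noise_sd = 0.1, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * (3 + p_noise)), n, 3 + p_noise,
              dimnames = list(NULL, paste0("x", seq_len(3 + p_noise))))
  beta <- c(2, -1.5, 0.8)
  y <- as.numeric(X[, 1:3] %*% beta) + rnorm(n, 0, noise_sd)
  list(X = X, y = y, beta = beta)
}

test_that("noiseless planted signal is recovered exactly", {
  d <- planted_design(100, noise_sd = 0, seed = 2)
  f <- fit_scr(d$X, d$y)
  expect_true(all(c("x1", "x2", "x3") %in% f$variables))
  expect_equal(unname(f$coef[c("x1", "x2", "x3")]), d$beta,
               tolerance = 1e-6)
  expect_lt(max(abs(predict(f, d$X) - d$y)), 1e-5)
  expect_error(fit_scr(d$X[1:4, ], d$y[1:4]), "at least 5")
})

test_that("planted variables survive selection across seeded replicates", {
  hits <- vapply(1:100, function(s) {
    d <- planted_design(100, noise_sd = 0.1, seed = s)
    all(c("x1", "x2", "x3") %in% fit_scr(d$X, d$y)$variables)
  }, TRUE)
  expect_gte(sum(hits), 95L)
})

test_that("selection on an orthonormal design matches OLS backward elimination", {
  # on (near-)orthonormal columns the coefficients are decoupled, so
  # iterative elimination reduces to thresholding; cross-check against
  # an independent lm()-based backward elimination on <= 8 columns
  lm_backward <- function(X, y, threshold = 2) {
    vars <- colnames(X)
    repeat {
      fit <- stats::lm(y ~ ., data = data.frame(X[, vars, drop = FALSE], y = y))
      tv <- abs(summary(fit)$coefficients[-1, "t value"])
      if (!length(tv) || min(tv) >= threshold) return(sort(vars))
      vars <- vars[-which.min(tv)]
      if (!length(vars)) return(character(0))
    }
  }
  set.seed(31)
  for (i in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(40 * 8), 40, 8)))
    colnames(Q) <- paste0("q", 1:8)
    y <- 3 * Q[, 1] - 2 * Q[, 2] + rnorm(40, 0, 0.25)
    got <- sort(fit_scr(Q, y, scr_config(lambda_grid = 1e-8))$variables)
    expect_equal(got, lm_backward(Q, y), info = paste("replicate", i))
  }
})

test_that("RBF-SCR interpolates under a negligible ridge and shares selection", {
  set.seed(11)
  n <- 25
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- 1.5 * X[, 1] - X[, 2] + 0.7 * X[, 3] + rnorm(n, 0, 0.05)
  cfg <- scr_config(rbf_ridge = 1e-12)
  fr <- fit_rbf_scr(X, y, cfg)
  fs <- fit_scr(X, y, cfg)
  expect_identical(fr$variables, fs$variables)
  expect_lt(max(abs(predict(fr, X) - y)), 1e-6)
})

test_that("RBF-SCR beats SCR on a smooth nonlinear response", {
  set.seed(21)
  n <- 100
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- sin(X[, 1] * 1.5) + rnorm(n, 0, 0.05)
  fs <- fit_scr(X, y)
  fr <- fit_rbf_scr(X, y)
  expect_true("x1" %in% fs$variables)
  expect_gt(fr$r2, fs$r2)
})

test_that("degenerate inputs give a flagged intercept-only model", {
  set.seed(4)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- rep(2.5, 40) + rnorm(40, 0, 1e-8)  # essentially no signal
  f <- fit_scr(X, y)
  expect_true(f$degenerate || length(f$variables) <= 1)
  co <- fit_scr(matrix(1, 10, 2, dimnames = list(NULL, c("a", "b"))),
                rnorm(10))
  expect_true(co$degenerate)
  expect_equal(predict(co, matrix(1, 3, 2,
                                  dimnames = list(NULL, c("a", "b")))),
               rep(co$intercept, 3))
})

test_that("leave-many-out Q2 behaves as expected at the extremes", {
  d <- planted_design(60, noise_sd = 0, seed = 9)
  q <- lmo_cross_validation(d$X, d$y, seed = 1)
  expect_gte(as.numeric(q), 0.99)
  # determinism: identical seeds give identical folds and Q2
  q2 <- lmo_cross_validation(d$X, d$y, seed = 1)
  expect_identical(attr(q, "rounds"), attr(q2, "rounds"))
  dn <- planted_design(60, noise_sd = 0.3, seed = 10)
  qa <- lmo_cross_validation(dn$X, dn$y, seed = 1)
  qb <- lmo_cross_validation(dn$X, dn$y, seed = 2)
  expect_false(identical(as.numeric(qa), as.numeric(qb)))
  # pure noise: Q2 stays low across seeded replicates
  low <- vapply(1:20, function(s) {
    set.seed(s + 400)
    Xn <- matrix(rnorm(60 * 8), 60, 8,
                 dimnames = list(NULL, paste0("x", 1:8)))
    yn <- rnorm(60)
    as.numeric(lmo_cross_validation(Xn, yn, seed = s)) <= 0.2
  }, TRUE)
  expect_gte(sum(low), 19L)
  expect_error(lmo_cross_validation(d$X, rep(1, 60)), "constant")
})

test_that("stability index reproduces the published values and bands", {
  a1 <- stability(0.825, 0.758)
  expect_equal(round(as.numeric(a1), 3), 0.067)
  expect_equal(attr(a1, "label"), "high")
  a13 <- stability(0.996, 0.753)
  expect_equal(round(as.numeric(a13), 3), 0.243)
  expect_equal(attr(a13, "label"), "low")
  expect_equal(as.numeric(stability(0.8, 0.8)), 0)
  expect_equal(attr(stability(0.9, 0.75), "label"), "acceptable")
  expect_equal(attr(stability(0.99, 0.60), "label"), "unstable")
})
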