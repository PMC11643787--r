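small_train <- function(seed = 1L, n = 40L) {
  spec <- synthetic_spec(n = n, seed = seed, noise_sd = 0.2)
  generate_activity(generate_molecules(spec), spec)
}

test_that("consensus pools have the requested composition", {
  ds <- small_train(3)
  m <- build_consensus(ds, "SCR", "QNA", n_partials = 8L, seed = 5)
  expect_length(m$partials, 8L)
  expect_true(all(vapply(m$partials, function(p) p$method, "") == "SCR"))
  expect_true(all(vapply(m$partials, function(p) p$family, "") == "QNA"))
  mixed <- build_consensus(ds, "Both", "both", n_partials = 8L, seed = 5)
  fams <- vapply(mixed$partials, function(p) p$family, "")
  meths <- vapply(mixed$partials, function(p) p$method, "")
  expect_equal(sum(fams == "QNA"), 4L)
  expect_equal(sum(fams == "MNA"), 4L)
  expect_equal(sum(meths == "SCR"), 4L)
  expect_equal(sum(meths == "RBF-SCR"), 4L)
  # defaults: 20 partials single family, 320 mixed
  expect_equal(formals(build_consensus)$n_partials, NULL)
})

test_that("consensus building is deterministic in the seed", {
  ds <- small_train(4)
  m1 <- build_consensus(ds, "SCR", "QNA", n_partials = 6L, seed = 11)
  m2 <- build_consensus(ds, "SCR", "QNA", n_partials = 6L, seed = 11)
  expect_equal(m1$summary, m2$summary)
  p1 <- predict(m1, ds$structures[1:5])
  p2 <- predict(m2, ds$structures[1:5])
  expect_identical(p1$predicted, p2$predicted)
  m3 <- build_consensus(ds, "SCR", "QNA", n_partials = 6L, seed = 12)
  expect_false(identical(m1$summary$r2_mean, m3$summary$r2_mean))
})

test_that("a single-partial consensus equals its partial model", {
  ds <- small_train(5)
  m <- build_consensus(ds, "SCR", "QNA", n_partials = 1L, seed = 3)
  X <- descriptor_matrix(ds$structures, m$desc_config)
  pr <- predict(m, ds$structures)
  expect_equal(pr$predicted, predict(m$partials[[1]], X),
               tolerance = 1e-12)
  expect_true(all(pr$sd == 0 | is.na(pr$sd)))
})

test_that("consensus predictions are invariant to partial-model order", {
  ds <- small_train(6)
  m <- build_consensus(ds, "Both", "both", n_partials = 6L, seed = 7)
  shuffled <- m
  set.seed(1); shuffled$partials <- m$partials[sample(6)]
  p1 <- predict(m, ds$structures[1:6])
  p2 <- predict(shuffled, ds$structures[1:6])
  expect_equal(p2$predicted, p1$predicted, tolerance = 1e-12)
  expect_equal(p2$sd, p1$sd, tolerance = 1e-12)
})

test_that("the applicability domain accepts training compounds and rejects aliens", {
  ds <- small_train(8)
  m <- build_consensus(ds, "SCR", "MNA", n_partials = 6L, seed = 9)
  pr_train <- predict(m, ds$structures)
  expect_true(all(pr_train$in_ad))
  # an element with no property entry: descriptors cannot be computed
  alien <- molgraph(c("Se", "C"), rbind(c(1, 2, 1)))
  pr <- predict(m, list(alien = alien))
  expect_false(pr$in_ad)
  expect_true(is.na(pr$predicted))
  forced <- predict(m, list(alien = alien), force = TRUE)
  expect_false(forced$in_ad)
  # forcing cannot conjure descriptors for unseen elements either
  expect_true(is.na(forced$predicted))
  # a dissimilar but computable structure with out-of-range size
  jumbo_spec <- synthetic_spec(n = 1, seed = 99, size_range = c(60L, 70L))
  jumbo <- generate_molecules(jumbo_spec)[[1]]
  prj <- predict(m, list(jumbo = jumbo))
  expect_false(prj$in_ad)
  expect_true(is.na(prj$predicted))
  prjf <- predict(m, list(jumbo = jumbo), force = TRUE)
  expect_false(is.na(prjf$predicted))
})

test_that("consensus training R2 approaches 1 as noise vanishes and test RMSE tracks noise", {
  spec0 <- synthetic_spec(n = 60, seed = 13, noise_sd = 0)
  mols <- generate_molecules(spec0)
  ds0 <- generate_activity(mols, spec0)
  m0 <- build_consensus(ds0, "SCR", "MNA", n_partials = 10L, seed = 2)
  pr0 <- predict(m0, ds0$structures)
  r2_consensus <- cor(pr0$predicted, ds0$records$pic50)^2
  expect_gt(r2_consensus, 0.98)
  expect_gt(m0$summary$r2_mean, 0.9)
  # with noise: held-out RMSE close to the (rescaled) noise SD when the
  # partials' candidate pool contains the planted descriptors (a
  # whole-molecule planted model under the QNA family)
  mols1 <- generate_molecules(synthetic_spec(n = 100, seed = 13))
  wmv <- t(vapply(mols1, whole_molecule_descriptors, numeric(3)))
  w <- 0.8 / apply(wmv, 2, sd)
  names(w) <- colnames(wmv)
  spec1 <- synthetic_spec(n = 100, seed = 13, noise_sd = 0.15, planted = w)
  ds1 <- generate_activity(mols1, spec1)
  sp <- ranked_split(ds1)
  m1 <- build_consensus(sp$train, "SCR", "QNA", n_partials = 10L, seed = 2)
  pr <- predict(m1, setNames(sp$test$structures, sp$test$records$id),
                force = TRUE)
  rmse <- sqrt(mean((pr$predicted - sp$test$records$pic50)^2))
  noise <- attr(ds1, "planted")$noise_sd
  expect_lt(rmse, 2.5 * noise)
})

test_that("consensus models survive a JSON archive round trip", {
  ds <- small_train(10)
  m <- build_consensus(ds, "Both", "both", n_partials = 4L, seed = 21)
  tf <- withr::local_tempfile(fileext = ".json")
  consensus_save(m, tf)
  m2 <- consensus_load(tf)
  p1 <- predict(m, ds$structures[1:8])
  p2 <- predict(m2, ds$structures[1:8])
  expect_equal(p2$predicted, p1$predicted, tolerance = 1e-9)
  expect_equal(p2$in_ad, p1$in_ad)
  expect_equal(m2$summary$r2_mean, m$summary$r2_mean, tolerance = 1e-12)
})
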