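test_that("atom marks carry element and cyclicity", {
  benz <- fix_benzene()
  expect_equal(mna_atom_mark(benz, 1), "C")
  eth <- fix_ethanol()
  expect_equal(mna_atom_mark(eth, 3), "-O")
  # symmetry-equivalent atoms get identical marks
  marks <- vapply(1:6, function(a) mna_atom_mark(benz, a), "")
  expect_equal(unique(marks), "C")
})

test_that("MNA recursion reproduces hand-derived methane descriptors", {
  m <- add_explicit_hydrogens(fix_methane())
  lvl0 <- mna_descriptors(m, 0)
  expect_equal(lvl0[["-C"]], 1L)
  expect_equal(lvl0[["-H"]], 4L)
  expect_equal(sum(lvl0), n_atoms(m))     # one level-0 string per atom
  lvl1 <- mna_descriptors(m, 1)
  expect_equal(lvl1[["-C(-H-H-H-H)"]], 1L)
  expect_equal(lvl1[["-H(-C)"]], 4L)
  expect_error(mna_descriptors(m, -1), "max_level")
})

test_that("MNA multiset matches an independent recursion on random graphs", {
  set.seed(99)
  for (i in 1:10) {
    g <- add_explicit_hydrogens(random_test_graph(9L))
    for (lev in 0:2) {
      expect_equal(mna_descriptors(g, lev), oracle_mna(g, lev),
                   info = paste("graph", i, "level", lev))
    }
  }
})

test_that("MNA and QNA descriptors are invariant to atom relabelling", {
  set.seed(7)
  for (i in 1:20) {
    g <- random_test_graph(10L)
    gp <- permute_graph(g)
    gh <- add_explicit_hydrogens(g)
    gph <- add_explicit_hydrogens(gp)
    expect_equal(mna_descriptors(gph, 2), mna_descriptors(gh, 2))
    pq <- qna_values(g); pqp <- qna_values(gp)
    key <- function(d) paste(round(sort(d$P), 10), round(sort(d$Q), 10))
    expect_equal(key(pqp), key(pq))
  }
})

test_that("vocabulary is the sorted union and grows monotonically", {
  m <- mna_descriptors(add_explicit_hydrogens(fix_methane()), 1)
  voc <- build_vocabulary(list(m))
  expect_setequal(voc, c("-C", "-H", "-C(-H-H-H-H)", "-H(-C)"))
  expect_equal(voc, sort(voc, method = "radix"))
  e <- mna_descriptors(add_explicit_hydrogens(fix_ethanol()), 1)
  voc2 <- build_vocabulary(list(m, e))
  expect_true(all(voc %in% voc2))
  expect_error(build_vocabulary(list()), "empty")
})

test_that("QNA values have closed forms for trivial graphs", {
  props <- element_properties()
  single <- qna_values(molgraph("C"), props)
  B <- props["C", "ip_ev"] - props["C", "ea_ev"]
  A <- (props["C", "ip_ev"] + props["C", "ea_ev"]) / 2
  expect_equal(single$P, 1 / B, tolerance = 1e-12)
  expect_equal(single$Q, A / B, tolerance = 1e-12)
  # homonuclear diatomic: P_i = exp(-1/2)/B
  di <- qna_values(molgraph(c("C", "C"), rbind(c(1, 2, 1))), props)
  expect_equal(di$P, rep(exp(-0.5) / B, 2), tolerance = 1e-12)
  expect_equal(di$Q, A * di$P, tolerance = 1e-12)
})

test_that("QNA agrees with a dense matrix-exponential oracle to 1e-10", {
  set.seed(3)
  graphs <- c(fixture_graphs(),
              lapply(1:10, function(i) random_test_graph(12L)))
  for (g in graphs) {
    got <- qna_values(g)
    want <- oracle_qna(g)
    expect_equal(got$P, want$P, tolerance = 1e-10)
    expect_equal(got$Q, want$Q, tolerance = 1e-10)
  }
})

test_that("QNA Chebyshev features follow the stated layout", {
  pts <- qna_values(fix_ethanol())
  sc <- qna_scaling(list(pts))
  expect_equal(as.numeric(qna_features(pts, sc, 0)), 1)
  single <- qna_values(molgraph("C"))
  sc1 <- qna_scaling(list(qna_values(fix_ethanol()), single))
  f <- qna_features(single, sc1, 1)
  p <- scrqsar:::scale_clip(single$P, sc1$p_min, sc1$p_max, FALSE)
  q <- scrqsar:::scale_clip(single$Q, sc1$q_min, sc1$q_max, FALSE)
  expect_equal(as.numeric(f), c(1, q, p, p * q), tolerance = 1e-12)
  expect_named(f, c("qna_p0_q0", "qna_p0_q1", "qna_p1_q0", "qna_p1_q1"))
})

test_that("whole-molecule descriptors have their defining properties", {
  expect_equal(topological_length(fix_methane()), 0L)
  chain5 <- molgraph(rep("C", 5), cbind(1:4, 2:5, 1))
  expect_equal(topological_length(chain5), 4L)
  expect_equal(topological_length(fix_cyclohexane()), 3L)
  props <- element_properties()
  expect_gt(topological_volume(molgraph(c("C", "C"), rbind(c(1, 2, 1)))),
            topological_volume(fix_methane()))
  # hand summation on propane: three carbons
  expect_equal(lipophilicity(fix_propane(), props),
               3 * props["C", "logp_contrib"], tolerance = 1e-12)
  expect_equal(topological_volume(fix_propane(), props),
               3 * 4 / 3 * pi * props["C", "r_cov_a"]^3, tolerance = 1e-12)
  # order invariance
  g <- random_test_graph(8L)
  gp <- permute_graph(g)
  expect_equal(whole_molecule_descriptors(gp), whole_molecule_descriptors(g),
               tolerance = 1e-12)
  # disconnected graphs are rejected
  frag <- molgraph(c("C", "C", "C"), rbind(c(1, 2, 1)), perceive = FALSE)
  expect_error(topological_length(frag), "disconnected")
})

test_that("descriptor matrix assembles families over a fixed vocabulary", {
  set.seed(12)
  graphs <- lapply(1:12, function(i) random_test_graph(10L))
  names(graphs) <- sprintf("g%02d", 1:12)
  dc <- fit_descriptor_config(graphs, min_support = 2L)
  X <- descriptor_matrix(graphs, dc)
  expect_equal(nrow(X), 12L)
  wm <- c("topological_length", "topological_volume", "lipophilicity")
  expect_true(all(wm %in% colnames(X)))
  expect_true(all(wm %in% family_columns(X, "QNA")))
  expect_true(all(wm %in% family_columns(X, "MNA")))
  expect_equal(sum(startsWith(colnames(X), "qna_")), 9L)
  # prediction-time matrix for a subset uses the same columns
  X2 <- descriptor_matrix(graphs[1:3], dc)
  expect_equal(colnames(X2), colnames(X))
  expect_equal(X2, X[1:3, , drop = FALSE], ignore_attr = TRUE)
})
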