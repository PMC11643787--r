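test_that("SMILES records parse into graphs with correct topology", {
  g <- read_structures("CCO\tethanol\nC1CCCCC1\tcyclohexane",
                       format = "smiles", text = TRUE)
  expect_named(g, c("ethanol", "cyclohexane"))
  expect_equal(n_atoms(g$ethanol), 3L)
  expect_equal(nrow(g$ethanol$bonds), 2L)
  expect_true(all(g$ethanol$bonds$order == 1))
  expect_false(any(g$ethanol$atoms$in_ring))
  expect_equal(n_atoms(g$cyclohexane), 6L)
  expect_equal(nrow(g$cyclohexane$bonds), 6L)
  expect_true(all(g$cyclohexane$atoms$in_ring))
})

test_that("unparsable records raise indexed errors", {
  expect_error(read_structures("CCO\nnot_a_smiles((", format = "smiles",
                               text = TRUE),
               "record 2")
  expect_error(read_structures("", format = "smiles", text = TRUE), "empty")
  g <- read_structures("CCO\ta\nCCC\tb\nCCN\tc", format = "smiles",
                       text = TRUE)
  tf <- withr::local_tempfile(fileext = ".sdf")
  write_structures(g, tf)
  lines <- readLines(tf)
  delims <- grep("^[$][$][$][$]", lines)
  lines[delims[1] + 4] <- "garbage"     # counts line of record 2
  expect_error(read_structures(paste(lines, collapse = "\n"),
                               format = "sdf", text = TRUE),
               "record at index 2")
})

test_that("unsupported elements are rejected by name", {
  expect_error(read_structures("[SeH2]\tx", format = "smiles", text = TRUE),
               "Se")
})

test_that("hydrogen addition satisfies standard valences and is idempotent", {
  m <- add_explicit_hydrogens(fix_methane())
  expect_equal(n_atoms(m), 5L)
  expect_equal(sum(m$atoms$element == "H"), 4L)
  w <- add_explicit_hydrogens(fix_water())
  expect_equal(n_atoms(w), 3L)
  expect_identical(add_explicit_hydrogens(m), m)
  # heavy-atom subgraph unchanged
  e <- add_explicit_hydrogens(fix_ethanol())
  expect_equal(e$atoms$element[1:3], c("C", "C", "O"))
  expect_equal(n_atoms(e), 9L)
  # aromatic carbons: 1.5 + 1.5 + 1 H -> one hydrogen each
  b <- add_explicit_hydrogens(fix_benzene())
  expect_equal(sum(b$atoms$element == "H"), 6L)
})

test_that("ring perception flags exactly the cycle atoms", {
  expect_true(all(perceive_rings(fix_benzene())$atoms$in_ring))
  tol <- perceive_rings(fix_toluene())
  expect_equal(sum(tol$atoms$in_ring), 6L)
  expect_false(tol$atoms$in_ring[7])
  bip <- perceive_rings(fix_biphenyl())
  expect_equal(bip$atoms$in_ring, oracle_ring_atoms(bip))
  expect_true(all(bip$atoms$in_ring[c(1, 7)]))  # bridge bond endpoints
})

test_that("ring perception agrees with the edge-deletion oracle", {
  set.seed(42)
  for (i in 1:25) {
    g <- random_test_graph(12L)
    expect_equal(perceive_rings(g)$atoms$in_ring, oracle_ring_atoms(g),
                 info = paste("random graph", i))
  }
})

test_that("SDF round-trip preserves the graph", {
  graphs <- c(fixture_graphs()["ethanol"], fixture_graphs()["benzene"],
              list(rnd = random_test_graph(10L)))
  tf <- withr::local_tempfile(fileext = ".sdf")
  write_structures(graphs, tf)
  back <- read_structures(tf, format = "sdf")
  expect_named(back, names(graphs))
  for (nm in names(graphs)) {
    a <- graphs[[nm]]; b <- back[[nm]]
    expect_equal(b$atoms$element, a$atoms$element)
    expect_equal(b$atoms$in_ring, a$atoms$in_ring)
    key <- function(g) sort(paste(pmin(g$bonds$a1, g$bonds$a2),
                                  pmax(g$bonds$a1, g$bonds$a2),
                                  g$bonds$order))
    expect_equal(key(b), key(a))
  }
})

test_that("multi-fragment structures are reduced to the largest component", {
  frag <- molgraph(c("C", "C", "C", "O"),
                   rbind(c(1, 2, 1), c(2, 3, 1)), perceive = FALSE)
  expect_warning(red <- largest_component(frag), "largest component")
  expect_equal(n_atoms(red), 3L)
  expect_true(all(red$atoms$element == "C"))
})

test_that("graph validation rejects malformed bonds", {
  expect_error(molgraph(c("C", "C"), rbind(c(1, 3, 1))), "out of range")
  expect_error(molgraph(c("C", "C"), rbind(c(1, 1, 1))), "self-loop")
  expect_error(molgraph(c("C", "C"), rbind(c(1, 2, 5))), "order")
  expect_error(molgraph(c("C", "C"), rbind(c(1, 2, 1), c(2, 1, 1))),
               "duplicate")
})
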