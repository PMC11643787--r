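# Small molecular graphs built in code, plus generators used by the
# property-style tests.

fix_methane <- function() molgraph("C")
fix_water <- function() molgraph("O")
fix_ethanol <- function() molgraph(c("C", "C", "O"),
                                   rbind(c(1, 2, 1), c(2, 3, 1)))
fix_benzene <- function() {
  molgraph(rep("C", 6),
           cbind(1:6, c(2:6, 1), rep(1.5, 6)))
}
fix_cyclohexane <- function() molgraph(rep("C", 6), cbind(1:6, c(2:6, 1), 1))
fix_toluene <- function() {
  molgraph(rep("C", 7),
           rbind(cbind(1:6, c(2:6, 1), 1.5), c(1, 7, 1)))
}
fix_biphenyl <- function() {
  ring <- cbind(1:6, c(2:6, 1), 1.5)
  ring2 <- ring
  ring2[, 1:2] <- ring2[, 1:2] + 6
  molgraph(rep("C", 12), rbind(ring, ring2, c(1, 7, 1)))
}
fix_propane <- function() molgraph(rep("C", 3), rbind(c(1, 2, 1), c(2, 3, 1)))

fixture_graphs <- function() {
  list(methane = fix_methane(), water = fix_water(), ethanol = fix_ethanol(),
       benzene = fix_benzene(), cyclohexane = fix_cyclohexane(),
       toluene = fix_toluene(), biphenyl = fix_biphenyl(),
       propane = fix_propane())
}

# random connected valence-correct graph over C/N/O, <= max_atoms heavy
random_test_graph <- function(max_atoms = 12L) {
  spec <- synthetic_spec(n = 1L, seed = sample.int(1e6, 1),
                         size_range = c(3L, max_atoms), ring_prob = 0.5)
  generate_molecules(spec)[[1]]
}

# relabel atoms by a random permutation
permute_graph <- function(g, perm = sample(nrow(g$atoms))) {
  inv <- order(perm)   # inv[old] = new position
  b <- g$bonds
  out <- molgraph(g$atoms$element[perm],
                  if (nrow(b)) cbind(inv[b$a1], inv[b$a2], b$order) else NULL,
                  g$atoms$charge[perm], perceive = TRUE)
  out
}

table4_curves <- function() {
  read_curves(system.file("extdata", "lox_inhibition_curves.tsv",
                          package = "scrqsar"))
}
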