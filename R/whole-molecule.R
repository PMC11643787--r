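#' Topological length of a molecule
#'
#' Diameter of the heavy-atom graph: the largest shortest-path distance
#' (in bonds) between any pair of heavy atoms.
#'
#' @param g A `molgraph`.
#' @return Integer number of bonds (0 for a single atom).
#' @export
topological_length <- function(g) {
  h <- heavy_graph(g)
  n <- nrow(h$atoms)
  if (n == 0L) stop("no heavy atoms")
  if (n == 1L) return(0L)
  ig <- as_igraph(h)
  d <- igraph::distances(ig)
  if (any(is.infinite(d))) {
    stop("disconnected graph: reduce fragments before computing topological length")
  }
  as.integer(max(d))
}

#' Topological volume of a molecule
#'
#' Additive sphere-volume proxy: the sum over heavy atoms of
#' (4/3) * pi * r_cov^3 with single-bond covalent radii in Angstrom.
#'
#' @param g A `molgraph`.
#' @param props Element property table.
#' @return Volume in cubic Angstrom.
#' @export
topological_volume <- function(g, props = element_properties()) {
  h <- heavy_graph(g)
  if (nrow(h$atoms) == 0L) stop("no heavy atoms")
  r <- element_lookup(h$atoms$element, "r_cov_a", props)
  sum(4 / 3 * pi * r^3)
}

#' Additive atomic lipophilicity
#'
#' Sum of per-heavy-atom contributions from the element-level additive
#' logP scale in the property table.
#'
#' @param g A `molgraph`.
#' @param props Element property table.
#' @return Unitless lipophilicity estimate.
#' @export
lipophilicity <- function(g, props = element_properties()) {
  h <- heavy_graph(g)
  if (nrow(h$atoms) == 0L) stop("no heavy atoms")
  sum(element_lookup(h$atoms$element, "logp_contrib", props))
}

#' The three whole-molecule descriptors as a named vector
#'
#' @param g A `molgraph`.
#' @param props Element property table.
#' @return Numeric vector `(topological_length, topological_volume,
#'   lipophilicity)`.
#' @export
whole_molecule_descriptors <- function(g, props = element_properties()) {
  c(topological_length = as.numeric(topological_length(g)),
    topological_volume = topological_volume(g),
    lipophilicity = lipophilicity(g))
}
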