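#' Molecular graph
#'
#' Lightweight undirected graph representation of one molecule: an atom
#' table (element symbol, formal charge, ring membership flag) and a bond
#' table (endpoint indices and bond order).  Aromatic bonds are stored
#' with order 1.5; for valence arithmetic each aromatic bond contributes
#' 1.5 and the total is rounded to the nearest integer, which keeps a
#' benzene carbon at valence 4 without kekulisation.  Stereochemistry is
#' not represented: the descriptor families built on this graph are
#' purely topological.
#'
#' @param elements Character vector of element symbols.
#' @param bonds Two-column integer matrix (or data.frame) of bond
#'   endpoints, 1-based; may have a third column `order` (1, 2, 3, or
#'   1.5 for aromatic; defaults to 1).
#' @param charges Integer vector of formal charges (default 0).
#' @param perceive Logical; run ring perception immediately (default TRUE).
#' @return An object of class `molgraph` with components `atoms`
#'   (data.frame: element, charge, in_ring) and `bonds` (data.frame:
#'   a1, a2, order).
#' @export
molgraph <- function(elements, bonds = NULL, charges = 0L, perceive = TRUE) {
  elements <- as.character(elements)
  n <- length(elements)
  charges <- rep_len(as.integer(charges), n)
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = numeric())
  } else {
    bonds <- as.data.frame(bonds)
    if (ncol(bonds) == 2L) bonds$order <- 1
    names(bonds) <- c("a1", "a2", "order")
    bonds$a1 <- as.integer(bonds$a1)
    bonds$a2 <- as.integer(bonds$a2)
    bonds$order <- as.numeric(bonds$order)
  }
  g <- structure(
    list(atoms = data.frame(element = elements, charge = charges,
                            in_ring = logical(n)),
         bonds = bonds),
    class = "molgraph")
  validate_molgraph(g)
  if (perceive && n > 0L) g <- perceive_rings(g)
  g
}

validate_molgraph <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  n <- nrow(g$atoms)
  b <- g$bonds
  if (nrow(b)) {
    if (any(b$a1 < 1L | b$a1 > n | b$a2 < 1L | b$a2 > n)) {
      stop("bond endpoint out of range")
    }
    if (any(b$a1 == b$a2)) stop("self-loop bond not allowed")
    if (!all(b$order %in% c(1, 1.5, 2, 3))) {
      stop("bond order must be 1, 2, 3 or 1.5 (aromatic)")
    }
    key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
  }
  invisible(g)
}

#' Number of atoms in a molecular graph
#' @param g A `molgraph`.
#' @return Integer atom count.
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("molgraph: %d atoms (%s), %d bonds, %d in rings\n",
              nrow(x$atoms),
              paste(names(table(x$atoms$element)), table(x$atoms$element),
                    sep = ":", collapse = " "),
              nrow(x$bonds), sum(x$atoms$in_ring)))
  invisible(x)
}

as_igraph <- function(g, heavy_only = FALSE) {
  keep <- if (heavy_only) which(g$atoms$element != "H") else seq_len(nrow(g$atoms))
  idx <- match(seq_len(nrow(g$atoms)), keep)
  b <- g$bonds[g$bonds$a1 %in% keep & g$bonds$a2 %in% keep, , drop = FALSE]
  igraph::graph_from_data_frame(
    d = data.frame(from = idx[b$a1], to = idx[b$a2]),
    directed = FALSE,
    vertices = data.frame(name = seq_along(keep)))
}

#' Perceive ring membership
#'
#' Sets the `in_ring` flag of every atom: true iff the atom lies on at
#' least one cycle, i.e. iff it is incident to a bond that is not a
#' bridge of the graph.
#'
#' @param g A `molgraph`.
#' @return The graph with `in_ring` flags recomputed.
#' @export
perceive_rings <- function(g) {
  n <- nrow(g$atoms)
  g$atoms$in_ring <- logical(n)
  if (nrow(g$bonds) == 0L) return(g)
  ig <- as_igraph(g)
  br <- igraph::bridges(ig)
  cyc_edges <- setdiff(seq_len(nrow(g$bonds)), as.integer(br))
  on_cycle <- unique(c(g$bonds$a1[cyc_edges], g$bonds$a2[cyc_edges]))
  g$atoms$in_ring[on_cycle] <- TRUE
  g
}

atom_valence_sum <- function(g) {
  v <- numeric(nrow(g$atoms))
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      o <- g$bonds$order[k]
      v[g$bonds$a1[k]] <- v[g$bonds$a1[k]] + o
      v[g$bonds$a2[k]] <- v[g$bonds$a2[k]] + o
    }
  }
  v
}

#' Add explicit hydrogens to satisfy standard valences
#'
#' Appends hydrogen atoms bonded to each heavy atom until its rounded
#' bond-order sum reaches the element's standard valence (adjusted by
#' formal charge for the common cases N+ and O-).  Idempotent: atoms
#' already at valence receive nothing.
#'
#' @param g A `molgraph`.
#' @param props Element property table supplying the valence column.
#' @return A new `molgraph` whose heavy-atom subgraph equals the input.
#' @export
add_explicit_hydrogens <- function(g, props = element_properties()) {
  val <- element_lookup(g$atoms$element, "valence", props)
  # common charge adjustments: N+ gains a bond slot, O-/N- lose one
  val <- val + ifelse(g$atoms$element %in% c("N", "P"), g$atoms$charge,
                      -abs(g$atoms$charge))
  have <- round(atom_valence_sum(g))
  need <- pmax(0, round(val) - have)
  need[g$atoms$element == "H"] <- 0L
  if (!any(need > 0)) return(g)
  new_elems <- c(g$atoms$element, rep("H", sum(need)))
  new_charges <- c(g$atoms$charge, rep(0L, sum(need)))
  h_idx <- nrow(g$atoms)
  nb <- list()
  for (a in which(need > 0)) {
    for (i in seq_len(need[a])) {
      h_idx <- h_idx + 1L
      nb[[length(nb) + 1L]] <- c(a, h_idx, 1)
    }
  }
  extra <- do.call(rbind, nb)
  bonds <- rbind(as.matrix(g$bonds), extra)
  out <- molgraph(new_elems, bonds, new_charges, perceive = FALSE)
  out$atoms$in_ring <- c(g$atoms$in_ring, rep(FALSE, sum(need)))
  out
}

#' Reduce a multi-fragment structure to its largest connected component
#'
#' Salt forms and co-crystallised fragments are reduced to the largest
#' component (by atom count; ties broken by lowest first atom index),
#' with a warning, since the models operate on single structures.
#'
#' @param g A `molgraph`.
#' @return A `molgraph` containing one connected component.
#' @export
largest_component <- function(g) {
  if (nrow(g$atoms) == 0L) return(g)
  comp <- igraph::components(as_igraph(g))
  if (comp$no <= 1L) return(g)
  keep_comp <- which.max(comp$csize)
  keep <- which(comp$membership == keep_comp)
  warning(sprintf("multi-fragment structure: keeping largest component (%d of %d atoms)",
                  length(keep), nrow(g$atoms)))
  subgraph_atoms(g, keep)
}

subgraph_atoms <- function(g, keep) {
  idx <- match(seq_len(nrow(g$atoms)), keep)
  b <- g$bonds[g$bonds$a1 %in% keep & g$bonds$a2 %in% keep, , drop = FALSE]
  out <- molgraph(g$atoms$element[keep],
                  if (nrow(b)) cbind(idx[b$a1], idx[b$a2], b$order) else NULL,
                  g$atoms$charge[keep], perceive = FALSE)
  out$atoms$in_ring <- g$atoms$in_ring[keep]
  out
}

heavy_graph <- function(g) {
  keep <- which(g$atoms$element != "H")
  subgraph_atoms(g, keep)
}
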