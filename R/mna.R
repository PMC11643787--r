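#' Atom mark for MNA descriptors
#'
#' The level-0 label of an atom: its element symbol, prefixed with "-"
#' when the atom does not belong to any ring.  Formal charges and
#' isotopes do not enter the mark by default; set `with_charge = TRUE`
#' to append a +n/-n suffix.
#'
#' @param g A `molgraph` with rings perceived.
#' @param atom Atom index.
#' @param with_charge Logical; append the formal charge to the mark.
#' @return A single string.
#' @export
mna_atom_mark <- function(g, atom, with_charge = FALSE) {
  stopifnot(atom >= 1L, atom <= nrow(g$atoms))
  mark <- g$atoms$element[atom]
  if (!g$atoms$in_ring[atom]) mark <- paste0("-", mark)
  if (with_charge && g$atoms$charge[atom] != 0L) {
    mark <- paste0(mark, sprintf("%+d", g$atoms$charge[atom]))
  }
  mark
}

adjacency_list <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Multilevel Neighborhoods of Atoms descriptors
#'
#' Generates the recursive neighbourhood strings of every atom at every
#' level 0..`max_level` and aggregates them into a named count vector
#' (the molecule's MNA multiset).  The level-0 descriptor of an atom is
#' its mark; the level-k descriptor is
#' `mark(neighbour level-(k-1) descriptors, sorted lexicographically)`.
#' Hydrogens must be explicit so that the neighbourhoods are complete.
#'
#' @param g A `molgraph` (hydrogens explicit, rings perceived).
#' @param max_level Highest neighbourhood level, >= 0 (default 2).
#' @param with_charge Passed to [mna_atom_mark()].
#' @return Named integer vector: descriptor string -> occurrence count.
#' @export
mna_descriptors <- function(g, max_level = 2L, with_charge = FALSE) {
  if (max_level < 0L) stop("max_level must be >= 0")
  n <- nrow(g$atoms)
  if (n == 0L) return(integer(0))
  marks <- vapply(seq_len(n), function(a) mna_atom_mark(g, a, with_charge), "")
  adj <- adjacency_list(g)
  levels <- vector("list", max_level + 1L)
  levels[[1L]] <- marks
  if (max_level >= 1L) {
    # C-locale ordering so the canonical strings are platform-stable
    old <- Sys.getlocale("LC_COLLATE")
    on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
    Sys.setlocale("LC_COLLATE", "C")
    for (k in seq_len(max_level)) {
      prev <- levels[[k]]
      levels[[k + 1L]] <- vapply(seq_len(n), function(a) {
        nb <- prev[adj[[a]]]
        paste0(marks[a], "(", paste(sort(nb, method = "radix"), collapse = ""), ")")
      }, "")
    }
  }
  all_desc <- unlist(levels, use.names = FALSE)
  tab <- table(all_desc)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Build the descriptor vocabulary of a training set
#'
#' @param multisets List of named count vectors from [mna_descriptors()].
#' @return Sorted (C locale) character vector: the union of descriptor
#'   strings across the training molecules.
#' @export
build_vocabulary <- function(multisets) {
  if (!length(multisets)) stop("empty input: vocabulary needs >= 1 molecule")
  voc <- unique(unlist(lapply(multisets, names), use.names = FALSE))
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(voc, method = "radix")
}

#' MNA count matrix over a fixed vocabulary
#'
#' @param multisets List of named count vectors.
#' @param vocabulary Character vector from [build_vocabulary()].
#' @return Integer matrix, molecules x vocabulary; unseen strings are 0,
#'   strings outside the vocabulary are dropped (they contribute to the
#'   applicability-domain similarity instead).
#' @export
mna_count_matrix <- function(multisets, vocabulary) {
  m <- matrix(0L, nrow = length(multisets), ncol = length(vocabulary),
              dimnames = list(names(multisets), vocabulary))
  for (i in seq_along(multisets)) {
    ms <- multisets[[i]]
    hit <- intersect(names(ms), vocabulary)
    m[i, hit] <- ms[hit]
  }
  m
}

#' Tanimoto similarity between two MNA descriptor sets
#'
#' Computed on the descriptor *sets* (presence, not counts), the form
#' used by the applicability domain.
#'
#' @param a,b Named count vectors from [mna_descriptors()].
#' @return Similarity in [0, 1].
#' @export
mna_tanimoto <- function(a, b) {
  sa <- names(a); sb <- names(b)
  u <- length(union(sa, sb))
  if (u == 0L) return(0)
  length(intersect(sa, sb)) / u
}
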