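#' Fit the descriptor configuration of a training set
#'
#' Computes, once per training set, everything prediction-time
#' featurisation needs: the MNA vocabulary (optionally filtered to
#' descriptors occurring in at least `min_support` molecules, which
#' removes near-singleton strings that cannot generalise), the QNA
#' scaling box, and the element property table in use.
#'
#' @param graphs List of `molgraph` (heavy-atom structures as read).
#' @param mna_level Maximum MNA level (default 2).
#' @param qna_degree Chebyshev degree per QNA axis (default 2).
#' @param min_support Minimum number of training molecules an MNA string
#'   must occur in to enter the regression vocabulary (default 3; the
#'   full vocabulary is kept separately for the applicability domain).
#' @param props Element property table.
#' @return An object of class `descriptor_config`.
#' @export
fit_descriptor_config <- function(graphs, mna_level = 2L, qna_degree = 2L,
                                  min_support = 3L,
                                  props = element_properties()) {
  if (!length(graphs)) stop("no structures")
  graphs_h <- lapply(graphs, add_explicit_hydrogens, props = props)
  multisets <- lapply(graphs_h, mna_descriptors, max_level = mna_level)
  full_voc <- build_vocabulary(multisets)
  support <- colSums(mna_count_matrix(multisets, full_voc) > 0)
  voc <- full_voc[support >= min_support]
  if (!length(voc)) voc <- full_voc
  qna_pts <- lapply(graphs, qna_values, props = props)
  structure(list(
    mna_level = mna_level,
    qna_degree = qna_degree,
    min_support = min_support,
    vocabulary = voc,
    full_vocabulary = full_voc,
    scaling = qna_scaling(qna_pts),
    props = props
  ), class = "descriptor_config")
}

#' Descriptor matrix for a set of structures
#'
#' Assembles, under a fitted [fit_descriptor_config()] configuration,
#' the full numeric descriptor matrix: MNA counts over the training
#' vocabulary, QNA Chebyshev features, and the three whole-molecule
#' descriptors.  Column name prefixes `mna:` and `qna_` identify the
#' families.
#'
#' @param graphs List of `molgraph`.
#' @param config A `descriptor_config`.
#' @return Numeric matrix, one row per structure; attribute `multisets`
#'   carries the per-molecule MNA multisets (for the applicability
#'   domain).
#' @export
descriptor_matrix <- function(graphs, config) {
  graphs_h <- lapply(graphs, add_explicit_hydrogens, props = config$props)
  multisets <- lapply(graphs_h, mna_descriptors, max_level = config$mna_level)
  mna <- mna_count_matrix(multisets, config$vocabulary)
  colnames(mna) <- paste0("mna:", config$vocabulary)
  qna <- t(vapply(graphs, function(g) {
    as.numeric(qna_features(qna_values(g, config$props), config$scaling,
                            config$qna_degree))
  }, numeric((config$qna_degree + 1L)^2)))
  colnames(qna) <- names(qna_features(qna_values(graphs[[1]], config$props),
                                      config$scaling, config$qna_degree))
  wm <- t(vapply(graphs, whole_molecule_descriptors,
                 numeric(3), props = config$props))
  out <- cbind(mna, qna, wm)
  rownames(out) <- names(graphs)
  attr(out, "multisets") <- multisets
  out
}

#' Column names of one descriptor family plus the whole-molecule block
#'
#' @param X A matrix from [descriptor_matrix()].
#' @param family `"QNA"`, `"MNA"`, or `"all"`.
#' @return Character vector of column names.  The three whole-molecule
#'   descriptors are always included: they are in every model's
#'   candidate pool.
#' @export
family_columns <- function(X, family = c("QNA", "MNA", "all")) {
  family <- match.arg(family)
  cols <- colnames(X)
  wm <- c("topological_length", "topological_volume", "lipophilicity")
  fam <- switch(family,
                QNA = cols[startsWith(cols, "qna_")],
                MNA = cols[startsWith(cols, "mna:")],
                all = setdiff(cols, wm))
  c(fam, wm)
}

#' Export a descriptor matrix as delimited text
#'
#' @param X Matrix from [descriptor_matrix()].
#' @param path Output TSV path (compounds x named columns).
#' @return Invisibly, `path`.
#' @export
write_descriptor_matrix <- function(X, path) {
  df <- data.frame(compound = if (is.null(rownames(X))) seq_len(nrow(X))
                              else rownames(X),
                   as.data.frame(X, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
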