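#' Atomic property table for descriptor calculation
#'
#' Loads the per-element table used by the QNA and whole-molecule
#' descriptors: Mulliken-scale experimental ionization potential and
#' electron affinity (eV), single-bond covalent radius (Angstrom), an
#' element-level additive lipophilicity contribution, and the standard
#' valence used when adding explicit hydrogens.  The table ships as a
#' delimited text file so it can be swapped for an alternative
#' parameterisation.
#'
#' @param path Optional path to a replacement CSV with columns
#'   `symbol, ip_ev, ea_ev, r_cov_a, logp_contrib, valence`.
#' @return A data.frame keyed by element symbol, with the invariant
#'   `ip_ev > ea_ev` checked on load.
#' @export
element_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "element_properties.csv", package = "scrqsar")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("element property table not found: ", path)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("symbol", "ip_ev", "ea_ev", "r_cov_a", "logp_contrib", "valence")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("element property table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(tab$ip_ev <= tab$ea_ev)) {
    stop("element property table violates IP > EA for: ",
         paste(tab$symbol[tab$ip_ev <= tab$ea_ev], collapse = ", "))
  }
  rownames(tab) <- tab$symbol
  tab
}

#' Look up one property for a vector of element symbols
#'
#' @param symbols Character vector of element symbols.
#' @param property Column name in the property table.
#' @param props Property table from [element_properties()].
#' @return Numeric vector aligned with `symbols`.
#' @keywords internal
element_lookup <- function(symbols, property, props = element_properties()) {
  unknown <- setdiff(unique(symbols), rownames(props))
  if (length(unknown)) {
    stop("no ", property, " tabulated for element(s): ",
         paste(unknown, collapse = ", "))
  }
  props[symbols, property]
}
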