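#' Read molecular structures from SMILES or SDF
#'
#' Parses structures into [molgraph] objects.  SMILES input is one
#' record per line, optionally followed by a tab-separated identifier;
#' SDF input is V2000.  Parsing is delegated to ChemmineR (with
#' OpenBabel behind SMILES interpretation); each record is then
#' converted to the package's graph representation, hydrogens left as
#' given, ring membership perceived.  Multi-fragment records are
#' reduced to their largest connected component with a warning.
#'
#' @param source File path, or raw text when `text = TRUE`.
#' @param format `"smiles"` or `"sdf"`.
#' @param text Logical; treat `source` as literal text instead of a path.
#' @return A named list of `molgraph` objects, input order preserved.
#'   Unparsable records raise an error naming the record index.
#' @export
read_structures <- function(source, format = c("smiles", "sdf"), text = FALSE) {
  format <- match.arg(format)
  if (!text) {
    if (!file.exists(source)) stop("input file not found: ", source)
    lines <- readLines(source, warn = FALSE)
  } else {
    if (!nzchar(paste(source, collapse = ""))) stop("empty structure text")
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
  }
  if (format == "smiles") {
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("no SMILES records in input")
    parts <- strsplit(lines, "\t")
    smi <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1L) parts[[i]][[2L]] else sprintf("mol%03d", i)
    }, "")
    out <- vector("list", length(smi))
    for (i in seq_along(smi)) {
      sdfset <- tryCatch(
        suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smi[i], "m"))),
        error = function(e) NULL)
      if (is.null(sdfset) || !suppressWarnings(ChemmineR::validSDF(sdfset))) {
        stop(sprintf("unparsable SMILES at record %d: '%s'", i, smi[[i]]))
      }
      out[[i]] <- sdf_to_molgraph(sdfset[[1]], record = i)
    }
    names(out) <- ids
    return(out)
  }
  # SDF: split on the record delimiter and parse each record on its
  # own, so a malformed record is reported by its index
  delim <- grep("^\\${4}", lines)
  if (!length(delim) || max(delim) < length(lines)) {
    delim <- c(delim, length(lines) + 1L)
  }
  starts <- c(1L, head(delim, -1L) + 1L)
  records <- Map(function(s, e) lines[s:e], starts, delim)
  records <- records[vapply(records, function(r)
    any(nzchar(trimws(r[r != "$$$$"]))), TRUE)]
  if (!length(records)) stop("no SDF records in input")
  out <- vector("list", length(records))
  ids <- character(length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (!identical(rec[length(rec)], "$$$$")) rec <- c(rec, "$$$$")
    tmp <- tempfile(fileext = ".sdf")
    writeLines(rec, tmp)
    sdfset <- tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(tmp, skipErrors = TRUE)),
      error = function(e) NULL)
    unlink(tmp)
    ok <- !is.null(sdfset) && length(sdfset) == 1L &&
      isTRUE(suppressWarnings(ChemmineR::validSDF(sdfset))[1])
    if (!ok) stop("malformed SDF record at index ", i)
    out[[i]] <- sdf_to_molgraph(sdfset[[1]], record = i)
    h <- ChemmineR::header(sdfset[[1]])[["Molecule_Name"]]
    ids[i] <- if (is.null(h) || !nzchar(trimws(h))) sprintf("mol%03d", i)
              else trimws(h)
  }
  names(out) <- ids
  out
}

sdf_to_molgraph <- function(sdf, record = NA_integer_) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elems <- sub("_.*$", "", rownames(ab))
  known <- rownames(element_properties())
  bad <- setdiff(unique(elems), known)
  if (length(bad)) {
    stop(sprintf("unsupported element symbol(s) %s in record %s",
                 paste(bad, collapse = ", "), record))
  }
  charges <- if ("charge" %in% colnames(ab)) as.integer(ab[, "charge"]) else 0L
  bonds <- NULL
  if (NROW(bb)) {
    ord <- as.numeric(bb[, 3L])
    ord[ord == 4] <- 1.5  # SDF aromatic bond type
    bonds <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]), ord)
  }
  g <- molgraph(elems, bonds, charges, perceive = FALSE)
  g <- largest_component(g)
  perceive_rings(g)
}

#' Write molecular graphs to an SDF V2000 file
#'
#' @param graphs A list of `molgraph` objects (names used as record titles).
#' @param path Output file path; UTF-8 text.
#' @return Invisibly, `path`.
#' @export
write_structures <- function(graphs, path) {
  if (inherits(graphs, "molgraph")) graphs <- list(graphs)
  sdfs <- lapply(seq_along(graphs), function(i) {
    molgraph_to_sdf(graphs[[i]], title = name_or(graphs, i))
  })
  sdfset <- methods::new("SDFset", SDF = sdfs,
                         ID = vapply(seq_along(sdfs), function(i)
                           sprintf("CMP%d", i), ""))
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}

molgraph_to_sdf <- function(g, title = "mol") {
  n <- nrow(g$atoms)
  # the standard atom/bond block shapes ChemmineR writes and re-reads
  ab_cols <- c("C1", "C2", "C3", paste0("C", 5:16))
  ab <- matrix(0, nrow = n, ncol = length(ab_cols),
               dimnames = list(paste(g$atoms$element, seq_len(n), sep = "_"),
                               ab_cols))
  ord <- g$bonds$order
  ord[ord == 1.5] <- 4
  bb <- matrix(0, nrow = nrow(g$bonds), ncol = 7,
               dimnames = list(NULL, paste0("C", 1:7)))
  if (nrow(g$bonds)) {
    bb[, 1] <- g$bonds$a1; bb[, 2] <- g$bonds$a2; bb[, 3] <- ord
  }
  header <- c(Molecule_Name = title, Source = "scrqsar", Comment = "",
              Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                    n, nrow(g$bonds)))
  methods::new("SDF", header = header, atomblock = ab, bondblock = bb,
               datablock = character(0))
}

name_or <- function(x, i, prefix = "mol") {
  nm <- names(x)[i]
  if (is.null(names(x)) || is.na(nm) || !nzchar(nm)) sprintf("%s%03d", prefix, i)
  else nm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
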