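#' Percent inhibition from optical densities
#'
#' I = (Dc - Dt) / Dc * 100, where Dc is the optical density of the
#' control sample and Dt that of the sample containing the test
#' compound, both read at the same time point.
#'
#' @param dc Control optical density (> 0).
#' @param dt Test-sample optical density (>= 0).
#' @return Percent inhibition.
#' @export
percent_inhibition <- function(dc, dt) {
  if (any(dc <= 0)) stop("control optical density must be positive")
  if (any(dt < 0)) stop("optical density cannot be negative")
  (dc - dt) / dc * 100
}

#' Inhibition curve
#'
#' @param id Compound identifier.
#' @param concentration Concentrations in umol/L, strictly increasing.
#' @param inhibition Mean percent inhibition per concentration.
#' @param sd Optional per-point SD of inhibition.
#' @param replicates Replicate count behind each mean (default NA).
#' @return List of class `inhibition_curve`.
#' @export
inhibition_curve <- function(id, concentration, inhibition, sd = NULL,
                             replicates = NA_integer_) {
  ord <- order(concentration)
  concentration <- concentration[ord]
  inhibition <- inhibition[ord]
  if (!is.null(sd)) sd <- sd[ord]
  if (any(duplicated(concentration))) stop("duplicate concentrations in curve ", id)
  if (any(inhibition < -10 | inhibition > 110)) {
    warning("curve ", id, ": inhibition outside [-10, 110]%")
  }
  structure(list(id = id, concentration = concentration,
                 inhibition = inhibition, sd = sd, replicates = replicates),
            class = "inhibition_curve")
}

#' IC50 by linear interpolation around 50% inhibition
#'
#' Finds the bracketing pair around the first upward crossing of 50%
#' inhibition — the last point below 50 and the next point at or above
#' 50 — and interpolates linearly between them.  A point exactly at 50%
#' returns its concentration.  If the curve crosses 50% more than once
#' (noisy data), the bracketing pair whose summed |inhibition - 50| is
#' smallest is used, with a warning.  The replicate means are
#' interpolated as given; per-point SDs do not enter.
#'
#' @param curve An `inhibition_curve` (or a list with `concentration`
#'   and `inhibition`).
#' @return IC50 in umol/L (full precision; report to 1 decimal).
#' @export
ic50_interpolate <- function(curve) {
  conc <- curve$concentration
  inh <- curve$inhibition
  exact <- which(inh == 50)
  if (length(exact)) return(conc[exact[1L]])
  crossings <- which(inh[-length(inh)] < 50 & inh[-1L] > 50)
  if (!length(crossings)) {
    stop("IC50 outside tested range for curve ",
         if (!is.null(curve$id)) curve$id else "")
  }
  if (length(crossings) > 1L) {
    score <- abs(inh[crossings] - 50) + abs(inh[crossings + 1L] - 50)
    warning("multiple 50% crossings; using the pair closest to 50%")
    crossings <- crossings[which.min(score)]
  }
  lo <- crossings[1L]; hi <- lo + 1L
  conc[lo] + (50 - inh[lo]) * (conc[hi] - conc[lo]) / (inh[hi] - inh[lo])
}

#' Read inhibition curves from delimited text
#'
#' Expects a header `id, conc_uM, inhibition_pct` with an optional
#' `replicate` column; replicate rows are averaged per (id,
#' concentration) and each curve is sorted by concentration.
#'
#' @param path Path to a TSV/CSV file (separator auto-detected).
#' @return Named list of `inhibition_curve` objects (input order of
#'   first appearance).
#' @export
read_curves <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) return(list())
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!nrow(df)) return(list())
  need <- c("id", "conc_uM", "inhibition_pct")
  if (!all(need %in% names(df))) {
    stop("curve table needs columns: ", paste(need, collapse = ", "))
  }
  if ("replicate" %in% names(df)) {
    key <- paste(df$id, df$conc_uM, df$replicate)
    if (anyDuplicated(key)) {
      stop("duplicate (id, concentration, replicate) rows")
    }
  }
  ids <- unique(df$id)
  out <- lapply(ids, function(cid) {
    sub <- df[df$id == cid, , drop = FALSE]
    agg <- stats::aggregate(inhibition_pct ~ conc_uM, data = sub, FUN = mean)
    reps <- stats::aggregate(inhibition_pct ~ conc_uM, data = sub,
                             FUN = length)$inhibition_pct
    sds <- if (any(reps > 1)) {
      stats::aggregate(inhibition_pct ~ conc_uM, data = sub,
                       FUN = stats::sd)$inhibition_pct
    } else NULL
    inhibition_curve(as.character(cid), agg$conc_uM, agg$inhibition_pct,
                     sd = sds, replicates = max(reps))
  })
  names(out) <- as.character(ids)
  out
}

#' IC50/pIC50 table from a set of inhibition curves
#'
#' @param curves Named list of `inhibition_curve` objects, or a path
#'   readable by [read_curves()].
#' @return Data frame: id, ic50_umol (rounded to 1 decimal), pic50
#'   (rounded to 3 decimals, computed from the unrounded IC50), and an
#'   `error` column holding per-curve failure messages (NA when
#'   successful); failures do not abort the run.
#' @export
run_assay <- function(curves) {
  if (is.character(curves)) curves <- read_curves(curves)
  if (!length(curves)) {
    return(data.frame(id = character(), ic50_umol = numeric(),
                      pic50 = numeric(), error = character()))
  }
  rows <- lapply(curves, function(cv) {
    ic50 <- tryCatch(ic50_interpolate(cv), error = function(e)
      structure(NA_real_, msg = conditionMessage(e)))
    if (is.na(ic50)) {
      data.frame(id = cv$id, ic50_umol = NA_real_, pic50 = NA_real_,
                 error = attr(ic50, "msg"))
    } else {
      data.frame(id = cv$id, ic50_umol = round(ic50, 1),
                 pic50 = round(pic50_from_ic50(ic50), 3),
                 error = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
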