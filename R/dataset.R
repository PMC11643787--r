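#' Activity data set
#'
#' Couples an ordered table of compound activities with their molecular
#' structures.  Activities are held as pIC50 (the negative decimal
#' logarithm of IC50 in mol/L); an IC50 column in umol/L may be carried
#' alongside and is checked for consistency.
#'
#' @param ids Character vector of compound identifiers.
#' @param structures List of `molgraph` objects (may be NULL for
#'   activity-only operations such as splitting).
#' @param pic50 Numeric pIC50 values; if missing, computed from `ic50`.
#' @param ic50 Numeric IC50 in umol/L (optional).
#' @return An object of class `activity_dataset` with components
#'   `records` (data.frame: id, pic50, ic50) and `structures`.
#' @export
activity_dataset <- function(ids, structures = NULL, pic50 = NULL, ic50 = NULL) {
  ids <- as.character(ids)
  if (is.null(pic50)) {
    if (is.null(ic50)) stop("need pic50 or ic50")
    pic50 <- pic50_from_ic50(ic50)
  }
  if (!is.null(ic50)) {
    bad <- abs(pic50 - pic50_from_ic50(ic50)) > 5e-4
    if (any(bad)) {
      stop("inconsistent ic50/pic50 for: ", paste(ids[bad], collapse = ", "))
    }
  }
  if (any(!is.finite(pic50))) stop("non-finite pIC50")
  if (!is.null(structures) && length(structures) != length(ids)) {
    stop("structures and ids differ in length")
  }
  structure(list(
    records = data.frame(id = ids, pic50 = pic50,
                         ic50 = if (is.null(ic50)) NA_real_ else ic50),
    structures = structures
  ), class = "activity_dataset")
}

#' @export
print.activity_dataset <- function(x, ...) {
  cat(sprintf("activity_dataset: %d compounds, pIC50 mean %.3f, range %.3f\n",
              nrow(x$records), mean(x$records$pic50),
              diff(range(x$records$pic50))))
  invisible(x)
}

#' @export
length.activity_dataset <- function(x) nrow(x$records)

subset_dataset <- function(ds, idx) {
  structure(list(records = ds$records[idx, , drop = FALSE],
                 structures = if (is.null(ds$structures)) NULL
                              else ds$structures[idx]),
            class = "activity_dataset")
}

#' Convert IC50 (umol/L) to pIC50
#'
#' pIC50 = -log10(IC50 * 1e-6), i.e. the negative decimal logarithm of
#' the molar concentration.  Reported to 3 decimals in printed outputs;
#' returned at full precision.
#'
#' @param ic50 Positive IC50 values in umol/L.
#' @return pIC50 values.
#' @export
pic50_from_ic50 <- function(ic50) {
  if (any(ic50 <= 0)) stop("IC50 must be positive")
  -log10(ic50 * 1e-6)
}

#' Convert pIC50 back to IC50 in umol/L
#' @param pic50 pIC50 values.
#' @return IC50 in umol/L.
#' @export
ic50_from_pic50 <- function(pic50) 10^(-pic50) * 1e6

#' Ranked every-period train/test split
#'
#' Sorts the compounds in ascending pIC50 (stable with respect to input
#' order on ties) and transfers every `period`-th compound of the ranked
#' sequence (positions period, 2*period, ..., 1-based) to the test set;
#' the remainder forms the training set.  With the default period 6 this
#' realises a 5:1 split whose test set spans the whole activity range.
#'
#' @param ds An `activity_dataset`.
#' @param period Integer >= 2 (default 6).
#' @return List with `train` and `test` (both `activity_dataset`, in
#'   ranked order) and `period`.
#' @export
ranked_split <- function(ds, period = 6L) {
  n <- nrow(ds$records)
  if (period < 2L) stop("period must be >= 2")
  if (n < period) stop("need at least ", period, " records to split")
  ord <- order(ds$records$pic50)          # stable in R
  take <- seq(period, n, by = period)
  test_idx <- ord[take]
  train_idx <- ord[-take]
  list(train = subset_dataset(ds, train_idx),
       test = subset_dataset(ds, test_idx),
       period = as.integer(period))
}

#' Activity-set summary statistics and evaluation thresholds
#'
#' Computes the set size, mean pIC50, activity range Delta = max - min,
#' the evaluation thresholds 0.10/0.15/0.20/0.25 * Delta (rounded to 3
#' decimals, the bands against which MAE and the B criterion are
#' judged), and the percentage of observations falling within +/-0.5,
#' 1.0, 1.5, 2.0 pIC50 units of a reference mean.
#'
#' @param ds An `activity_dataset` (>= 2 records).
#' @param reference_mean Centre of the windows; defaults to the set's
#'   own mean (use the training mean to characterise a test set).
#' @return List of class `set_statistics`.
#' @export
set_statistics <- function(ds, reference_mean = NULL) {
  y <- ds$records$pic50
  if (length(y) < 2L) stop("need >= 2 records")
  delta <- max(y) - min(y)
  if (delta == 0) stop("zero activity range")
  if (is.null(reference_mean)) reference_mean <- mean(y)
  widths <- c(0.5, 1.0, 1.5, 2.0)
  fractions <- vapply(widths, function(w)
    100 * mean(abs(y - reference_mean) <= w), 0)
  names(fractions) <- sprintf("within_%.1f", widths)
  structure(list(
    n = length(y),
    mean_pic50 = mean(y),
    delta_pic50 = delta,
    thresholds = round(c(`0.10` = 0.10, `0.15` = 0.15,
                         `0.20` = 0.20, `0.25` = 0.25) * delta, 3),
    reference_mean = reference_mean,
    window_fractions = fractions
  ), class = "set_statistics")
}

#' @export
print.set_statistics <- function(x, ...) {
  cat(sprintf("n = %d, mean pIC50 = %.3f, delta pIC50 = %.3f\n",
              x$n, x$mean_pic50, x$delta_pic50))
  cat("thresholds:", paste(sprintf("%sxD=%.3f", names(x$thresholds),
                                   x$thresholds), collapse = "  "), "\n")
  cat("window fractions (%):",
      paste(sprintf("%s=%.3f", names(x$window_fractions),
                    x$window_fractions), collapse = "  "), "\n")
  invisible(x)
}

#' Check the activity-range precondition for modelling
#'
#' Regression on an activity set is considered well-posed only when the
#' pIC50 range strictly exceeds 3 log units.
#'
#' @param ds An `activity_dataset`.
#' @return TRUE iff Delta pIC50 > 3.
#' @export
check_modeling_precondition <- function(ds) {
  y <- ds$records$pic50
  if (length(y) < 2L) stop("need >= 2 records")
  diff(range(y)) > 3
}

#' Read an activity table from delimited text
#'
#' Expects a header with columns `id`, one of `smiles`/`sdf`, and one of
#' `ic50_umol`/`pic50`.
#'
#' @param path Path to a TSV/CSV file (separator auto-detected from the
#'   header line).
#' @return An `activity_dataset` (structures parsed when a `smiles`
#'   column is present).
#' @export
read_activity_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("activity table needs an 'id' column")
  structures <- NULL
  if ("smiles" %in% names(df)) {
    structures <- read_structures(paste(df$smiles, df$id, sep = "\t",
                                        collapse = "\n"),
                                  format = "smiles", text = TRUE)
  }
  activity_dataset(df$id, structures,
                   pic50 = if ("pic50" %in% names(df)) df$pic50 else NULL,
                   ic50 = if ("ic50_umol" %in% names(df)) df$ic50_umol else NULL)
}

#' Write a split manifest as two-column delimited text
#'
#' @param split Result of [ranked_split()].
#' @param path Output TSV path (columns: id, subset).
#' @return Invisibly, `path`.
#' @export
write_split_manifest <- function(split, path) {
  df <- rbind(data.frame(id = split$train$records$id, subset = "train"),
              data.frame(id = split$test$records$id, subset = "test"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
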