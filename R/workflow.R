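#' Run configuration for the consensus-model grid
#'
#' Bundles every tunable of a grid run so that outputs are reproducible
#' and self-describing; the configuration is echoed into the output
#' directory as JSON.
#'
#' @param seed Top-level integer seed.
#' @param mna_level,qna_degree,min_support Descriptor settings.
#' @param split_period Ranked-split period (default 6, a 5:1 split).
#' @param n_partials_single,n_partials_mixed Partial-model pool sizes
#'   for single-family and mixed-family consensus models (20 / 320).
#' @param lmo_rounds,lmo_fraction Leave-many-out settings (20 rounds of
#'   20%).
#' @param trim_fraction Worst-case trim for the 95% metric blocks.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, mna_level = 2L, qna_degree = 2L,
                       min_support = 3L, split_period = 6L,
                       n_partials_single = 20L, n_partials_mixed = 320L,
                       lmo_rounds = 20L, lmo_fraction = 0.2,
                       trim_fraction = 0.05) {
  structure(list(seed = as.integer(seed), mna_level = as.integer(mna_level),
                 qna_degree = as.integer(qna_degree),
                 min_support = as.integer(min_support),
                 split_period = as.integer(split_period),
                 n_partials_single = as.integer(n_partials_single),
                 n_partials_mixed = as.integer(n_partials_mixed),
                 lmo_rounds = as.integer(lmo_rounds),
                 lmo_fraction = lmo_fraction,
                 trim_fraction = trim_fraction),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with a subset of the [run_config()] fields;
#'   unknown keys are rejected.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Write a run configuration as JSON
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

grid_cells <- function() {
  # model numbering: rows of the summary table; M1-M9 on the first
  # training set, M10-M18 on the second, families x methods in the
  # order QNA, MNA, both within each method
  data.frame(
    model = 1:18,
    train_set = rep(c("TrS1", "TrS2"), each = 9),
    method = rep(rep(c("SCR", "RBF-SCR", "Both"), each = 3), 2),
    families = rep(c("QNA", "MNA", "both"), 6)
  )
}

#' Run the full consensus-model grid
#'
#' Executes the complete study design on one activity set: ranked 5:1
#' splitting into a primary training set and external test set, a second
#' ranked split of the primary training set (internal test set), and the
#' 18-cell grid {SCR, RBF-SCR, Both} x {QNA, MNA, both} x {two training
#' sets}.  Single-family cells carry 20 partial models, mixed-family
#' cells 320.  Every model gets a descriptive summary (mean R2, LMO Q2,
#' F, SD, variable count, stability A) and 100%/95% external-validation
#' reports on its training and test sets.
#'
#' @param ds An `activity_dataset` with structures (must pass the
#'   activity-range precondition).
#' @param config A [run_config()].
#' @param outdir Optional output directory; when given, the summary
#'   table, per-model metric reports (`M01` ... `M18`), split manifests
#'   and the echoed configuration are written there.
#' @param save_models Also serialise each consensus model as JSON
#'   (large; default FALSE).
#' @param progress Print one line per fitted model.
#' @return List: `models` (18 `consensus_model`s named M01..M18),
#'   `summary` (Table-style data frame), `reports` (per-model list of
#'   metric pairs), `splits`.
#' @export
run_grid <- function(ds, config = run_config(), outdir = NULL,
                     save_models = FALSE, progress = FALSE) {
  if (!check_modeling_precondition(ds)) {
    stop("activity range precondition failed: delta pIC50 must exceed 3")
  }
  sp1 <- ranked_split(ds, config$split_period)
  sp2 <- ranked_split(sp1$train, config$split_period)
  sets <- list(TrS1 = sp1$train, TrS2 = sp2$train,
               TS1 = sp1$test, TS2 = sp2$test)
  scfg <- scr_config()
  desc <- list(
    TrS1 = fit_descriptor_config(sets$TrS1$structures, config$mna_level,
                                 config$qna_degree, config$min_support),
    TrS2 = fit_descriptor_config(sets$TrS2$structures, config$mna_level,
                                 config$qna_degree, config$min_support))
  cells <- grid_cells()
  models <- vector("list", 18L)
  reports <- vector("list", 18L)
  names(models) <- names(reports) <- sprintf("M%02d", cells$model)
  summary_rows <- vector("list", 18L)
  for (i in seq_len(18L)) {
    cell <- cells[i, ]
    train <- sets[[cell$train_set]]
    n_partials <- if (cell$families == "both") config$n_partials_mixed
                  else config$n_partials_single
    m <- build_consensus(train, method = cell$method,
                         families = cell$families, n_partials = n_partials,
                         seed = config$seed + cell$model,
                         config = scfg, desc_config = desc[[cell$train_set]],
                         lmo_rounds = config$lmo_rounds,
                         lmo_fraction = config$lmo_fraction)
    test_sets <- if (cell$train_set == "TrS1") "TS1" else c("TS1", "TS2")
    rep_i <- list()
    pred_tr <- predict(m, stats::setNames(train$structures,
                                          train$records$id))
    rep_i$train <- metric_report_pair(train$records$pic50,
                                      pred_tr$predicted, m$train_mean,
                                      config$trim_fraction)
    for (tsname in test_sets) {
      tset <- sets[[tsname]]
      pred <- predict(m, stats::setNames(tset$structures, tset$records$id),
                      force = TRUE)
      rep_i[[tsname]] <- metric_report_pair(tset$records$pic50,
                                            pred$predicted, m$train_mean,
                                            config$trim_fraction)
    }
    primary_ts <- if (cell$train_set == "TrS1") "TS1" else "TS2"
    m$rmsep <- c(full = rep_i[[primary_ts]]$full$rmse,
                 trimmed = rep_i[[primary_ts]]$trimmed$rmse)
    models[[i]] <- m
    reports[[i]] <- rep_i
    s <- m$summary
    summary_rows[[i]] <- data.frame(
      train_set = cell$train_set, method = cell$method,
      model = sprintf("M%d", cell$model), n = nrow(train$records),
      n_pm = n_partials, r2 = s$r2_mean, q2_lmo = s$q2_lmo_mean,
      f = s$f_mean, sd = s$sd_mean, v = s$v_mean,
      a = as.numeric(s$stability))
    if (progress) {
      message(sprintf("fitted M%02d (%s/%s/%s, %d partials): R2=%.3f Q2=%.3f",
                      cell$model, cell$train_set, cell$method, cell$families,
                      n_partials, s$r2_mean, s$q2_lmo_mean))
    }
  }
  summary <- do.call(rbind, summary_rows)
  out <- list(models = models, summary = summary, reports = reports,
              splits = list(split1 = sp1, split2 = sp2), config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_run_config(config, file.path(outdir, "config.json"))
    utils::write.table(data.frame(summary, check.names = FALSE),
                       file.path(outdir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_split_manifest(sp1, file.path(outdir, "split_primary.tsv"))
    write_split_manifest(sp2, file.path(outdir, "split_secondary.tsv"))
    for (i in seq_len(18L)) {
      mdir <- file.path(outdir, names(models)[i])
      dir.create(mdir, showWarnings = FALSE)
      for (blk in names(reports[[i]])) {
        write_metric_report(reports[[i]][[blk]],
                            file.path(mdir, sprintf("metrics_%s.tsv", blk)))
      }
      if (save_models) {
        consensus_save(models[[i]], file.path(mdir, "model.json"))
      }
    }
  }
  out
}

#' Evaluate a consensus model on external compounds
#'
#' Predicts the external structures, compares against experimental
#' values within the +/- 2*RMSEP confidence window, and lists
#' out-of-domain compounds separately rather than dropping them.
#'
#' @param model A `consensus_model` with a stored RMSEP (from
#'   [run_grid()]), or supply `rmsep` explicitly.
#' @param structures Named list of `molgraph`.
#' @param experimentals Experimental pIC50 values aligned with
#'   `structures`.
#' @param rmsep Optional RMSEP override; by default the smallest stored
#'   value is used.
#' @return List: `report` (prediction-window rows for in-domain
#'   compounds), `out_of_domain` (ids), `predictions` (full prediction
#'   table).
#' @export
run_evaluate <- function(model, structures, experimentals, rmsep = NULL) {
  if (is.null(rmsep)) {
    if (is.null(model$rmsep)) stop("model has no stored RMSEP; supply rmsep")
    rmsep <- min(model$rmsep)
  }
  pred <- predict(model, structures, force = TRUE)
  in_ad <- pred$in_ad
  report <- prediction_window_report(rmsep, pred$predicted[in_ad],
                                     experimentals[in_ad],
                                     ids = pred$id[in_ad])
  list(report = report, out_of_domain = pred$id[!in_ad], predictions = pred)
}
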