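#' Serialise a consensus model to JSON
#'
#' Writes a self-contained text archive: descriptor configuration
#' (vocabulary, QNA scaling, property table), every partial model's
#' selected variables and coefficients (SCR) or centres/weights/width
#' (RBF-SCR), the applicability-domain data, summary statistics and the
#' seed.
#'
#' @param model A `consensus_model`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
consensus_save <- function(model, path) {
  dc <- model$desc_config
  partial_to_list <- function(pm) {
    base <- list(method = pm$method, family = pm$family,
                 variables = as.list(pm$variables))
    if (inherits(pm, "scr_model")) {
      c(base, list(coef = as.list(pm$coef), intercept = pm$intercept,
                   lambda = pm$lambda, r2 = pm$r2,
                   degenerate = pm$degenerate))
    } else {
      c(base, list(centers = pm$centers, weights = pm$weights,
                   width = pm$width, ybar = pm$ybar, ctr = as.list(pm$ctr),
                   sdz = as.list(pm$sdz), r2 = pm$r2, lambda = pm$lambda,
                   degenerate = pm$degenerate))
    }
  }
  obj <- list(
    format = "scrqsar-consensus-1",
    method = model$method, families = model$families,
    n_partials = model$n_partials, seed = model$seed,
    desc_config = list(mna_level = dc$mna_level, qna_degree = dc$qna_degree,
                       min_support = dc$min_support,
                       vocabulary = dc$vocabulary,
                       full_vocabulary = dc$full_vocabulary,
                       scaling = unclass(dc$scaling),
                       props = dc$props),
    partials = lapply(model$partials, partial_to_list),
    ad = list(train_multisets = lapply(model$ad$train_multisets, as.list),
              wm_range = model$ad$wm_range,
              tanimoto_min = model$ad$tanimoto_min,
              range_expand = model$ad$range_expand),
    summary = list(r2_mean = model$summary$r2_mean,
                   q2_lmo_mean = model$summary$q2_lmo_mean,
                   f_mean = model$summary$f_mean,
                   sd_mean = model$summary$sd_mean,
                   v_mean = model$summary$v_mean),
    train_ids = model$train_ids, train_mean = model$train_mean,
    train_range = model$train_range, rmsep = model$rmsep)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a consensus model from a JSON archive
#'
#' @param path Archive written by [consensus_save()].
#' @return A `consensus_model` usable with [predict.consensus_model()].
#' @export
consensus_load <- function(path) {
  # parse without simplification: heterogeneous partial models would
  # otherwise be coerced into ragged tables
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "scrqsar-consensus-1")) {
    stop("not a consensus-model archive: ", path)
  }
  num <- function(x) if (is.null(x)) numeric(0) else
    vapply(x, function(v) as.numeric(v), 0)
  chr <- function(x) if (is.null(x)) character(0) else
    vapply(x, function(v) as.character(v), "")
  props <- do.call(rbind, lapply(obj$desc_config$props, function(row)
    data.frame(symbol = row$symbol, ip_ev = row$ip_ev, ea_ev = row$ea_ev,
               r_cov_a = row$r_cov_a, logp_contrib = row$logp_contrib,
               valence = row$valence)))
  rownames(props) <- props$symbol
  sc <- obj$desc_config$scaling
  sc <- structure(list(p_min = sc$p_min, p_max = sc$p_max,
                       q_min = sc$q_min, q_max = sc$q_max,
                       p_degenerate = isTRUE(sc$p_degenerate),
                       q_degenerate = isTRUE(sc$q_degenerate)),
                  class = "qna_scaling")
  dc <- structure(list(
    mna_level = obj$desc_config$mna_level,
    qna_degree = obj$desc_config$qna_degree,
    min_support = obj$desc_config$min_support,
    vocabulary = chr(obj$desc_config$vocabulary),
    full_vocabulary = chr(obj$desc_config$full_vocabulary),
    scaling = sc, props = props), class = "descriptor_config")
  restore_partial <- function(p) {
    vars <- chr(p$variables)
    if (identical(p$method, "SCR")) {
      structure(list(method = "SCR", family = p$family, variables = vars,
                     coef = stats::setNames(num(p$coef), vars),
                     intercept = p$intercept, lambda = p$lambda, r2 = p$r2,
                     degenerate = isTRUE(p$degenerate)),
                class = "scr_model")
    } else {
      centers <- matrix(num(unlist(p$centers, recursive = FALSE)),
                        ncol = max(1L, length(vars)), byrow = TRUE)
      colnames(centers) <- vars
      structure(list(method = "RBF-SCR", family = p$family, variables = vars,
                     centers = centers, weights = num(p$weights),
                     width = p$width, ybar = p$ybar,
                     ctr = stats::setNames(num(p$ctr), vars),
                     sdz = stats::setNames(num(p$sdz), vars),
                     r2 = p$r2, lambda = p$lambda,
                     degenerate = isTRUE(p$degenerate)),
                class = "rbf_scr_model")
    }
  }
  partials <- lapply(obj$partials, restore_partial)
  wm_range <- matrix(num(unlist(obj$ad$wm_range, recursive = FALSE)),
                     nrow = 2, byrow = TRUE)
  colnames(wm_range) <- c("topological_length", "topological_volume",
                          "lipophilicity")
  multisets <- lapply(obj$ad$train_multisets, function(ms)
    stats::setNames(vapply(ms, as.integer, 0L), names(ms)))
  summ <- list(r2_mean = obj$summary$r2_mean,
               q2_lmo_mean = obj$summary$q2_lmo_mean,
               f_mean = obj$summary$f_mean,
               sd_mean = obj$summary$sd_mean,
               v_mean = obj$summary$v_mean)
  summ$stability <- stability(max(-1, min(1, summ$r2_mean)),
                              max(-1, min(1, summ$q2_lmo_mean)))
  structure(list(
    method = obj$method, families = obj$families,
    n_partials = obj$n_partials, seed = obj$seed,
    partials = partials, desc_config = dc,
    ad = list(train_multisets = multisets, wm_range = wm_range,
              tanimoto_min = obj$ad$tanimoto_min,
              range_expand = obj$ad$range_expand),
    summary = summ,
    train_ids = chr(obj$train_ids), train_mean = obj$train_mean,
    train_range = obj$train_range, rmsep = num(obj$rmsep)),
    class = "consensus_model")
}
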