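#' Boosted-regression-tree configuration
#'
#' Hyper-parameters of the stochastic gradient-boosted regression trees
#' used to attribute dispersal success to predictors: learning rate 0.075
#' for the full-parameter model and 0.025 for the trait-only model, tree
#' complexity (interaction depth) 5, bag fraction 0.75, squared-error
#' (Gaussian) loss.  The ensemble size is chosen by cross-validated early
#' stopping.
#'
#' @param learning_rate Shrinkage per tree.
#' @param tree_complexity Maximum tree depth.
#' @param bag_fraction Subsample fraction per tree.
#' @param n_folds Cross-validation folds for the tree-count rule.
#' @param max_trees Upper bound on ensemble size.
#' @param patience Early-stopping rounds without CV improvement.
#' @return A `brt_config` list.
#' @export
brt_config <- function(learning_rate = 0.075, tree_complexity = 5L,
                       bag_fraction = 0.75, n_folds = 5L,
                       max_trees = 4000L, patience = 50L) {
  if (learning_rate <= 0 || learning_rate >= 1)
    stop("`learning_rate` must lie in (0, 1)", call. = FALSE)
  if (bag_fraction <= 0 || bag_fraction > 1)
    stop("`bag_fraction` must lie in (0, 1]", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 tree_complexity = as.integer(tree_complexity),
                 bag_fraction = bag_fraction, n_folds = as.integer(n_folds),
                 max_trees = as.integer(max_trees),
                 patience = as.integer(patience)),
            class = "brt_config")
}

#' Fit a boosted regression tree ensemble
#'
#' Stochastic gradient boosting with squared-error loss on a numeric
#' predictor table.  The number of trees is selected by `n_folds`-fold
#' cross-validated early stopping (bounded by `max_trees`), then the final
#' ensemble is refitted on all rows.  Deterministic for a fixed R random
#' seed.
#'
#' @param X Data frame or matrix of numeric predictors.
#' @param y Numeric response (dispersal success proportions).
#' @param cfg A [brt_config()].
#' @return A `dispersim_brt` object wrapping the fitted booster with
#'   `n_trees`, the predictor names and the configuration.
#' @export
fit_brt <- function(X, y, cfg = brt_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) < 2L) stop("need at least two predictors", call. = FALSE)
  if (nrow(X) < 50L) stop("need at least 50 rows", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in predictors or response", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  out <- list(features = colnames(X), cfg = cfg, y_mean = mean(y))
  if (stats::var(y) == 0) {         # degenerate: predict the mean, no splits
    out$booster <- NULL
    out$n_trees <- 0L
    class(out) <- "dispersim_brt"
    return(out)
  }
  params <- list(objective = "reg:squarederror",
                 eta = cfg$learning_rate,
                 max_depth = cfg$tree_complexity,
                 subsample = cfg$bag_fraction,
                 nthread = 1)
  dm <- xgboost::xgb.DMatrix(X, label = y)
  cv <- xgboost::xgb.cv(params = params, data = dm, nrounds = cfg$max_trees,
                        nfold = cfg$n_folds,
                        early_stopping_rounds = cfg$patience, verbose = 0)
  best <- cv$early_stop$best_iteration
  if (is.null(best)) best <- cv$best_iteration       # older xgboost layout
  if (is.null(best) || is.na(best)) best <- cfg$max_trees
  out$booster <- xgboost::xgb.train(params = params, data = dm,
                                    nrounds = best, verbose = 0)
  out$n_trees <- as.integer(best)
  class(out) <- "dispersim_brt"
  out
}

#' @export
predict.dispersim_brt <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (is.null(object$booster)) return(rep(object$y_mean, nrow(newdata)))
  stats::predict(object$booster, newdata)
}

#' @export
print.dispersim_brt <- function(x, ...) {
  cat(sprintf("boosted regression trees: %d trees (lr %.3f, depth %d, bag %.2f), %d predictors\n",
              x$n_trees, x$cfg$learning_rate, x$cfg$tree_complexity,
              x$cfg$bag_fraction, length(x$features)))
  invisible(x)
}

#' Relative influence of predictors
#'
#' Friedman-style split-improvement importance: the total squared-error
#' gain attributed to each predictor across all splits of the ensemble,
#' normalized to sum to 100.  Predictors never used in a split get 0; a
#' degenerate (constant-response) model reports all zeros.
#'
#' @param model A fitted [fit_brt()] model.
#' @return Data frame with `predictor` and `influence` (percent), sorted
#'   decreasing.
#' @export
relative_influence <- function(model) {
  if (!inherits(model, "dispersim_brt"))
    stop("`model` must be a fitted dispersim_brt", call. = FALSE)
  infl <- stats::setNames(rep(0, length(model$features)), model$features)
  if (!is.null(model$booster)) {
    imp <- xgboost::xgb.importance(model = model$booster)
    infl[imp$Feature] <- imp$Gain * 100
  }
  out <- data.frame(predictor = names(infl), influence = unname(infl))
  out <- out[order(-out$influence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantile-regression slopes of success on trait investment
#'
#' For each trait, fits a univariate linear quantile regression of
#' dispersal success on that trait's investment share at quantile `tau`
#' (default 0.25 -- the lower envelope of the success distribution),
#' separately within each (habitat amount, aggregation) environment.
#'
#' @param table Budget-experiment results ([run_budget_experiment()]):
#'   needs `success`, the `share_*` columns, `hab_amount` and `hab_agg`.
#' @param tau Quantile level (default 0.25).
#' @param traits Trait names to fit (default all five).
#' @return A `quantile_fit` data frame with `hab_amount`, `hab_agg`,
#'   `trait`, `slope`, `se`, `tau`; constant share columns are flagged
#'   with `NA` slopes.
#' @export
quantile_slopes <- function(table, tau = 0.25,
                            traits = c("speed", "range", "mortality",
                                       "min_area", "foraging")) {
  stopifnot(is.data.frame(table), "success" %in% names(table))
  cols <- paste0("share_", traits)
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  envs <- unique(table[, c("hab_amount", "hab_agg"), drop = FALSE])
  rows <- list()
  for (e in seq_len(nrow(envs))) {
    sub <- table[table$hab_amount == envs$hab_amount[e] &
                 table$hab_agg == envs$hab_agg[e], , drop = FALSE]
    if (nrow(sub) < 30L)
      stop("need >= 30 rows per environment", call. = FALSE)
    for (j in seq_along(traits)) {
      x <- sub[[cols[j]]]
      if (stats::sd(x) == 0) {
        slope <- NA_real_; se <- NA_real_
      } else {
        fit <- quantreg::rq(sub$success ~ x, tau = tau)
        slope <- unname(stats::coef(fit)[2])
        # "nid" sandwich standard errors; degenerate fits (e.g. an exact
        # line) make the local density estimate singular -> NA
        se <- tryCatch(
          suppressWarnings(
            summary(fit, se = "nid", covariance = TRUE)$coefficients[2, 2]),
          error = function(e) NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        hab_amount = envs$hab_amount[e], hab_agg = envs$hab_agg[e],
        trait = traits[j], slope = slope, se = se, tau = tau)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("quantile_fit", class(out))
  out
}

#' Payoff ratios standardized to movement speed
#'
#' Divides each trait's quantile-regression slope by the slope for
#' movement speed within the same environment; signs are preserved, so
#' negative payoffs remain negative.  Speed's own ratio is identically 1.
#'
#' @param fit A [quantile_slopes()] result.
#' @return Data frame with `hab_amount`, `hab_agg`, `trait`, `slope`,
#'   `ratio`.
#' @export
payoff_ratios <- function(fit) {
  stopifnot(inherits(fit, "quantile_fit") || is.data.frame(fit))
  envs <- unique(fit[, c("hab_amount", "hab_agg"), drop = FALSE])
  rows <- list()
  for (e in seq_len(nrow(envs))) {
    sub <- fit[fit$hab_amount == envs$hab_amount[e] &
               fit$hab_agg == envs$hab_agg[e], , drop = FALSE]
    s_speed <- sub$slope[sub$trait == "speed"]
    if (length(s_speed) != 1L || is.na(s_speed) || s_speed == 0)
      stop("speed slope missing or zero; payoff ratios undefined",
           call. = FALSE)
    sub$ratio <- sub$slope / s_speed
    rows[[length(rows) + 1L]] <-
      sub[, c("hab_amount", "hab_agg", "trait", "slope", "ratio")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
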