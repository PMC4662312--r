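#' Default predictor category map
#'
#' Assigns each of the nine standard predictors to a climate, soil or
#' topographic category: climate = `gsai`, `tmaysep`, `pmaysep`; soil =
#' `ph`, `clay`, `sieve10`, `sprod`; topographic = `elvmax`, `sieve200`.
#' Fully user-editable: pass any named character vector to
#' [group_importance()].
#'
#' @return Named character vector (predictor -> category).
#' @export
predictor_categories <- function() {
  c(gsai = "climate", tmaysep = "climate", pmaysep = "climate",
    ph = "soil", clay = "soil", sieve10 = "soil", sprod = "soil",
    elvmax = "topo", sieve200 = "topo")
}

#' Growing-season climate sub-categories
#'
#' Splits the climate predictors into growing-season moisture (`gsai`,
#' `pmaysep`) and growing-season temperature (`tmaysep`).
#'
#' @return Named character vector (predictor -> category).
#' @export
climate_categories <- function() {
  c(gsai = "gs_moisture", pmaysep = "gs_moisture",
    tmaysep = "gs_temperature")
}

#' Group raw predictor importances into category percentages
#'
#' Sums (non-negative) raw importances within each category of the map and
#' expresses each category as a percentage of the mapped total, so the
#' percentages sum to 100.  Negative raw importances (possible for
#' permutation importance of irrelevant predictors) are floored at zero
#' before grouping.
#'
#' @param importance Named numeric vector of raw importances.
#' @param categories Named character vector mapping predictors to
#'   categories; every predictor appearing in `importance` and in the map's
#'   domain is used, but an `importance` entry absent from the map is an
#'   error when it is expected to be grouped (`strict = TRUE`).
#' @param strict Error when a predictor in `importance` has no category?
#'   With `FALSE`, unmapped predictors are ignored (used for the climate
#'   sub-grouping, which maps only the climate variables).
#' @return Tibble with `category`, `importance` (summed raw) and `percent`.
#' @export
#' @examples
#' imp <- setNames(rep(1, 9), predictor_names())
#' group_importance(imp, predictor_categories())
group_importance <- function(importance, categories = predictor_categories(),
                             strict = TRUE) {
  if (is.null(names(importance))) abort("`importance` must be named.")
  unmapped <- setdiff(names(importance), names(categories))
  if (strict && length(unmapped)) {
    abort(paste0("Predictor(s) without a category: ",
                 paste(unmapped, collapse = ", ")))
  }
  keep <- intersect(names(importance), names(categories))
  vals <- pmax(importance[keep], 0)
  sums <- tapply(vals, categories[keep], sum)
  total <- sum(sums)
  pct <- if (total > 0) 100 * sums / total else {
    warn("Total importance is zero; percentages undefined.")
    rep(NA_real_, length(sums))
  }
  tibble(category = names(sums), importance = as.numeric(sums),
         percent = as.numeric(pct))
}

#' Fit a randomized tree ensemble and grouped importance report
#'
#' Fits a random-forest regression (bagged randomized trees, out-of-bag
#' error, permutation variable importance) on the cell-level response,
#' optionally after an automated predictor-subset search: `subset_runs`
#' random candidate subsets (uniform size) are each scored by the out-of-bag
#' R-squared of a small ensemble, and the best subset is refitted with the
#' full `n_trees`.  Predictors outside the selected subset receive zero
#' importance.  The forest fitting itself is delegated to
#' \pkg{ranger}; subset search, importance grouping and reporting are
#' performed here.
#'
#' @param data Data frame of grid cells.
#' @param response Response column (e.g. `"iv"`).
#' @param predictors Predictor columns; defaults to the standard nine.
#' @param n_trees Trees in the (final) ensemble, default 1000.
#' @param subset_runs Number of candidate-subset evaluations (0 disables the
#'   search and uses all predictors).
#' @param subset_trees Trees per candidate evaluation during the search.
#' @param mtry Predictors tried per split; default `ceiling(p / 3)`.
#' @param min_node Minimum node size, default 5.
#' @param seed Integer seed making the fit reproducible.
#' @return Object of class `zd_ensemble` with elements `r2` (out-of-bag
#'   R-squared), `importance` (named raw permutation importances over all
#'   predictors), `selected` (predictors in the fitted subset), `groups`
#'   (grouped percentage tibble for the category map and the climate
#'   sub-map), and the underlying \pkg{ranger} `model`.
#' @export
fit_ensemble <- function(data, response, predictors = NULL, n_trees = 1000,
                         subset_runs = 0, subset_trees = 100, mtry = NULL,
                         min_node = 5, seed = 1) {
  predictors <- predictors %||% intersect(predictor_names(), names(data))
  if (!length(predictors)) abort("No predictor columns found.")
  if (n_trees < 1) abort("`n_trees` must be at least 1.")
  X <- as.data.frame(data)[predictors]
  y <- as.data.frame(data)[[response]]
  if (anyNA(X) || anyNA(y)) abort("Missing values in model columns.")
  p <- length(predictors)
  if (!is.null(mtry) && mtry > p) {
    abort("`mtry` exceeds the number of predictors supplied.")
  }

  fit1 <- function(cols, ntree, sd) {
    m <- if (is.null(mtry)) max(1L, ceiling(length(cols) / 3)) else {
      min(mtry, length(cols))
    }
    ranger::ranger(
      x = X[cols], y = y, num.trees = ntree, mtry = m,
      min.node.size = min_node, importance = "permutation",
      seed = sd, num.threads = 1
    )
  }

  withr::with_seed(seed, {
    selected <- predictors
    if (subset_runs > 0) {
      best_r2 <- -Inf
      for (r in seq_len(subset_runs)) {
        size <- sample.int(p, 1)
        cand <- sort(sample.int(p, size))
        fit <- fit1(predictors[cand], subset_trees, sample.int(2^30, 1))
        r2 <- fit$r.squared
        if (r2 > best_r2) {
          best_r2 <- r2
          selected <- predictors[cand]
        }
      }
    }
    final <- fit1(selected, n_trees, sample.int(2^30, 1))
  })

  imp <- setNames(rep(0, p), predictors)
  imp[names(final$variable.importance)] <- final$variable.importance
  groups <- bind_rows(
    mutate(group_importance(imp, predictor_categories(), strict = FALSE),
           grouping = "category"),
    mutate(group_importance(imp, climate_categories(), strict = FALSE),
           grouping = "climate")
  ) |> relocate("grouping")

  structure(
    list(model = final, r2 = final$r.squared, importance = imp,
         selected = selected, groups = groups, response = response,
         predictors = predictors, n_trees = n_trees,
         subset_runs = subset_runs, seed = seed, n = length(y)),
    class = "zd_ensemble"
  )
}

#' @export
print.zd_ensemble <- function(x, ...) {
  cat(sprintf("<zd_ensemble> %d trees on %d cells, response '%s'\n",
              x$n_trees, x$n, x$response))
  cat(sprintf("  out-of-bag R-squared: %.3f; predictors used: %s\n",
              x$r2, paste(x$selected, collapse = ", ")))
  print(x$groups)
  invisible(x)
}

#' Tidy an ensemble into a per-predictor importance table
#'
#' @param x A `zd_ensemble`.
#' @param ... Unused.
#' @return Tibble with `predictor`, `importance` (raw permutation
#'   importance), `selected`.
#' @export
tidy.zd_ensemble <- function(x, ...) {
  tibble(predictor = names(x$importance),
         importance = as.numeric(x$importance),
         selected = names(x$importance) %in% x$selected)
}

#' One-row summary of an ensemble fit
#'
#' @param x A `zd_ensemble`.
#' @param ... Unused.
#' @return Tibble with `n`, `n_trees`, `r2` and `n_selected`.
#' @export
glance.zd_ensemble <- function(x, ...) {
  tibble(n = x$n, n_trees = x$n_trees, r2 = x$r2,
         n_selected = length(x$selected))
}

#' Does geographic position add anything beyond the environment?
#'
#' Compares the out-of-bag R-squared of an ensemble fitted on the
#' environmental predictors alone with one also given the cell coordinates.
#' A small difference means the macroscale spatial trend is already captured
#' by the environmental gradients (environmental distance dominates
#' geographic distance); a large one flags residual spatial structure.
#'
#' @param data Data frame of grid cells including the coordinate columns.
#' @param response Response column.
#' @param predictors Environmental predictor columns (default standard nine).
#' @param coords Coordinate column names, default `c("x", "y")`.
#' @param n_trees Trees per fit.
#' @param seed Integer seed shared by both fits.
#' @return Tibble with `r2_env`, `r2_env_coords`, `delta_r2`.
#' @export
spatial_trend_check <- function(data, response, predictors = NULL,
                                coords = c("x", "y"), n_trees = 500,
                                seed = 1) {
  predictors <- predictors %||% intersect(predictor_names(), names(data))
  miss <- setdiff(coords, names(data))
  if (length(miss)) {
    abort(paste0("Missing coordinate column(s): ",
                 paste(miss, collapse = ", ")))
  }
  base <- fit_ensemble(data, response, predictors, n_trees = n_trees,
                       seed = seed)
  with_xy <- fit_ensemble(data, response, c(predictors, coords),
                          n_trees = n_trees, seed = seed)
  tibble(r2_env = base$r2, r2_env_coords = with_xy$r2,
         delta_r2 = with_xy$r2 - base$r2)
}
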