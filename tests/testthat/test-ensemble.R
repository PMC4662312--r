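test_that("grouping arithmetic matches hand calculation", {
  imp <- setNames(rep(1, 9), predictor_names())
  g <- group_importance(imp, predictor_categories())
  expect_equal(g$percent[g$category == "climate"], 100 * 3 / 9)
  expect_equal(g$percent[g$category == "soil"], 100 * 4 / 9)
  expect_equal(g$percent[g$category == "topo"], 100 * 2 / 9)
  expect_equal(sum(g$percent), 100, tolerance = 1e-6)
  expect_true(all(g$percent >= 0))

  only_t <- setNames(c(0, 0, 1), c("gsai", "pmaysep", "tmaysep"))
  gc <- group_importance(only_t, climate_categories())
  expect_equal(gc$percent[gc$category == "gs_temperature"], 100)

  # negative raw importances are floored before grouping
  neg <- setNames(c(-2, 1, 1), c("gsai", "pmaysep", "tmaysep"))
  gn <- group_importance(neg, climate_categories())
  expect_equal(gn$percent[gn$category == "gs_moisture"], 50)
  expect_error(group_importance(c(zzz = 1), predictor_categories()),
               "without a category")
})

test_that("a single informative predictor takes all grouped importance", {
  set.seed(2)
  d <- tibble::tibble(gsai = runif(120, 0.5, 2))
  d$iv <- 20 * d$gsai + rnorm(120, sd = 0.5)
  ens <- fit_ensemble(d, "iv", "gsai", n_trees = 100, seed = 3)
  g <- dplyr::filter(ens$groups, grouping == "category")
  expect_equal(g$category, "climate")
  expect_equal(g$percent, 100)
  expect_gt(ens$r2, 0.8)
})

test_that("a pure-noise response has near-zero out-of-bag fit", {
  set.seed(4)
  land <- small_landscape(seed = 41)
  d <- land$coarse
  for (s in 1:10) {
    d$y <- rnorm(nrow(d))
    # irrelevant predictors can have all-negative permutation importance,
    # which makes the percentage grouping warn of a zero total
    ens <- suppressWarnings(
      fit_ensemble(d, "y", predictor_names(), n_trees = 150, seed = s))
    expect_lte(ens$r2, 0.05)
  }
})

test_that("grouped importance is invariant to predictor column order", {
  study <- default_study(seed = 42)
  fwd <- fit_ensemble(study$coarse, "iv", predictor_names(),
                      n_trees = 300, seed = 9)
  rev_fit <- fit_ensemble(study$coarse, "iv", rev(predictor_names()),
                          n_trees = 300, seed = 9)
  g1 <- dplyr::arrange(dplyr::filter(fwd$groups, grouping == "category"),
                       category)
  g2 <- dplyr::arrange(dplyr::filter(rev_fit$groups, grouping == "category"),
                       category)
  expect_equal(g1$percent, g2$percent, tolerance = 0.25)
  expect_equal(fwd$r2, rev_fit$r2, tolerance = 0.1)
})

test_that("subset search keeps informative predictors and reports zeros elsewhere", {
  set.seed(6)
  land <- small_landscape(seed = 43, nrow = 10, ncol = 8)
  d <- land$coarse
  d$y <- 2 * scale(d$gsai)[, 1] + rnorm(nrow(d), sd = 0.3)
  ens <- fit_ensemble(d, "y", predictor_names(), n_trees = 150,
                      subset_runs = 40, subset_trees = 50, seed = 7)
  expect_true("gsai" %in% ens$selected)
  unselected <- setdiff(predictor_names(), ens$selected)
  expect_true(all(ens$importance[unselected] == 0))
  expect_identical(
    fit_ensemble(d, "y", predictor_names(), n_trees = 150,
                 subset_runs = 40, subset_trees = 50, seed = 7)$importance,
    ens$importance)
  expect_error(fit_ensemble(d, "y", predictor_names(), mtry = 50), "mtry")
})

test_that("coordinates add nothing when the response is environmental", {
  study <- default_study(seed = 44, nrow = 12, ncol = 8)
  d <- study$coarse
  set.seed(8)
  d$resp <- 3 * scale(d$ph)[, 1] + 2 * scale(d$gsai)[, 1] +
    rnorm(nrow(d), sd = 0.5)
  deltas <- vapply(1:10, function(s) {
    spatial_trend_check(d, "resp", predictor_names(),
                        n_trees = 150, seed = s)$delta_r2
  }, 0)
  expect_true(all(abs(deltas) < 0.05))
})

test_that("coordinates matter when the response is a pure spatial ramp", {
  land <- small_landscape(seed = 45, nrow = 12, ncol = 8,
                          length_scale = 0.5)
  d <- land$coarse
  set.seed(9)
  d$resp <- 0.5 * d$y + rnorm(nrow(d), sd = 0.2)
  res <- spatial_trend_check(d, "resp", predictor_names(),
                             n_trees = 300, seed = 10)
  expect_gt(res$delta_r2, 0.3)
})

test_that("duplicating coordinates already in the model changes nothing", {
  study <- default_study(seed = 46)
  d <- study$coarse
  d$x2 <- d$x
  d$y2 <- d$y
  res <- spatial_trend_check(d, "iv",
                             c(predictor_names(), "x2", "y2"),
                             coords = c("x", "y"), n_trees = 300, seed = 11)
  expect_lt(abs(res$delta_r2), 0.05)
})
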