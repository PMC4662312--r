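test_that("importance value matches hand evaluations of the formula", {
  mono <- make_plot(rep("focal", 4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(compute_iv(mono, "focal"), 100)

  absent <- make_plot(c("a", "b"), c(0.2, 0.3))
  expect_equal(compute_iv(absent, "focal"), 0)

  # focal species holds 30% of basal area and 50% of stems -> 50*0.3 + 50*0.5
  mixed <- make_plot(c("focal", "other"), c(0.3, 0.7))
  expect_equal(compute_iv(mixed, "focal"), 40)
})

test_that("IV is undefined (not zero) for a treeless plot", {
  empty <- make_plot(character(), numeric())
  expect_warning(iv <- compute_iv(empty, "focal"), "undefined")
  expect_true(is.na(iv))
})

test_that("per-plot IVs sum to 100 over species and ignore area rescaling", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    plot <- make_plot(sample(letters[1:4], n, replace = TRUE),
                      runif(n, 0.01, 0.8),
                      sample(c("alive", "dead"), n, replace = TRUE))
    ivs <- vapply(unique(plot$species), function(s) compute_iv(plot, s), 0)
    expect_equal(sum(ivs), 100)
    scaled <- dplyr::mutate(plot, basal_area = basal_area * 7.3)
    for (s in unique(plot$species)) {
      expect_equal(compute_iv(scaled, s), compute_iv(plot, s))
    }
  }
})

test_that("dead trees can be excluded from IV via the documented switch", {
  plot <- make_plot(c("focal", "focal", "other"), c(0.2, 0.2, 0.6),
                    status = c("dead", "alive", "alive"))
  with_dead <- compute_iv(plot, "focal")
  live_only <- compute_iv(plot, "focal", include_dead = FALSE)
  expect_equal(with_dead, 50 * 0.4 + 50 * 2 / 3)
  expect_equal(live_only, 50 * 0.25 + 50 * 0.5)
})

test_that("percent mortality is the dead fraction of the species' trees", {
  plots <- make_plot(rep("focal", 10), rep(0.1, 10),
                     status = c(rep("dead", 2), rep("alive", 8)))
  expect_equal(compute_pm(plots, "focal"), 20)
  expect_equal(compute_pm(dplyr::mutate(plots, status = "alive"), "focal"), 0)
  expect_equal(compute_pm(dplyr::mutate(plots, status = "dead"), "focal"), 100)
  expect_warning(pm <- compute_pm(plots, "ghost"), "undefined")
  expect_true(is.na(pm))
})

test_that("seedling counting applies the printed size thresholds", {
  s <- make_seedlings(rep("focal", 3), diameter = c(0.5, 1.2, 0.5),
                      height = c(14, 20, 10))
  expect_equal(count_seedlings(s, "focal"), 1)
  expect_equal(count_seedlings(make_plot("a", 0.1), "focal"), 0)
  # boundary: diameter strictly < 1 inch, height >= 12 inches
  b <- make_seedlings(c("focal", "focal", "focal"),
                      diameter = c(0.999, 1.0, 0.5),
                      height = c(12.0, 14, 11.999))
  expect_equal(count_seedlings(b, "focal"), 1)
})

test_that("cell aggregation averages IV, pools mortality, sums seedlings", {
  land <- small_landscape(seed = 1, nrow = 2, ncol = 2, refinement = 1)
  p1 <- make_plot(c("focal", "other"), c(0.3, 0.7), plot_id = 1,
                  x = 0.3, y = 0.4)                      # IV 40
  p2 <- make_plot(c("other", "other"), c(0.5, 0.5), plot_id = 2,
                  x = 0.6, y = 0.6)                      # IV 0
  cells <- aggregate_to_grid(dplyr::bind_rows(p1, p2), land, "coarse")
  expect_equal(nrow(cells), 1)
  expect_equal(cells$iv, 20)
  expect_equal(cells$n_plots, 2)

  # pooled PM equals PM over the union of plots, not the mean of plot PMs
  q1 <- make_plot(rep("focal", 3), rep(0.1, 3),
                  status = c("dead", "dead", "dead"), plot_id = 3,
                  x = 1.3, y = 0.5)
  q2 <- make_plot(rep("focal", 9), rep(0.1, 9), plot_id = 4,
                  x = 1.6, y = 0.5)
  cells2 <- aggregate_to_grid(dplyr::bind_rows(q1, q2), land, "coarse")
  expect_equal(cells2$pm, 100 * 3 / 12)
  expect_equal(cells2$pm,
               compute_pm(dplyr::bind_rows(q1, q2), "focal"))
})

test_that("nonpresence cells are retained with IV 0, PM NA, SC 0", {
  land <- small_landscape(seed = 1, nrow = 2, ncol = 2, refinement = 1)
  p <- make_plot(c("a", "b"), c(0.2, 0.8), x = 0.5, y = 0.5)
  cells <- aggregate_to_grid(p, land, "coarse", species = "focal")
  expect_equal(cells$iv, 0)
  expect_true(is.na(cells$pm))
  expect_equal(cells$sc, 0)
  # only the one cell with a plot appears
  expect_equal(nrow(cells), 1)
})

test_that("plots outside the grid extent are an error", {
  land <- small_landscape(seed = 1, nrow = 2, ncol = 2, refinement = 1)
  p <- make_plot("focal", 0.3, x = 99, y = 0.5)
  expect_error(aggregate_to_grid(p, land, "coarse"), "outside")
})

test_that("one plot per cell reproduces the plot responses at cell level", {
  study <- default_study(seed = 6)
  land <- study$landscape
  scen <- demography_scenario(breakpoints = hemlock_bp(),
                              plots_per_cell = 0.3, seed = 9)
  plots <- generate_plots(land, scen)
  fine <- aggregate_to_grid(plots, land, "fine")
  single <- dplyr::filter(fine, n_plots == 1)
  expect_gt(nrow(single), 0)
  for (i in sample(seq_len(nrow(single)), min(5, nrow(single)))) {
    cell <- single[i, ]
    rec <- dplyr::filter(plots, ceiling(x) == cell$col,
                         ceiling(y) == cell$row)
    expect_equal(cell$iv, compute_iv(rec, "focal"))
    expect_equal(cell$sc, count_seedlings(rec, "focal"))
  }
})
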