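# Shared fixtures and independent oracles.

# build a plot-record tibble from terse per-tree vectors
make_plot <- function(species, basal_area, status = "alive",
                      overstory = TRUE, plot_id = 1L, x = 0.5, y = 0.5) {
  n <- length(species)
  tibble::tibble(
    plot_id = plot_id, x = x, y = y, record_type = "tree",
    species = species, basal_area = basal_area,
    status = rep_len(status, n), overstory = rep_len(overstory, n),
    diameter = NA_real_, height = NA_real_
  )
}

make_seedlings <- function(species, diameter, height, plot_id = 1L) {
  tibble::tibble(
    plot_id = plot_id, x = 0.5, y = 0.5, record_type = "seedling",
    species = species, basal_area = NA_real_, status = NA_character_,
    overstory = NA, diameter = diameter, height = height
  )
}

# independent exhaustive-enumeration split oracle: direct SSE arithmetic,
# no shared code with the tree fitter
brute_force_split <- function(X, Y, min_node = 1L) {
  Y <- as.matrix(Y)
  sse <- function(rows) {
    if (!length(rows)) return(0)
    sum(sweep(Y[rows, , drop = FALSE], 2,
              colMeans(Y[rows, , drop = FALSE]))^2)
  }
  eps <- 1e-9 * max(sse(seq_len(nrow(Y))), 1)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    ux <- sort(unique(X[, j]))
    if (length(ux) < 2) next
    thrs <- (ux[-1] + ux[-length(ux)]) / 2
    for (thr in thrs) {
      left <- which(X[, j] < thr)
      right <- which(X[, j] >= thr)
      if (length(left) < min_node || length(right) < min_node) next
      total <- sse(left) + sse(right)
      if (is.null(best) || total < best$sse - eps) {
        best <- list(var = j, threshold = thr, sse = total)
      }
    }
  }
  best
}

small_landscape <- function(seed = 11, nrow = 8, ncol = 6, refinement = 2,
                            ...) {
  generate_landscape(landscape_config(nrow = nrow, ncol = ncol,
                                      refinement = refinement, seed = seed,
                                      ...))
}

hemlock_bp <- function() species_breakpoints("eastern_hemlock")

# a small but fully populated synthetic study used by several files
default_study <- function(seed = 3, nrow = 10, ncol = 6) {
  land <- small_landscape(seed = seed, nrow = nrow, ncol = ncol)
  scen <- demography_scenario(breakpoints = hemlock_bp(), seed = seed + 1)
  plots <- generate_plots(land, scen)
  list(landscape = land, scenario = scen, plots = plots,
       coarse = aggregate_to_grid(plots, land, "coarse"),
       fine = aggregate_to_grid(plots, land, "fine"))
}
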