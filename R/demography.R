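tree_records <- function(records) {
  filter(records, .data$record_type == "tree")
}

#' Importance value of a species in a plot
#'
#' The importance value (IV) is a relativized abundance index: half the
#' species' share of the plot's total basal area plus half its share of the
#' plot's stems, overstory and understory trees summed,
#' \deqn{IV(x) = 50 \frac{BA(x)}{\sum BA} + 50 \frac{NS(x)}{\sum NS}.}
#' A monotypic plot scores 100; an absent species scores 0.  By default all
#' sampled trees count, dead ones included (abundance and mortality are
#' separate indices); set `include_dead = FALSE` to restrict to live trees.
#'
#' @param records Records of a single plot, in the layout produced by
#'   [generate_plots()]; only `record_type == "tree"` rows are used.
#' @param species Focal species id.
#' @param include_dead Count dead trees in the basal-area and stem shares?
#' @return IV in \[0, 100\], or `NA` with a warning when the plot has no tree
#'   records (IV is undefined, not zero).
#' @export
#' @examples
#' plot <- tibble::tibble(record_type = "tree",
#'                        species = c("a", "a", "b"),
#'                        basal_area = c(0.2, 0.1, 0.7),
#'                        status = "alive")
#' compute_iv(plot, "a")
compute_iv <- function(records, species, include_dead = TRUE) {
  trees <- tree_records(records)
  if (!include_dead) trees <- filter(trees, .data$status == "alive")
  if (nrow(trees) == 0) {
    warn("Plot has no tree records; IV is undefined.")
    return(NA_real_)
  }
  if (any(trees$basal_area <= 0, na.rm = TRUE) ||
      any(is.na(trees$basal_area))) {
    abort("Every tree record must have a positive basal area.")
  }
  focal <- trees$species == species
  50 * sum(trees$basal_area[focal]) / sum(trees$basal_area) +
    50 * sum(focal) / nrow(trees)
}

#' Percent mortality of a species
#'
#' Percentage of the species' sampled trees recorded dead, pooled over all
#' tree records in `records` (one plot or many).
#'
#' @inheritParams compute_iv
#' @return Percent in \[0, 100\], or `NA` with a warning when no tree of the
#'   species is present (mortality is undefined).
#' @export
compute_pm <- function(records, species) {
  trees <- filter(tree_records(records), .data$species == !!species)
  if (nrow(trees) == 0) {
    warn("No trees of the species; percent mortality is undefined.")
    return(NA_real_)
  }
  100 * sum(trees$status == "dead") / nrow(trees)
}

#' Seedling count of a species in a plot
#'
#' Counts regeneration-layer records passing the size filters: diameter
#' strictly less than 1 inch and height at least 12 inches.
#'
#' @inheritParams compute_iv
#' @return Non-negative integer (0 for a plot without seedling records).
#' @export
count_seedlings <- function(records, species) {
  s <- filter(records, .data$record_type == "seedling",
              .data$species == !!species,
              .data$diameter < 1, .data$height >= 12)
  nrow(s)
}

# per-plot response table used by aggregate_to_grid and tests
plot_responses <- function(records, species) {
  trees <- tree_records(records)
  per_tree <- trees |>
    group_by(.data$plot_id) |>
    summarise(
      x = .data$x[1], y = .data$y[1],
      n_trees = n(),
      ba_total = sum(.data$basal_area),
      ba_focal = sum(.data$basal_area[.data$species == !!species]),
      ns_focal = sum(.data$species == !!species),
      dead_focal = sum(.data$species == !!species & .data$status == "dead"),
      .groups = "drop"
    ) |>
    mutate(iv = 50 * .data$ba_focal / .data$ba_total +
             50 * .data$ns_focal / .data$n_trees)
  seeds <- records |>
    filter(.data$record_type == "seedling", .data$species == !!species,
           .data$diameter < 1, .data$height >= 12) |>
    count(.data$plot_id, name = "sc")
  per_tree |>
    left_join(seeds, by = "plot_id") |>
    mutate(sc = coalesce(.data$sc, 0L))
}

#' Aggregate plot responses and predictors to grid cells
#'
#' Computes per-plot IV, focal tree counts and seedling counts, assigns each
#' plot to a grid cell at the requested resolution, and summarises per cell:
#' IV as the unweighted mean of plot IVs, percent mortality pooled over all
#' the cell's focal trees, and seedling count summed.  Cells without plots
#' are excluded; cells whose plots lack the focal species are retained with
#' IV = 0, undefined (NA) mortality, and seedling count 0, so the grid covers
#' the species' full climatic space including nonpresence.
#'
#' @param records Plot records (layout of [generate_plots()]); plots with no
#'   tree records are dropped with a warning.
#' @param landscape A [generate_landscape()] result supplying the grids.
#' @param resolution `"coarse"` or `"fine"`.
#' @param species Focal species id.
#' @return Tibble of grid cells: `cell`, `row`, `col`, `x`, `y`, `n_plots`,
#'   `iv`, `pm`, `sc`, the nine predictors and `tmin`.
#' @export
aggregate_to_grid <- function(records, landscape,
                              resolution = c("coarse", "fine"),
                              species = "focal") {
  resolution <- match.arg(resolution)
  if (!inherits(landscape, "zd_landscape")) {
    abort("`landscape` must come from generate_landscape().")
  }
  grid <- landscape[[resolution]]
  cellsize <- if (resolution == "coarse") landscape$config$refinement else 1
  nr <- max(grid$row); nc <- max(grid$col)

  resp <- plot_responses(records, species)
  dropped <- setdiff(unique(records$plot_id), resp$plot_id)
  if (length(dropped)) {
    warn(sprintf("%d plot(s) without tree records dropped.", length(dropped)))
  }
  crow <- ceiling(resp$y / cellsize)
  ccol <- ceiling(resp$x / cellsize)
  if (any(crow < 1 | crow > nr | ccol < 1 | ccol > nc)) {
    abort("Plot coordinates fall outside the grid extent.")
  }
  resp$cell <- (ccol - 1L) * nr + crow

  cells <- resp |>
    group_by(.data$cell) |>
    summarise(
      n_plots = n(),
      iv = mean(.data$iv),
      pm = if (sum(.data$ns_focal) > 0) {
        100 * sum(.data$dead_focal) / sum(.data$ns_focal)
      } else NA_real_,
      sc = sum(.data$sc),
      .groups = "drop"
    )
  grid |>
    inner_join(cells, by = "cell") |>
    relocate("n_plots", "iv", "pm", "sc", .after = "y") |>
    arrange(.data$cell)
}
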