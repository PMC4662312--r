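#' Names of the standard environmental predictors
#'
#' The nine-predictor set used throughout the package: three growing-season
#' climate variables (`gsai`, aridity index, dimensionless; `tmaysep`,
#' May--September mean temperature, degrees C; `pmaysep`, May--September total
#' precipitation, mm), five edaphic variables (`ph`; `sieve10`, percent coarse
#' texture; `sieve200`, percent fine texture; `clay`, percent clay; `sprod`,
#' ordinal soil productivity 0--19) and one topographic variable (`elvmax`,
#' maximum elevation, m).
#'
#' @return Character vector of the nine predictor names.
#' @export
predictor_names <- function() {
  c("gsai", "tmaysep", "pmaysep", "ph", "sieve10", "sieve200", "clay",
    "sprod", "elvmax")
}

default_predictor_ranges <- function() {
  list(
    gsai     = c(0.5, 2),
    tmaysep  = c(12, 24),
    pmaysep  = c(300, 700),
    ph       = c(4, 8),
    sieve10  = c(0, 100),
    sieve200 = c(0, 100),
    clay     = c(0, 60),
    sprod    = c(0, 19),
    elvmax   = c(0, 1500)
  )
}

#' Configure a synthetic landscape
#'
#' Defines the geometry and statistical structure of a synthetic two-scale
#' landscape: a coarse grid of `nrow` x `ncol` cells, each subdivided into
#' `refinement` x `refinement` fine cells.  Predictor surfaces are smooth
#' (spatially autocorrelated) random fields rescaled to the configured value
#' ranges; the average annual extreme-minimum-temperature surface is a linear
#' gradient along one axis plus smooth noise, mimicking the latitudinal
#' hardiness-zone gradient.
#'
#' @param nrow,ncol Coarse grid extent (cells); each must be at least 2.
#' @param refinement Integer number of fine cells per coarse cell side
#'   (default 2); 1 makes the two resolutions identical.
#' @param length_scale Autocorrelation length scale in fine-cell units:
#'   either a single number for all predictors or a named vector/list by
#'   predictor.
#' @param ranges Named list of `c(lo, hi)` value ranges overriding the
#'   defaults; `sprod` is integer-valued in \[0, 19\], the texture and clay
#'   percentages lie in \[0, 100\], `ph` in \[3, 9\], `gsai` and `elvmax` are
#'   non-negative.
#' @param tmin_range `c(cold, warm)` degrees C of the extreme-minimum
#'   temperature gradient.
#' @param gradient_axis `"row"` (temperature increases with row index) or
#'   `"col"`.
#' @param tmin_noise_sd Standard deviation (degrees C) of the smooth noise
#'   added to the temperature gradient.
#' @param seed Integer random seed; the landscape is a deterministic function
#'   of the configuration.
#'
#' @return An object of class `zd_landscape_config`.
#' @export
#' @examples
#' cfg <- landscape_config(nrow = 6, ncol = 4, seed = 1)
#' land <- generate_landscape(cfg)
landscape_config <- function(nrow = 20, ncol = 10, refinement = 2,
                             length_scale = 3, ranges = NULL,
                             tmin_range = c(-35, -5),
                             gradient_axis = c("row", "col"),
                             tmin_noise_sd = 0.5, seed = 1) {
  gradient_axis <- match.arg(gradient_axis)
  if (refinement != as.integer(refinement) || refinement < 1) {
    abort("`refinement` must be a positive integer.")
  }
  if (nrow < 2 || ncol < 2) {
    abort("Landscape extent is degenerate: need at least 2 cells per side.")
  }
  rng <- default_predictor_ranges()
  if (!is.null(ranges)) {
    bad <- setdiff(names(ranges), names(rng))
    if (length(bad)) abort(paste0("Unknown predictor(s): ",
                                  paste(bad, collapse = ", ")))
    rng[names(ranges)] <- ranges
  }
  check_range <- function(name, lo_min, hi_max) {
    r <- rng[[name]]
    if (length(r) != 2 || r[1] > r[2]) abort(paste0("Bad range for ", name))
    if (r[1] < lo_min || r[2] > hi_max) {
      abort(sprintf("Range for %s must lie in [%g, %g].", name, lo_min, hi_max))
    }
  }
  check_range("sprod", 0, 19)
  for (p in c("sieve10", "sieve200", "clay")) check_range(p, 0, 100)
  check_range("ph", 3, 9)
  check_range("gsai", 0, Inf)
  check_range("elvmax", 0, Inf)

  ls <- length_scale
  if (length(ls) == 1 && is.null(names(ls))) {
    ls <- setNames(rep(as.numeric(ls), 9), predictor_names())
  } else {
    full <- setNames(rep(3, 9), predictor_names())
    full[names(ls)] <- unlist(ls)
    ls <- full
  }

  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         refinement = as.integer(refinement), length_scale = ls,
         ranges = rng, tmin_range = tmin_range,
         gradient_axis = gradient_axis, tmin_noise_sd = tmin_noise_sd,
         seed = as.integer(seed)),
    class = "zd_landscape_config"
  )
}

# 1-D convolution along rows with reflection padding
conv1d_reflect <- function(m, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  idx <- seq_len(n)
  for (j in seq_along(k)) {
    src <- idx + (j - half - 1L)
    src[src < 1L] <- 2L - src[src < 1L]
    src[src > n] <- 2L * n - src[src > n]
    src <- pmin(pmax(src, 1L), n)
    out <- out + k[j] * m[src, , drop = FALSE]
  }
  out
}

# smooth white noise with a separable Gaussian kernel and re-standardize
gaussian_field <- function(nr, nc, sigma) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (sigma > 0) {
    half <- max(1L, ceiling(3 * sigma))
    k <- dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    z <- conv1d_reflect(z, k)
    z <- t(conv1d_reflect(t(z), k))
  }
  (z - mean(z)) / sd(as.vector(z))
}

rescale_range <- function(z, range) {
  span <- diff(range(z))
  if (span == 0) return(matrix(mean(range), nrow(z), ncol(z)))
  range[1] + (z - min(z)) / span * diff(range)
}

#' Generate a synthetic two-scale landscape
#'
#' Simulates the nine predictor surfaces and the extreme-minimum-temperature
#' surface at fine resolution and aggregates them to the coarse grid, so the
#' coarse value of every variable equals the mean of its fine children by
#' construction (the nesting a coarse-to-fine rule-mapping analysis relies
#' on).  Fields are Gaussian-smoothed white noise rescaled to the configured
#' ranges; `sprod` is rounded to its ordinal levels at fine scale.
#'
#' @param config A [landscape_config()].
#'
#' @return An object of class `zd_landscape`: a list with
#'   \describe{
#'     \item{fine}{tibble of fine cells: `cell`, `row`, `col`, `x`, `y`
#'       (cell-centre coordinates in fine-cell units), `coarse_cell`, the nine
#'       predictors, and `tmin` (degrees C).}
#'     \item{coarse}{tibble of coarse cells: `cell`, `row`, `col`, `x`, `y`,
#'       `n_fine`, predictors and `tmin`, each the mean of the cell's fine
#'       children.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_landscape <- function(config) {
  if (!inherits(config, "zd_landscape_config")) {
    abort("`config` must come from landscape_config().")
  }
  ref <- config$refinement
  nrf <- config$nrow * ref
  ncf <- config$ncol * ref

  withr::with_seed(config$seed, {
    preds <- lapply(predictor_names(), function(p) {
      z <- gaussian_field(nrf, ncf, config$length_scale[[p]])
      v <- rescale_range(z, config$ranges[[p]])
      if (p == "sprod") v <- pmin(pmax(round(v), 0), 19)
      v
    })
    names(preds) <- predictor_names()

    frac <- if (config$gradient_axis == "row") {
      matrix((seq_len(nrf) - 0.5) / nrf, nrf, ncf)
    } else {
      matrix((seq_len(ncf) - 0.5) / ncf, nrf, ncf, byrow = TRUE)
    }
    tmin <- config$tmin_range[1] + diff(config$tmin_range) * frac
    if (config$tmin_noise_sd > 0) {
      tmin <- tmin + config$tmin_noise_sd * gaussian_field(nrf, ncf, 3)
    }
  })

  row <- rep(seq_len(nrf), times = ncf)
  col <- rep(seq_len(ncf), each = nrf)
  fine <- tibble(
    cell = (col - 1L) * nrf + row,
    row = row, col = col,
    x = col - 0.5, y = row - 0.5,
    coarse_row = ceiling(row / ref),
    coarse_col = ceiling(col / ref)
  )
  fine$coarse_cell <- (fine$coarse_col - 1L) * config$nrow + fine$coarse_row
  for (p in predictor_names()) fine[[p]] <- as.vector(preds[[p]])
  fine$tmin <- as.vector(tmin)

  coarse <- fine |>
    group_by(cell = .data$coarse_cell) |>
    summarise(
      row = .data$coarse_row[1], col = .data$coarse_col[1],
      n_fine = n(),
      across(all_of(c(predictor_names(), "tmin")), mean),
      .groups = "drop"
    ) |>
    mutate(x = (.data$col - 0.5) * ref, y = (.data$row - 0.5) * ref) |>
    relocate("x", "y", .after = "col") |>
    arrange(.data$cell)

  fine <- fine |> select(-"coarse_row", -"coarse_col") |>
    relocate("coarse_cell", .after = "y") |> arrange(.data$cell)

  structure(list(fine = fine, coarse = coarse, config = config),
            class = "zd_landscape")
}

#' @export
print.zd_landscape <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<zd_landscape> %d x %d coarse cells, refinement %d (%d fine cells)\n",
    cfg$nrow, cfg$ncol, cfg$refinement, nrow(x$fine)))
  cat(sprintf("  tmin %.1f to %.1f degC along %s axis; seed %d\n",
              cfg$tmin_range[1], cfg$tmin_range[2], cfg$gradient_axis,
              cfg$seed))
  invisible(x)
}

#' Write a grid variable as an ASCII raster
#'
#' Writes one variable of a landscape-style cell table in ESRI ASCII-grid
#' format: a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of values from the top row
#' down.  Cells absent from `cells` are written as nodata.
#'
#' @param cells Tibble with `row`, `col` and the variable column.
#' @param var Name of the column to rasterize.
#' @param path Output file path.
#' @param cellsize Cell size in fine-cell units (use the landscape refinement
#'   factor for coarse grids).
#' @param nodata Nodata sentinel written for missing cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(cells, var, path, cellsize = 1, nodata = -9999) {
  nr <- max(cells$row)
  nc <- max(cells$col)
  m <- matrix(NA_real_, nr, nc)
  m[cbind(cells$row, cells$col)] <- cells[[var]]
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc), sprintf("nrows %d", nr),
    "xllcorner 0", "yllcorner 0",
    sprintf("cellsize %g", cellsize), sprintf("NODATA_value %g", nodata)
  ), con)
  # ASCII grids list rows north-to-south; our row 1 is the grid origin
  for (r in rev(seq_len(nr))) {
    writeLines(paste(format(m[r, ], trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ASCII raster into a cell table
#'
#' Inverse of [write_ascii_grid()]: returns a tibble with `row`, `col`, `x`,
#' `y` and a `value` column; nodata cells are dropped.
#'
#' @param path File written by [write_ascii_grid()] (or any ESRI ASCII grid).
#' @return A tibble of cells.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                   tolower(vapply(kv, `[`, "", 1)))
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # back to row 1 = origin
  m[m == vals[["nodata_value"]]] <- NA_real_
  cs <- vals[["cellsize"]]
  out <- tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    value = as.vector(m)
  ) |>
    mutate(x = (.data$col - 0.5) * cs, y = (.data$row - 0.5) * cs) |>
    filter(!is.na(.data$value))
  out
}
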