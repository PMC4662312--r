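#' Default plant-hardiness-zone temperature breakpoints
#'
#' Boundaries of the 19 hardiness zones spanning average annual
#' extreme-minimum temperatures from -42.8 to 10 degrees C (equal steps of
#' about 2.78 degrees C).  The table is a plain numeric vector of length 20
#' so users can substitute the published product's exact boundaries.
#'
#' @return Numeric vector of 20 increasing zone boundaries (degrees C).
#' @export
phz_breakpoints <- function() {
  seq(-42.8, 10, length.out = 20L)
}

#' Classify temperatures into plant hardiness zones
#'
#' Assigns each average annual extreme-minimum temperature to one of the 19
#' hardiness zones.  Zone intervals are lower-closed, upper-open;
#' temperatures below the coldest boundary clamp to zone 1 and at or above
#' the warmest to zone 19.
#'
#' @param temp Numeric vector of temperatures (degrees C); must be finite.
#' @param breakpoints Increasing vector of zone boundaries, one more entry
#'   than there are zones (default [phz_breakpoints()]).
#' @return Integer vector of zone indices in `1:(length(breakpoints) - 1)`.
#' @export
#' @examples
#' classify_phz(c(-42.8, -30, 10))
classify_phz <- function(temp, breakpoints = phz_breakpoints()) {
  if (any(!is.finite(temp))) abort("`temp` contains non-finite values.")
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    abort("`breakpoints` must be strictly increasing.")
  }
  findInterval(temp, breakpoints, all.inside = TRUE)
}

#' Species cold/core/warm zone breakpoints
#'
#' Extreme-minimum-temperature intervals delimiting the cold-adapted leading
#' region (CLR), middle core region (MCR), and warm-adapted trailing region
#' (WTR) of a species' range.  Ships with entries for eastern hemlock, sweet
#' birch, tulip poplar and chestnut oak; any CSV with the same columns can be
#' supplied instead.  Intervals are lower-closed, upper-open; sweet birch has
#' a gap between its CLR and MCR intervals, and temperatures falling in a gap
#' are treated as outside the analysed range.
#'
#' @param species Optional species name(s) to filter to.
#' @param file Optional path to a CSV with columns `species`, `clr_lo`,
#'   `clr_hi`, `mcr_lo`, `mcr_hi`, `wtr_lo`, `wtr_hi` (degrees C).
#' @return A tibble, one row per species.
#' @export
#' @examples
#' species_breakpoints("eastern_hemlock")
species_breakpoints <- function(species = NULL, file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "species_zone_breakpoints.csv",
                        package = "zonedemog", mustWork = TRUE)
  }
  bp <- as_tibble(read.csv(file, stringsAsFactors = FALSE))
  validate_breakpoints(bp)
  if (!is.null(species)) {
    missing <- setdiff(species, bp$species)
    if (length(missing)) {
      abort(paste0("No breakpoints for species: ",
                   paste(missing, collapse = ", ")))
    }
    bp <- bp[match(species, bp$species), ]
  }
  bp
}

validate_breakpoints <- function(bp) {
  need <- c("species", "clr_lo", "clr_hi", "mcr_lo", "mcr_hi",
            "wtr_lo", "wtr_hi")
  miss <- setdiff(need, names(bp))
  if (length(miss)) {
    abort(paste0("Breakpoint table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  ok <- with(bp, clr_lo < clr_hi & clr_hi <= mcr_lo & mcr_lo < mcr_hi &
               mcr_hi <= wtr_lo & wtr_lo < wtr_hi)
  if (any(!ok)) {
    abort(paste0("Non-increasing zone intervals for: ",
                 paste(bp$species[!ok], collapse = ", ")))
  }
  invisible(bp)
}

zone_levels <- function() c("CLR", "MCR", "WTR", "outside")

#' Assign temperatures to a species' climatic zones
#'
#' Labels each temperature CLR, MCR or WTR according to the species'
#' breakpoints, or `"outside"` when it falls beyond the species' climatic
#' range.  Intervals are lower-closed, upper-open, so a temperature exactly
#' on a shared boundary belongs to the warmer zone.  Temperatures falling in
#' a configured gap between zones (as printed for sweet birch) are labelled
#' `"outside"` with a warning.
#'
#' @param temp Numeric vector of extreme-minimum temperatures (degrees C).
#' @param breakpoints A single-species row from [species_breakpoints()].
#' @return Factor with levels `CLR`, `MCR`, `WTR`, `outside`.
#' @export
#' @examples
#' bp <- species_breakpoints("eastern_hemlock")
#' assign_species_zone(c(-30, -22, -15), bp)
assign_species_zone <- function(temp, breakpoints) {
  validate_breakpoints(breakpoints)
  if (nrow(breakpoints) != 1) {
    abort("`breakpoints` must be a single-species row.")
  }
  bp <- breakpoints
  zone <- rep("outside", length(temp))
  zone[temp >= bp$clr_lo & temp < bp$clr_hi] <- "CLR"
  zone[temp >= bp$mcr_lo & temp < bp$mcr_hi] <- "MCR"
  zone[temp >= bp$wtr_lo & temp < bp$wtr_hi] <- "WTR"
  if (bp$clr_hi < bp$mcr_lo) {
    in_gap <- temp >= bp$clr_hi & temp < bp$mcr_lo
    if (any(in_gap, na.rm = TRUE)) {
      warn(sprintf(
        "%d temperature(s) fall in the configured gap (%g to %g degC) between CLR and MCR for %s; labelled 'outside'.",
        sum(in_gap, na.rm = TRUE), bp$clr_hi, bp$mcr_lo, bp$species))
    }
  }
  zone[is.na(temp)] <- NA
  factor(zone, levels = zone_levels())
}

#' Split grid cells into the species' climatic zones
#'
#' Partitions cells carrying an extreme-minimum temperature (`tmin` column)
#' into CLR/MCR/WTR subsets; cells outside the species' climatic range are
#' dropped.  Nonpresence cells (species absent, IV = 0) are retained within
#' their zone, delimiting the full climatic space.
#'
#' @param cells Tibble of grid cells with a `tmin` column.
#' @param breakpoints A single-species row from [species_breakpoints()].
#' @return Named list of tibbles `CLR`, `MCR`, `WTR` (each possibly empty,
#'   each with a `zone` column); attribute `counts` holds the per-zone and
#'   outside cell counts.
#' @export
split_cells_by_zone <- function(cells, breakpoints) {
  if (!"tmin" %in% names(cells)) abort("`cells` must have a `tmin` column.")
  zone <- assign_species_zone(cells$tmin, breakpoints)
  cells$zone <- zone
  counts <- table(zone)
  out <- lapply(c("CLR", "MCR", "WTR"), function(z) {
    filter(cells, .data$zone == z)
  })
  names(out) <- c("CLR", "MCR", "WTR")
  attr(out, "counts") <- counts
  inform(sprintf("Zone cell counts: CLR %d, MCR %d, WTR %d (outside %d)",
                 counts[["CLR"]], counts[["MCR"]], counts[["WTR"]],
                 counts[["outside"]]))
  out
}
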