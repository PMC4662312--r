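default_abundance_effects <- function() {
  # cold-zone abundance driven by soil, warm-zone by growing-season moisture;
  # the core zone mixes both.  Coefficients act on z-scored predictors.
  list(
    CLR = c(intercept = -1.0, ph = 0.9, sieve10 = 0.8, sprod = 0.7),
    MCR = c(intercept = -0.6, ph = 0.4, gsai = 0.4, pmaysep = 0.3),
    WTR = c(intercept = -1.0, gsai = 1.0, pmaysep = 0.9)
  )
}

default_mortality_effects <- function() {
  list(CLR = c(baseline = 0.08), MCR = c(baseline = 0.10),
       WTR = c(baseline = 0.18))
}

default_seedling_effects <- function() {
  list(CLR = c(intercept = 3), MCR = c(intercept = 2),
       WTR = c(intercept = 1))
}

#' Configure a demographic scenario for a focal species
#'
#' Defines how a focal species' abundance, per-tree mortality and seedling
#' production respond to the environment in each climatic zone of a synthetic
#' landscape.  Effects are linear combinations of z-scored predictors:
#' abundance on the logit scale of the species' within-plot share, mortality
#' as a per-tree death probability (`baseline` plus effects, clamped to
#' \[0, 1\]), and seedling production as a Poisson intensity (`intercept`
#' plus effects, floored at 0).  The default scenario encodes soil-driven
#' abundance in the cold zone, moisture-driven abundance in the warm zone,
#' higher mortality and lower regeneration toward the warm trailing edge.
#'
#' @param breakpoints Single-species row from [species_breakpoints()] that
#'   maps cell temperatures to zones.
#' @param species Focal species id used in the generated records.
#' @param abundance,mortality,seedlings Named lists with one numeric vector
#'   per zone (`CLR`, `MCR`, `WTR`).  Vector names are `intercept`
#'   (`baseline` for mortality) plus predictor names; unnamed zones fall back
#'   to defaults, and every zone must be covered.
#' @param abundance_noise_sd Plot-level noise SD on the abundance logit.
#' @param plots_per_cell Mean of the Poisson number of inventory plots per
#'   fine cell.
#' @param trees_per_plot Mean number of tree records per plot (at least 2
#'   trees are always generated).
#' @param n_background Number of non-focal background species.
#' @param background_mortality Death probability for background-species trees.
#' @param seed Integer seed; plot generation is deterministic given the
#'   landscape and scenario.
#' @return Object of class `zd_scenario`.
#' @export
demography_scenario <- function(breakpoints = species_breakpoints("eastern_hemlock"),
                                species = "focal",
                                abundance = default_abundance_effects(),
                                mortality = default_mortality_effects(),
                                seedlings = default_seedling_effects(),
                                abundance_noise_sd = 0.4,
                                plots_per_cell = 1.5,
                                trees_per_plot = 8,
                                n_background = 2,
                                background_mortality = 0.08,
                                seed = 1) {
  validate_breakpoints(breakpoints)
  zones <- c("CLR", "MCR", "WTR")
  for (nm in c("abundance", "mortality", "seedlings")) {
    eff <- get(nm)
    missing <- setdiff(zones, names(eff))
    if (length(missing)) {
      abort(sprintf("`%s` must define all zones; missing: %s", nm,
                    paste(missing, collapse = ", ")))
    }
    extra <- setdiff(names(eff), zones)
    if (length(extra)) {
      abort(sprintf("`%s` references undefined zone(s): %s", nm,
                    paste(extra, collapse = ", ")))
    }
  }
  for (z in zones) {
    b <- mortality[[z]][["baseline"]]
    if (is.na(b) || b < 0 || b > 1) {
      abort("Mortality `baseline` must lie in [0, 1] for every zone.")
    }
  }
  if (plots_per_cell < 0) abort("`plots_per_cell` must be non-negative.")
  structure(
    list(breakpoints = breakpoints, species = species,
         abundance = abundance, mortality = mortality,
         seedlings = seedlings, abundance_noise_sd = abundance_noise_sd,
         plots_per_cell = plots_per_cell, trees_per_plot = trees_per_plot,
         n_background = as.integer(n_background),
         background_mortality = background_mortality,
         seed = as.integer(seed)),
    class = "zd_scenario"
  )
}

# linear predictor intercept + Z %*% beta for a zone's effect vector
zone_linear <- function(Z, effects, intercept_name = "intercept") {
  eta <- rep(0, nrow(Z))
  for (nm in names(effects)) {
    if (nm %in% c(intercept_name)) {
      eta <- eta + effects[[nm]]
    } else if (nm %in% colnames(Z)) {
      eta <- eta + effects[[nm]] * Z[, nm]
    } else {
      abort(paste0("Effect references unknown predictor: ", nm))
    }
  }
  eta
}

#' Generate synthetic inventory plot records
#'
#' Places inventory plots in the fine cells of a synthetic landscape
#' (Poisson number per cell) and draws tree and seedling records under the
#' scenario's zone-specific demographic models.  Within the species' climatic
#' range the focal species' share of a plot follows the zone's abundance
#' model; outside it the focal species is absent.  Every plot contains at
#' least one non-focal tree so relativized abundance is informative, and at
#' least two trees in total.  Seedling records carry a diameter and height so
#' that the regeneration size filters are exercised.
#'
#' @param landscape A [generate_landscape()] result.
#' @param scenario A [demography_scenario()].
#' @return A tibble of records, one row per tree or seedling:
#'   `plot_id`, `x`, `y` (fine-cell units), `record_type`
#'   (`"tree"`/`"seedling"`), `species`, `basal_area` (m^2, trees only),
#'   `status` (`"alive"`/`"dead"`, trees only), `overstory` (logical, trees
#'   only), `diameter` and `height` (inches, seedlings only).
#' @export
generate_plots <- function(landscape, scenario) {
  if (!inherits(landscape, "zd_landscape")) {
    abort("`landscape` must come from generate_landscape().")
  }
  if (!inherits(scenario, "zd_scenario")) {
    abort("`scenario` must come from demography_scenario().")
  }
  fine <- landscape$fine
  Z <- scale(as.matrix(fine[predictor_names()]))
  Z[is.nan(Z)] <- 0  # constant predictor surface
  zone <- as.character(suppressWarnings(
    assign_species_zone(fine$tmin, scenario$breakpoints)))

  withr::with_seed(scenario$seed, {
    n_plots <- rpois(nrow(fine), scenario$plots_per_cell)
    cell_of <- rep(seq_len(nrow(fine)), n_plots)
    np <- length(cell_of)
    if (np == 0) {
      return(tibble(plot_id = integer(), x = double(), y = double(),
                    record_type = character(), species = character(),
                    basal_area = double(), status = character(),
                    overstory = logical(), diameter = double(),
                    height = double()))
    }
    plot_x <- fine$col[cell_of] - runif(np)
    plot_y <- fine$row[cell_of] - runif(np)
    pzone <- zone[cell_of]

    eta <- rep(-Inf, np)      # focal absent outside the climatic range
    pmort <- rep(scenario$background_mortality, np)
    lambda <- rep(0, np)
    for (z in c("CLR", "MCR", "WTR")) {
      in_z <- pzone == z
      if (!any(in_z)) next
      Zi <- Z[cell_of[in_z], , drop = FALSE]
      eta[in_z] <- zone_linear(Zi, scenario$abundance[[z]])
      pmort[in_z] <- pmin(pmax(
        zone_linear(Zi, scenario$mortality[[z]], "baseline"), 0), 1)
      lambda[in_z] <- pmax(zone_linear(Zi, scenario$seedlings[[z]]), 0)
    }
    p_focal <- plogis(eta + rnorm(np, sd = scenario$abundance_noise_sd))
    p_focal[pzone == "outside"] <- 0

    n_tot <- 2L + rpois(np, max(scenario$trees_per_plot - 2, 0))
    n_focal <- rbinom(np, n_tot, p_focal)
    n_focal <- pmin(n_focal, n_tot - 1L)  # keep >= 1 non-focal tree

    plot_of_tree <- rep(seq_len(np), n_tot)
    is_focal <- sequence(n_tot) <= n_focal[plot_of_tree]
    nt <- length(plot_of_tree)
    sp <- character(nt)
    sp[is_focal] <- scenario$species
    sp[!is_focal] <- paste0("bg", sample.int(scenario$n_background,
                                             sum(!is_focal), replace = TRUE))
    death_p <- ifelse(is_focal, pmort[plot_of_tree],
                      scenario$background_mortality)
    trees <- tibble(
      plot_id = plot_of_tree,
      x = plot_x[plot_of_tree], y = plot_y[plot_of_tree],
      record_type = "tree",
      species = sp,
      basal_area = rlnorm(nt, meanlog = log(0.05), sdlog = 0.6),
      status = ifelse(runif(nt) < death_p, "dead", "alive"),
      overstory = runif(nt) < 0.7,
      diameter = NA_real_, height = NA_real_
    )

    n_seed <- rpois(np, lambda)
    plot_of_seed <- rep(seq_len(np), n_seed)
    ns <- length(plot_of_seed)
    seedlings <- tibble(
      plot_id = plot_of_seed,
      x = plot_x[plot_of_seed], y = plot_y[plot_of_seed],
      record_type = "seedling",
      species = scenario$species,
      basal_area = NA_real_, status = NA_character_, overstory = NA,
      diameter = runif(ns, 0.2, 1.4),
      height = runif(ns, 6, 40)
    )
  })

  bind_rows(trees, seedlings) |> arrange(.data$plot_id, .data$record_type)
}
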