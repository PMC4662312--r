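#' Build a pipeline configuration
#'
#' Collects every stage's parameters with the standard defaults: an 8-leaf
#' display tree, a 1000-tree ensemble with 750 predictor-subset evaluations,
#' and 100-cell subsamples in the zone comparison.  Any component can be
#' overridden; a YAML file with the same nested structure can be passed to
#' [run_pipeline()] directly.
#'
#' @param species Character vector of focal species; each must have a row in
#'   the breakpoint table.
#' @param breakpoint_file Optional CSV overriding the shipped zone
#'   breakpoints (see [species_breakpoints()]).
#' @param landscape Named list of [landscape_config()] arguments.
#' @param scenario Named list of [demography_scenario()] arguments
#'   (breakpoints and seed are filled in per species).
#' @param tree Named list: `k_leaves` (default 8), `min_node` (default 5).
#' @param ensemble Named list: `n_trees` (1000), `subset_runs` (750),
#'   `subset_trees` (100), `min_node` (5).
#' @param compare Named list: `n_sample` (100).
#' @param min_zone_cells Minimum cells a zone needs before its models are
#'   fitted; smaller zones are flagged `insufficient data` and skipped.
#' @param seed Master integer seed for the run.
#' @return Object of class `zd_config` (a nested list).
#' @export
pipeline_config <- function(species = "eastern_hemlock",
                            breakpoint_file = NULL,
                            landscape = list(), scenario = list(),
                            tree = list(), ensemble = list(),
                            compare = list(), min_zone_cells = 30,
                            seed = 1) {
  cfg <- list(
    species = species,
    breakpoint_file = breakpoint_file,
    landscape = utils::modifyList(list(nrow = 20, ncol = 10, refinement = 2),
                                  landscape),
    scenario = scenario,
    tree = utils::modifyList(list(k_leaves = 8, min_node = 5), tree),
    ensemble = utils::modifyList(
      list(n_trees = 1000, subset_runs = 750, subset_trees = 100,
           min_node = 5), ensemble),
    compare = utils::modifyList(list(n_sample = 100), compare),
    min_zone_cells = min_zone_cells,
    seed = as.integer(seed)
  )
  structure(cfg, class = "zd_config")
}

read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage_error <- function(stage, parent) {
  abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                conditionMessage(parent)))
}

#' Run the full zonal demographic pipeline
#'
#' Orchestrates every stage on a synthetic landscape: landscape and plot
#' generation, demographic aggregation at coarse and fine resolution,
#' climatic-zone splitting, per-zone ensemble importance, pruned display
#' tree with rule extraction and fine-resolution class mapping, multivariate
#' tree over (IV, PM, SC), and the cold-versus-warm comparison.  All outputs
#' are written to `outdir` as CSV / ASCII-grid / JSON, with a manifest
#' recording the seeds, configuration hash and package versions, so any
#' stage can be re-loaded and re-run standalone.  Zones with too few cells
#' are flagged in the manifest rather than fitted.
#'
#' @param config A [pipeline_config()] or path to an equivalent YAML file.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the landscape, per-species results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("zd_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "zd_config")) {
    abort("`config` must come from pipeline_config() or a YAML path.")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  bp_all <- species_breakpoints(file = config$breakpoint_file)
  missing <- setdiff(config$species, bp_all$species)
  if (length(missing)) {
    abort(paste0("No breakpoints for species: ",
                 paste(missing, collapse = ", ")))
  }

  inform("Stage: landscape generation")
  land <- tryCatch(
    generate_landscape(do.call(landscape_config,
                               c(config$landscape, list(seed = config$seed)))),
    error = function(e) stage_error("landscape", e))

  flags <- list()
  results <- list()
  for (sp in config$species) {
    inform(sprintf("Species: %s", sp))
    bp <- bp_all[bp_all$species == sp, ]
    sp_dir <- file.path(outdir, sp)
    dir.create(sp_dir, showWarnings = FALSE)

    scen_args <- utils::modifyList(
      list(breakpoints = bp, species = sp, seed = config$seed + 1L),
      config$scenario)
    scen <- do.call(demography_scenario, scen_args)

    inform("Stage: plot generation")
    plots <- tryCatch(generate_plots(land, scen),
                      error = function(e) stage_error("plots", e))
    write.csv(plots, file.path(sp_dir, "plots.csv"), row.names = FALSE)

    inform("Stage: demographic aggregation")
    coarse <- tryCatch(
      aggregate_to_grid(plots, land, "coarse", species = sp),
      error = function(e) stage_error("demography", e))
    fine <- aggregate_to_grid(plots, land, "fine", species = sp)
    write.csv(coarse, file.path(sp_dir, "cells_coarse.csv"),
              row.names = FALSE)
    write.csv(fine, file.path(sp_dir, "cells_fine.csv"), row.names = FALSE)
    for (v in c("iv", "pm", "sc")) {
      write_ascii_grid(coarse, v, file.path(sp_dir, paste0(v, "_coarse.asc")),
                       cellsize = land$config$refinement)
    }

    inform("Stage: zone splitting")
    zones_coarse <- split_cells_by_zone(coarse, bp)
    zones_fine <- split_cells_by_zone(fine, bp)

    sp_res <- list(scenario = scen, coarse = coarse, fine = fine,
                   zones = zones_coarse)
    for (zone in c("CLR", "MCR", "WTR")) {
      zc <- zones_coarse[[zone]]
      zf <- zones_fine[[zone]]
      if (nrow(zc) < config$min_zone_cells) {
        flags[[paste(sp, zone, sep = "/")]] <- "insufficient data"
        inform(sprintf("Zone %s: %d cells < %d; flagged insufficient.",
                       zone, nrow(zc), config$min_zone_cells))
        next
      }
      inform(sprintf("Stage: models for zone %s (%d cells)", zone, nrow(zc)))
      ens <- tryCatch(
        fit_ensemble(zc, "iv",
                     n_trees = config$ensemble$n_trees,
                     subset_runs = config$ensemble$subset_runs,
                     subset_trees = config$ensemble$subset_trees,
                     min_node = config$ensemble$min_node,
                     seed = config$seed + 2L),
        error = function(e) stage_error("ensemble", e))
      jsonlite::write_json(
        list(zone = zone, r2 = ens$r2,
             importance = as.list(ens$importance),
             selected = as.list(ens$selected),
             groups = ens$groups),
        file.path(sp_dir, sprintf("importance_%s.json", zone)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)

      tree <- tryCatch({
        full <- fit_tree(zc, "iv", min_node = config$tree$min_node)
        prune_to_leaves(full, config$tree$k_leaves)
      }, error = function(e) stage_error("tree", e))
      write_tree_json(tree, file.path(sp_dir, sprintf("tree_%s.json", zone)))

      rules <- extract_rules(tree)
      write.csv(select(rules, -"predicates"),
                file.path(sp_dir, sprintf("rules_%s.csv", zone)),
                row.names = FALSE)
      classified <- apply_rules(rules, zf)
      write_ascii_grid(classified, "class",
                       file.path(sp_dir, sprintf("classmap_%s.asc", zone)))
      write.csv(rule_class_stats(classified, "iv"),
                file.path(sp_dir, sprintf("class_stats_%s.csv", zone)),
                row.names = FALSE)

      mv_cells <- filter(zc, !is.na(.data$pm))
      mv <- NULL
      if (nrow(mv_cells) >= 2 * config$tree$min_node &&
          nrow(mv_cells) >= config$min_zone_cells) {
        mv <- tryCatch(
          fit_mvtree(mv_cells, min_node = config$tree$min_node,
                     max_leaves = config$tree$k_leaves),
          error = function(e) stage_error("mvtree", e))
        write_tree_json(mv, file.path(sp_dir,
                                      sprintf("mvtree_%s.json", zone)))
        write.csv(mvtree_report(mv),
                  file.path(sp_dir, sprintf("mvtree_leaves_%s.csv", zone)),
                  row.names = FALSE)
      } else {
        flags[[paste(sp, zone, "mvtree", sep = "/")]] <- "insufficient data"
      }
      sp_res[[zone]] <- list(ensemble = ens, tree = tree, rules = rules,
                             classified = classified, mvtree = mv)
    }

    inform("Stage: cold-versus-warm comparison")
    cmp <- NULL
    if (nrow(zones_coarse$CLR) > 0 && nrow(zones_coarse$WTR) > 0) {
      cmp <- purrr::list_rbind(purrr::map(c("iv", "pm", "sc"), function(v) {
        tryCatch(
          zone_compare(zones_coarse$CLR[[v]], zones_coarse$WTR[[v]],
                       n_sample = config$compare$n_sample,
                       seed = config$seed + 3L, response = v),
          error = function(e) {
            flags[[paste(sp, "compare", v, sep = "/")]] <<- conditionMessage(e)
            NULL
          })
      }))
      if (!is.null(cmp) && nrow(cmp)) {
        write.csv(cmp, file.path(sp_dir, "comparison.csv"),
                  row.names = FALSE)
      }
    } else {
      flags[[paste(sp, "compare", sep = "/")]] <- "insufficient data"
    }
    sp_res$comparison <- cmp
    results[[sp]] <- sp_res
  }

  cfg_path <- file.path(outdir, "config.json")
  cfg_plain <- rapply(unclass(config), function(x) x, how = "replace")
  cfg_plain$scenario <- NULL  # may hold non-scalar defaults; re-derived
  jsonlite::write_json(cfg_plain, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  manifest <- list(
    seed = config$seed,
    species = config$species,
    config_hash = unname(tools::md5sum(cfg_path)),
    flags = flags,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("zonedemog")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  invisible(list(landscape = land, results = results, manifest = manifest,
                 outdir = outdir))
}
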