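#' Plot grouped importance percentages of an ensemble
#'
#' Bar chart of the category-grouped permutation-importance percentages,
#' one panel for the climate/soil/topographic grouping and one for the
#' growing-season moisture/temperature sub-grouping.
#'
#' @param object A `zd_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zd_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~grouping, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "percent importance weight",
                  title = sprintf("Grouped predictor importance (R² = %.2f)",
                                  object$r2)) +
    ggplot2::theme_minimal()
}

#' Compare grouped importances across zones
#'
#' Side-by-side bars of grouped importance percentages for several zone
#' fits, the visual used to contrast the cold-leading and warm-trailing
#' regions.
#'
#' @param ensembles Named list of `zd_ensemble` objects (names are zone
#'   labels, e.g. `list(CLR = ..., WTR = ...)`).
#' @param grouping `"category"` or `"climate"`.
#' @return A ggplot object.
#' @export
plot_importance_comparison <- function(ensembles, grouping = "category") {
  df <- purrr::list_rbind(purrr::imap(ensembles, function(e, z) {
    mutate(filter(e$groups, .data$grouping == !!grouping), zone = z)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$percent,
                                   fill = .data$zone)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(CLR = "#3366cc", MCR = "grey60",
                                          WTR = "#cc3333")) +
    ggplot2::labs(x = NULL, y = "percent importance weight") +
    ggplot2::theme_minimal()
}

#' Plot a cold-versus-warm comparison table
#'
#' Paired bars of the zone population means for each compared response, with
#' an asterisk over responses whose t-test is significant at the 95% level.
#'
#' @param object One or more stacked [zone_compare()] rows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zd_zone_comparison <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(response = coalesce(.data$response,
                               paste0("response", seq_len(n())))) |>
    tidyr::pivot_longer(c("mean_cold", "mean_warm"), names_to = "zone",
                        values_to = "mean") |>
    mutate(zone = ifelse(.data$zone == "mean_cold", "cold", "warm"))
  labdf <- as_tibble(object) |>
    mutate(response = coalesce(.data$response,
                               paste0("response", seq_len(n()))),
           label = ifelse(.data$significant, "(*)", ""),
           y = pmax(.data$mean_cold, .data$mean_warm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$response, y = .data$mean,
                                   fill = .data$zone)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(data = labdf,
                       ggplot2::aes(x = .data$response, y = .data$y,
                                    label = .data$label),
                       inherit.aes = FALSE, vjust = -0.4) +
    ggplot2::scale_fill_manual(values = c(cold = "#3366cc",
                                          warm = "#cc3333")) +
    ggplot2::labs(x = NULL, y = "population mean (raw scale)") +
    ggplot2::theme_minimal()
}

#' Map the classes produced by a rule set
#'
#' Raster map of the per-cell class assignment from [apply_rules()], the
#' regional-species-group map at fine resolution.
#'
#' @param classified Output of [apply_rules()] (needs `x`, `y`, `class`).
#' @return A ggplot object.
#' @export
plot_class_map <- function(classified) {
  ggplot2::ggplot(classified,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = factor(.data$class))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "class") +
    ggplot2::theme_minimal()
}

#' Dendrogram sketch of a regression tree
#'
#' Draws the split structure with branch lengths proportional to the
#' deviance explained by each split, labels internal nodes with their split
#' predicate and leaves with the (first) mean response and cell count.
#'
#' @param object A `zd_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zd_tree <- function(object, ...) {
  leaves <- which(vapply(object$nodes, `[[`, TRUE, "is_leaf"))
  xpos <- setNames(rep(NA_real_, length(object$nodes)),
                   seq_along(object$nodes))
  xpos[leaves] <- seq_along(leaves)
  # internal node x = midpoint of children, computed bottom-up
  depth_order <- order(vapply(object$nodes, `[[`, 0L, "depth"),
                       decreasing = TRUE)
  for (id in depth_order) {
    nd <- object$nodes[[id]]
    if (!nd$is_leaf) xpos[id] <- mean(xpos[c(nd$left, nd$right)])
  }
  ypos <- vapply(object$nodes, function(nd) {
    if (is.na(nd$parent)) return(0)
    d <- 0; cur <- nd
    while (!is.na(cur$parent)) {
      par <- object$nodes[[cur$parent]]
      d <- d + par$improve / object$root_ss
      cur <- par
    }
    -d
  }, 0)
  segs <- purrr::list_rbind(purrr::map(object$nodes, function(nd) {
    if (nd$is_leaf) return(NULL)
    tibble(x = xpos[nd$id], y = ypos[nd$id],
           xend = xpos[c(nd$left, nd$right)],
           yend = ypos[c(nd$left, nd$right)])
  }))
  labs <- purrr::list_rbind(purrr::map(object$nodes, function(nd) {
    mu <- node_mean_display(object, nd$mean)
    tibble(x = xpos[nd$id], y = ypos[nd$id], is_leaf = nd$is_leaf,
           label = if (nd$is_leaf) {
             sprintf("%.3g\nn=%d", mu[1], nd$n)
           } else {
             sprintf("%s < %.4g", nd$split_var, nd$threshold)
           })
  }))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend)) +
    ggplot2::geom_label(data = labs,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$label),
                        size = 3) +
    ggplot2::labs(x = NULL, y = "cumulative deviance explained") +
    ggplot2::theme_void()
}
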