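# Rule paths: each terminal node of a tree is described by the conjunction
# of split predicates on the root-to-leaf path.  The comparator convention
# matches the split convention (left = "<", right = ">="), so boundary
# values route identically whether predicted by the tree or classified by
# the extracted rules.

render_rule <- function(pred) {
  if (nrow(pred) == 0) return("TRUE")
  paste(sprintf("%s %s %g", pred$predictor, pred$op, pred$threshold),
        collapse = " & ")
}

collapse_predicates <- function(pred) {
  if (nrow(pred) == 0) return(pred)
  pred |>
    mutate(.ord = seq_len(n())) |>
    group_by(.data$predictor, .data$op) |>
    summarise(
      threshold = if (.data$op[1] == "<") min(.data$threshold)
      else max(.data$threshold),
      .ord = min(.data$.ord), .groups = "drop"
    ) |>
    arrange(.data$.ord) |>
    select("predictor", "op", "threshold")
}

#' Extract rule paths from a regression tree
#'
#' Walks every root-to-leaf path and returns one rule per terminal node:
#' the predicates in root-to-leaf order, with redundant predicates on the
#' same predictor collapsed to the tightest interval.  Class ids number the
#' leaves 1..k in tree (preorder) order.  The rules of one tree are
#' exhaustive and mutually exclusive, so they classify any point of
#' predictor space into exactly one class.
#'
#' @param tree A fitted (optionally pruned) `zd_tree`.
#' @return A tibble of class `zd_rules`: `class_id`, `node` (terminal node
#'   id), `n` (training cells in the leaf), one `mean_<response>` column per
#'   response, `predicates` (list column of tibbles with `predictor`, `op`
#'   in `<`/`>=`, `threshold`) and `rule` (the rendered conjunction).
#' @export
extract_rules <- function(tree) {
  paths <- list()
  walk <- function(id, pred) {
    nd <- tree$nodes[[id]]
    if (nd$is_leaf) {
      paths[[length(paths) + 1L]] <<- list(node = id, pred = pred)
      return(invisible())
    }
    base <- tibble(predictor = nd$split_var, op = "<",
                   threshold = nd$threshold)
    walk(nd$left, bind_rows(pred, base))
    base$op <- ">="
    walk(nd$right, bind_rows(pred, base))
  }
  empty <- tibble(predictor = character(), op = character(),
                  threshold = double())
  walk(1L, empty)

  rows <- purrr::imap(paths, function(p, i) {
    nd <- tree$nodes[[p$node]]
    mu <- node_mean_display(tree, nd$mean)
    out <- tibble(class_id = i, node = p$node, n = nd$n)
    for (k in seq_along(tree$responses)) {
      out[[paste0("mean_", tree$responses[k])]] <- unname(mu[k])
    }
    pred <- collapse_predicates(p$pred)
    out$predicates <- list(pred)
    out$rule <- render_rule(pred)
    out
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("zd_rules", class(out))
  attr(out, "responses") <- tree$responses
  out
}

#' Apply tree rules to a predictor grid
#'
#' Classifies every cell of a (typically finer-resolution) predictor grid by
#' the rule set extracted from a coarse-resolution tree, mapping regional
#' species groups onto the finer grid.  Every cell is assigned exactly one
#' class; a missing predictor layer is an error.
#'
#' @param rules A [extract_rules()] result.
#' @param grid Tibble of cells carrying every predictor named in the rules.
#' @return `grid` with an integer `class` column appended.
#' @export
apply_rules <- function(rules, grid) {
  needed <- unique(unlist(purrr::map(rules$predicates, "predictor")))
  miss <- setdiff(needed, names(grid))
  if (length(miss)) {
    abort(paste0("Grid lacks predictor layer(s): ",
                 paste(miss, collapse = ", ")))
  }
  n <- nrow(grid)
  hits <- integer(n)
  cls <- rep(NA_integer_, n)
  for (i in seq_len(nrow(rules))) {
    pred <- rules$predicates[[i]]
    m <- rep(TRUE, n)
    for (j in seq_len(nrow(pred))) {
      v <- grid[[pred$predictor[j]]]
      ok <- if (pred$op[j] == "<") v < pred$threshold[j] else {
        v >= pred$threshold[j]
      }
      m <- m & ok
    }
    cls[m] <- rules$class_id[i]
    hits <- hits + m
  }
  if (any(hits != 1L)) {
    abort("Rule set is not an exhaustive partition of the grid (incomplete tree rules?).")
  }
  grid$class <- cls
  grid
}

#' Per-class summary of a classified grid
#'
#' @param classified Output of [apply_rules()].
#' @param response Optional response column to average per class (e.g. the
#'   fine-resolution abundance).
#' @return Tibble with `class`, `n_cells` and, when `response` is given,
#'   `mean_response`.
#' @export
rule_class_stats <- function(classified, response = NULL) {
  out <- count(classified, class = .data$class, name = "n_cells")
  if (!is.null(response)) {
    means <- classified |>
      group_by(class = .data$class) |>
      summarise(mean_response = mean(.data[[response]], na.rm = TRUE),
                .groups = "drop")
    out <- left_join(out, means, by = "class")
  }
  out
}

#' Rank rules by terminal mean response
#'
#' Orders the rule set by descending terminal mean (the first response for a
#' multivariate tree), so the top rules delimit the regions of highest
#' abundance.  Ties are broken by larger terminal `n`, then by class id.
#'
#' @param rules A [extract_rules()] result.
#' @param top Optional number of top rules to keep.
#' @return The reordered rules tibble.
#' @export
rank_rules_by_abundance <- function(rules, top = NULL) {
  mean_col <- paste0("mean_", attr(rules, "responses")[1])
  out <- arrange(rules, desc(.data[[mean_col]]), desc(.data$n),
                 .data$class_id)
  if (!is.null(top)) out <- head(out, top)
  out
}
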