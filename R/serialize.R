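# Nested-JSON tree serialization shared by the univariate and multivariate
# fitters.  The JSON stores per-node statistics (split, n, mean vector on
# the display scale, within-node SS), enough to re-extract rules and predict
# from a reloaded tree; training data are not stored.

tree_to_list <- function(tree, id = 1L) {
  nd <- tree$nodes[[id]]
  mu <- node_mean_display(tree, nd$mean)
  out <- list(n = nd$n, ss = nd$ss,
              mean = as.list(setNames(mu, tree$responses)))
  if (!nd$is_leaf) {
    out$split_var <- nd$split_var
    out$threshold <- nd$threshold
    out$improve <- nd$improve
    out$left <- tree_to_list(tree, nd$left)
    out$right <- tree_to_list(tree, nd$right)
  }
  out
}

#' Serialize a regression tree to JSON
#'
#' @param tree A `zd_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(responses = as.list(tree$responses),
              predictors = as.list(tree$predictors),
              deviance_explained = deviance_explained(tree),
              root = tree_to_list(tree))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reload a regression tree from JSON
#'
#' Reconstructs a `zd_tree` from [write_tree_json()] output.  Node means are
#' stored on the display scale, so the reloaded tree predicts and extracts
#' rules identically; training rows (`where`, `X`, `Y`) are not restored.
#'
#' @param path JSON file written by [write_tree_json()].
#' @return A `zd_tree`.
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path)
  responses <- unlist(obj$responses)
  nodes <- list()
  build <- function(nd, parent, depth) {
    id <- length(nodes) + 1L
    is_leaf <- is.null(nd$split_var)
    nodes[[id]] <<- list(
      id = id, parent = parent, depth = depth, n = nd$n,
      mean = unlist(nd$mean), ss = nd$ss, is_leaf = is_leaf,
      split_var = if (is_leaf) NA_character_ else nd$split_var,
      threshold = if (is_leaf) NA_real_ else nd$threshold,
      left = NA_integer_, right = NA_integer_,
      improve = if (is_leaf) NA_real_ else nd$improve
    )
    if (!is_leaf) {
      nodes[[id]]$left <<- build(nd$left, id, depth + 1L)
      nodes[[id]]$right <<- build(nd$right, id, depth + 1L)
    }
    id
  }
  build(obj$root, NA_integer_, 0L)
  structure(
    list(nodes = nodes, where = NULL,
         X = matrix(numeric(), 0, length(obj$predictors),
                    dimnames = list(NULL, unlist(obj$predictors))),
         Y = NULL, responses = responses,
         predictors = unlist(obj$predictors), scaling = NULL,
         root_ss = nodes[[1]]$ss),
    class = if (length(responses) > 1) c("zd_mvtree", "zd_tree")
    else "zd_tree"
  )
}
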