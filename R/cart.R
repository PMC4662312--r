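# Regression-tree engine shared by the univariate and multivariate fitters.
#
# A tree is a list of node records in preorder; each node stores its own
# summary statistics (n, mean response vector, within-node sum of squares),
# so pruning is pure tree surgery.  Splits minimize the summed within-child
# squared deviation about the child mean vectors, with candidate thresholds
# at midpoints of adjacent distinct predictor values; ties are broken toward
# the lower predictor column index, then the lower threshold, making fits
# deterministic.

node_stats <- function(Y, idx) {
  ym <- colMeans(Y[idx, , drop = FALSE])
  ss <- sum(sweep(Y[idx, , drop = FALSE], 2, ym)^2)
  list(mean = ym, ss = ss)
}

# exhaustive-but-vectorized best split for one node
best_split <- function(X, Y, idx, min_node) {
  n <- length(idx)
  q <- ncol(Y)
  Ysub <- Y[idx, , drop = FALSE]
  tot <- colSums(Ysub)
  totsq <- sum(Ysub^2)
  sse_parent <- totsq - sum(tot^2) / n
  eps <- 1e-9 * max(sse_parent, 1)  # fp-tie guard: ties go to lower column
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xv <- X[idx, j]
    o <- order(xv)
    xs <- xv[o]
    Ys <- Ysub[o, , drop = FALSE]
    cy <- apply(Ys, 2, cumsum)
    if (q == 1) cy <- matrix(cy, ncol = 1)
    csq <- cumsum(rowSums(Ys^2))
    nl <- seq_len(n - 1L)
    valid <- nl >= min_node & (n - nl) >= min_node & xs[-n] < xs[-1]
    if (!any(valid)) next
    suml2 <- rowSums(cy[nl, , drop = FALSE]^2)
    sumr2 <- rowSums((matrix(tot, n - 1L, q, byrow = TRUE) -
                        cy[nl, , drop = FALSE])^2)
    sse <- (csq[nl] - suml2 / nl) +
      ((totsq - csq[nl]) - sumr2 / (n - nl))
    sse[!valid] <- Inf
    i <- which.min(sse)                    # first minimum = lowest threshold
    if (!is.finite(sse[i])) next
    improve <- sse_parent - sse[i]
    if (is.null(best) || improve > best$improve + eps) {
      best <- list(var = j, threshold = (xs[i] + xs[i + 1L]) / 2,
                   improve = improve)
    }
  }
  best
}

grow_cart <- function(X, Y, min_node, max_depth) {
  n <- nrow(X)
  nodes <- vector("list", 2L * n)
  nid <- 0L
  tol <- 1e-10 * max(node_stats(Y, seq_len(n))$ss, 1)
  where <- integer(n)

  grow <- function(idx, depth, parent) {
    nid <<- nid + 1L
    id <- nid
    st <- node_stats(Y, idx)
    nodes[[id]] <<- list(id = id, parent = parent, depth = depth,
                         n = length(idx), mean = st$mean, ss = st$ss,
                         is_leaf = TRUE, split_var = NA_character_,
                         threshold = NA_real_, left = NA_integer_,
                         right = NA_integer_, improve = NA_real_)
    sp <- NULL
    if (length(idx) >= 2L * min_node && depth < max_depth && st$ss > tol) {
      sp <- best_split(X, Y, idx, min_node)
      if (!is.null(sp) && sp$improve <= tol) sp <- NULL
    }
    if (is.null(sp)) {
      where[idx] <<- id
      return(id)
    }
    go_left <- X[idx, sp$var] < sp$threshold
    lid <- grow(idx[go_left], depth + 1L, id)
    rid <- grow(idx[!go_left], depth + 1L, id)
    nodes[[id]]$is_leaf <<- FALSE
    nodes[[id]]$split_var <<- colnames(X)[sp$var]
    nodes[[id]]$threshold <<- sp$threshold
    nodes[[id]]$improve <<- sp$improve
    nodes[[id]]$left <<- lid
    nodes[[id]]$right <<- rid
    id
  }
  grow(seq_len(n), 0L, NA_integer_)
  list(nodes = nodes[seq_len(nid)], where = where)
}

new_zd_tree <- function(nodes, where, X, Y, responses, scaling = NULL) {
  structure(
    list(nodes = nodes, where = where, X = X, Y = Y,
         responses = responses, predictors = colnames(X),
         scaling = scaling, root_ss = nodes[[1]]$ss),
    class = if (length(responses) > 1) c("zd_mvtree", "zd_tree") else "zd_tree"
  )
}

check_model_frame <- function(data, vars) {
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(data)[vars])
  if (!is.numeric(m)) abort("Model columns must be numeric.")
  if (anyNA(m)) abort("Missing values are not allowed in model columns.")
  m
}

#' Fit a regression tree
#'
#' Grows a binary regression tree by recursive variance-reduction (CART)
#' splitting: each split maximizes the reduction in the within-node sum of
#' squared deviations, searched over every predictor and every midpoint
#' between adjacent distinct values.  Growth stops when a node has fewer
#' than `2 * min_node` observations, no split leaves both children with at
#' least `min_node` observations, the node is pure, or `max_depth` is
#' reached.  A constant response yields a root-only tree.
#'
#' @param data Data frame of grid cells (or any observations).
#' @param response Name of the numeric response column.
#' @param predictors Character vector of predictor columns (default: the
#'   standard nine-predictor set intersected with `data`'s columns).
#'   Predictor order is the tie-break order for equal-quality splits.
#' @param min_node Minimum observations in each child node (default 5).
#' @param max_depth Maximum tree depth.
#' @return An object of class `zd_tree`; see [tidy.zd_tree()],
#'   [glance.zd_tree()], [predict.zd_tree()], [prune_to_leaves()],
#'   [extract_rules()].
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:6, y = c(0, 0, 0, 10, 10, 10))
#' fit <- fit_tree(d, "y", "x", min_node = 1)
#' tidy(fit)
fit_tree <- function(data, response, predictors = NULL, min_node = 5,
                     max_depth = 30) {
  predictors <- predictors %||% intersect(predictor_names(), names(data))
  if (!length(predictors)) abort("No predictor columns found.")
  X <- check_model_frame(data, predictors)
  Y <- check_model_frame(data, response)
  g <- grow_cart(X, Y, as.integer(min_node), as.integer(max_depth))
  new_zd_tree(g$nodes, g$where, X, Y, response)
}

#' Standardize a response matrix
#'
#' Centers each column to mean 0 and scales to unit standard deviation, so
#' that no response dominates the squared-distance split criterion of a
#' multivariate tree.  Zero-variance columns are dropped with a warning.
#' The centering and scaling vectors are kept as attributes for
#' back-transformation with [unstandardize()].
#'
#' @param Y Numeric matrix or data frame of responses.
#' @return Standardized matrix with attributes `scaled:center` and
#'   `scaled:scale`.
#' @export
standardize_responses <- function(Y) {
  Y <- as.matrix(Y)
  sds <- apply(Y, 2, sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero)) {
    warn(paste0("Dropping zero-variance response column(s): ",
                paste(colnames(Y)[zero], collapse = ", ")))
    Y <- Y[, !zero, drop = FALSE]
    if (ncol(Y) == 0) abort("All response columns have zero variance.")
  }
  scale(Y)
}

#' Back-transform a standardized response matrix
#'
#' @param Ys Matrix produced by [standardize_responses()].
#' @return Matrix on the original scale.
#' @export
unstandardize <- function(Ys) {
  ctr <- attr(Ys, "scaled:center")
  scl <- attr(Ys, "scaled:scale")
  if (is.null(ctr) || is.null(scl)) abort("`Ys` carries no scaling record.")
  sweep(sweep(unclass(Ys), 2, scl, `*`), 2, ctr, `+`)
}

#' Fit a multivariate regression tree
#'
#' Fits a regression tree on a multivariate response (by default the
#' demographic triple IV, PM, SC), splitting to minimize the summed within-
#' child squared Euclidean distance to the child mean vectors -- a
#' constrained clustering of cells by their joint demographic response.
#' Responses are standardized to unit variance before splitting (so counts
#' do not dominate the distances); node means are reported back on the
#' original scale.  The grown tree is pruned to at most `max_leaves`
#' terminal nodes by weakest-link cost-complexity pruning.
#'
#' @param data Data frame of grid cells; rows with missing responses must be
#'   filtered out beforehand (e.g. nonpresence cells with undefined
#'   mortality).
#' @param responses Character vector of response columns.
#' @param predictors Predictor columns; defaults as in [fit_tree()].
#' @param min_node Minimum observations per child node.
#' @param max_leaves Terminal-node budget after pruning (default 8).
#' @param standardize Standardize responses before splitting? (default TRUE)
#' @param max_depth Maximum depth of the grown tree.
#' @return An object of classes `zd_mvtree`, `zd_tree`.
#' @export
fit_mvtree <- function(data, responses = c("iv", "pm", "sc"),
                       predictors = NULL, min_node = 5, max_leaves = 8,
                       standardize = TRUE, max_depth = 30) {
  predictors <- predictors %||% intersect(predictor_names(), names(data))
  X <- check_model_frame(data, predictors)
  Yraw <- check_model_frame(data, responses)
  if (nrow(Yraw) < 2 * min_node) {
    abort("Too few rows for the requested minimum node size.")
  }
  scaling <- NULL
  Y <- Yraw
  if (standardize) {
    Y <- standardize_responses(Yraw)
    scaling <- list(center = attr(Y, "scaled:center"),
                    scale = attr(Y, "scaled:scale"))
    Y <- unclass(Y)
    attr(Y, "scaled:center") <- NULL
    attr(Y, "scaled:scale") <- NULL
  }
  g <- grow_cart(X, Y, as.integer(min_node), as.integer(max_depth))
  tree <- new_zd_tree(g$nodes, g$where, X, Y, colnames(Y), scaling)
  if (n_leaves(tree) > max_leaves) tree <- prune_to_leaves(tree, max_leaves)
  tree
}

n_leaves <- function(tree) sum(vapply(tree$nodes, `[[`, TRUE, "is_leaf"))

subtree_leaf_ids <- function(nodes, id) {
  nd <- nodes[[id]]
  if (nd$is_leaf) return(id)
  c(subtree_leaf_ids(nodes, nd$left), subtree_leaf_ids(nodes, nd$right))
}

descendant_ids <- function(nodes, id) {
  nd <- nodes[[id]]
  if (nd$is_leaf) return(integer())
  c(nd$left, nd$right,
    descendant_ids(nodes, nd$left), descendant_ids(nodes, nd$right))
}

# renumber reachable nodes in preorder after collapses
compact_nodes <- function(nodes) {
  out <- list()
  walk <- function(id, parent, depth) {
    nd <- nodes[[id]]
    new_id <- length(out) + 1L
    nd$id <- new_id; nd$parent <- parent; nd$depth <- depth
    out[[new_id]] <<- nd
    if (!nd$is_leaf) {
      out[[new_id]]$left <<- walk(nd$left, new_id, depth + 1L)
      out[[new_id]]$right <<- walk(nd$right, new_id, depth + 1L)
    }
    new_id
  }
  walk(1L, NA_integer_, 0L)
  out
}

route_rows <- function(nodes, X) {
  n <- nrow(X)
  leaf <- integer(n)
  assign_node <- function(id, idx) {
    nd <- nodes[[id]]
    if (nd$is_leaf) {
      leaf[idx] <<- id
      return(invisible())
    }
    go_left <- X[idx, nd$split_var] < nd$threshold
    assign_node(nd$left, idx[go_left])
    assign_node(nd$right, idx[!go_left])
  }
  assign_node(1L, seq_len(n))
  leaf
}

#' Prune a tree to a target number of leaves
#'
#' Weakest-link cost-complexity pruning: repeatedly collapses the internal
#' node with the smallest per-leaf deviance gain
#' \eqn{g(t) = (SS_t - \sum_{leaves(t)} SS) / (|leaves(t)| - 1)} until at
#' most `k` terminal nodes remain (exactly `k` when the collapse sequence
#' passes through it; the pruning path is nested).  A tree with `k` or fewer
#' leaves is returned unchanged; a tree asked for more leaves than it has
#' triggers a warning.
#'
#' @param tree A `zd_tree`.
#' @param k Target number of terminal nodes (at least 1).
#' @return The pruned `zd_tree`.
#' @export
prune_to_leaves <- function(tree, k) {
  if (k < 1) abort("`k` must be at least 1.")
  if (n_leaves(tree) < k) {
    warn(sprintf("Tree has only %d leaves; returned unchanged.",
                 n_leaves(tree)))
    return(tree)
  }
  nodes <- tree$nodes
  count_leaves <- function() sum(vapply(nodes, `[[`, TRUE, "is_leaf"))
  while (count_leaves() > k) {
    internal <- which(!vapply(nodes, `[[`, TRUE, "is_leaf"))
    g <- vapply(internal, function(id) {
      leaves <- subtree_leaf_ids(nodes, id)
      r_sub <- sum(vapply(nodes[leaves], `[[`, 0, "ss"))
      (nodes[[id]]$ss - r_sub) / (length(leaves) - 1)
    }, 0)
    weakest <- internal[which.min(g)]        # ties: smallest id (nearest root)
    drop <- descendant_ids(nodes, weakest)
    nodes[[weakest]]$is_leaf <- TRUE
    nodes[[weakest]]$left <- NA_integer_
    nodes[[weakest]]$right <- NA_integer_
    nodes[[weakest]]$split_var <- NA_character_
    nodes[[weakest]]$threshold <- NA_real_
    nodes[[weakest]]$improve <- NA_real_
    for (id in drop) nodes[id] <- list(NULL)
    nodes <- nodes[!vapply(nodes, is.null, TRUE)]
    # re-index after removal
    nodes <- reindex_nodes(nodes)
  }
  tree$nodes <- compact_nodes(nodes)
  tree$where <- route_rows(tree$nodes, tree$X)
  tree
}

# after deleting entries, node ids no longer equal positions; rebuild maps
reindex_nodes <- function(nodes) {
  old_ids <- vapply(nodes, `[[`, 0L, "id")
  remap <- function(id) {
    if (is.na(id)) return(NA_integer_)
    match(id, old_ids)
  }
  for (i in seq_along(nodes)) {
    nodes[[i]]$id <- i
    nodes[[i]]$parent <- remap(nodes[[i]]$parent)
    nodes[[i]]$left <- remap(nodes[[i]]$left)
    nodes[[i]]$right <- remap(nodes[[i]]$right)
  }
  nodes
}

# node means on the reporting (original) scale
node_mean_display <- function(tree, mean_vec) {
  if (is.null(tree$scaling)) return(mean_vec)
  mean_vec * tree$scaling$scale + tree$scaling$center
}

#' Predict from a regression tree
#'
#' Routes observations down the tree (`<` goes left, `>=` goes right, the
#' same convention used in rule extraction and application).
#'
#' @param object A `zd_tree`.
#' @param newdata Data frame with the tree's predictor columns; defaults to
#'   the training data.
#' @param type `"response"` for fitted node means (a tibble, one column per
#'   response, back-transformed to the original scale) or `"leaf"` for the
#'   terminal-node id of each row.
#' @param ... Unused.
#' @return Tibble of fitted means or an integer vector of leaf ids.
#' @export
predict.zd_tree <- function(object, newdata = NULL,
                            type = c("response", "leaf"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else {
    check_model_frame(newdata, object$predictors)
  }
  leaf <- route_rows(object$nodes, X)
  if (type == "leaf") return(leaf)
  q <- length(object$responses)
  flat <- vapply(object$nodes[leaf],
                 function(nd) unname(node_mean_display(object, nd$mean)),
                 numeric(q))
  means <- if (q == 1) matrix(flat, ncol = 1) else t(flat)
  colnames(means) <- object$responses
  as_tibble(means)
}

#' @export
print.zd_tree <- function(x, digits = 4, ...) {
  kind <- if (inherits(x, "zd_mvtree")) "multivariate regression tree"
  else "regression tree"
  cat(sprintf("<zd_tree> %s: %d nodes, %d leaves, n = %d\n", kind,
              length(x$nodes), n_leaves(x), x$nodes[[1]]$n))
  cat(sprintf("  deviance explained: %.1f%%\n", 100 * deviance_explained(x)))
  show <- function(id, prefix) {
    nd <- x$nodes[[id]]
    mu <- node_mean_display(x, nd$mean)
    lab <- paste(signif(mu, digits), collapse = ", ")
    if (nd$is_leaf) {
      cat(sprintf("%s* leaf %d: mean %s (n=%d)\n", prefix, nd$id, lab, nd$n))
    } else {
      cat(sprintf("%s%s < %s (n=%d, mean %s)\n", prefix, nd$split_var,
                  signif(nd$threshold, digits), nd$n, lab))
      show(nd$left, paste0(prefix, "  "))
      cat(sprintf("%s%s >= %s\n", prefix, nd$split_var,
                  signif(nd$threshold, digits)))
      show(nd$right, paste0(prefix, "  "))
    }
  }
  show(1L, "  ")
  invisible(x)
}

#' Fraction of total deviance explained by a tree's leaves
#'
#' @param tree A `zd_tree`.
#' @return Fraction in \[0, 1\]: 1 - (sum of leaf within-node SS) / root SS.
#' @export
deviance_explained <- function(tree) {
  if (tree$root_ss == 0) return(0)
  leaf_ss <- sum(vapply(Filter(function(nd) nd$is_leaf, tree$nodes),
                        `[[`, 0, "ss"))
  1 - leaf_ss / tree$root_ss
}

#' Tidy a regression tree into a node table
#'
#' @param x A `zd_tree`.
#' @param ... Unused.
#' @return Tibble with one row per node: `node`, `parent`, `depth`,
#'   `is_leaf`, `split_var`, `threshold`, `n`, `ss`, `improve`,
#'   `pct_deviance` (percent of the root deviance explained by the node's
#'   split) and one `mean_<response>` column per response (original scale).
#' @export
tidy.zd_tree <- function(x, ...) {
  rows <- purrr::map(x$nodes, function(nd) {
    mu <- node_mean_display(x, nd$mean)
    out <- tibble(node = nd$id, parent = nd$parent, depth = nd$depth,
                  is_leaf = nd$is_leaf, split_var = nd$split_var,
                  threshold = nd$threshold, n = nd$n, ss = nd$ss,
                  improve = nd$improve,
                  pct_deviance = if (x$root_ss > 0) {
                    100 * nd$improve / x$root_ss
                  } else NA_real_)
    for (k in seq_along(x$responses)) {
      out[[paste0("mean_", x$responses[k])]] <- unname(mu[k])
    }
    out
  })
  purrr::list_rbind(rows)
}

#' One-row summary of a regression tree
#'
#' @param x A `zd_tree`.
#' @param ... Unused.
#' @return Tibble with `n`, `n_leaves`, `deviance_explained` (fraction) and
#'   `root_ss`.
#' @export
glance.zd_tree <- function(x, ...) {
  tibble(n = x$nodes[[1]]$n, n_leaves = n_leaves(x),
         deviance_explained = deviance_explained(x), root_ss = x$root_ss)
}

#' Per-leaf summary of a multivariate regression tree
#'
#' One row per terminal node with the back-transformed mean response vector,
#' the number of cells, and the root-to-leaf rule rendered as a conjunction
#' of predicates -- the tabular counterpart of a multivariate-tree figure in
#' which each leaf shows its joint demographic profile.
#'
#' @param tree A `zd_tree` (uni- or multivariate).
#' @return Tibble with `leaf` (class id), `node`, `n`, one `mean_<response>`
#'   column per response, and `rule`.
#' @export
mvtree_report <- function(tree) {
  rules <- extract_rules(tree)
  means <- tidy(tree) |>
    filter(.data$is_leaf) |>
    select("node", starts_with("mean_"))
  rules |>
    select(leaf = "class_id", "node", "n") |>
    left_join(means, by = "node") |>
    left_join(select(rules, "node", "rule"), by = "node")
}
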