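test_that("a constant response yields a root-only tree with zero deviance", {
  d <- tibble::tibble(x1 = 1:10, x2 = rnorm(10), y = 5)
  fit <- fit_tree(d, "y", c("x1", "x2"), min_node = 2)
  expect_equal(length(fit$nodes), 1)
  expect_equal(fit$nodes[[1]]$ss, 0)
  expect_equal(deviance_explained(fit), 0)
})

test_that("a step response splits at the midpoint with full deviance explained", {
  d <- tibble::tibble(x = 1:6, y = c(0, 0, 0, 10, 10, 10))
  fit <- fit_tree(d, "y", "x", min_node = 1)
  root <- fit$nodes[[1]]
  expect_false(root$is_leaf)
  expect_equal(root$threshold, 3.5)
  expect_equal(deviance_explained(fit), 1)
  # brute force over the 5 candidate splits agrees
  oracle <- brute_force_split(as.matrix(d["x"]), d["y"])
  expect_equal(oracle$threshold, 3.5)
})

test_that("first splits equal exhaustive enumeration on small instances", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(6:15, 1)
    p <- sample(1:3, 1)
    q <- sample(c(1, 3), 1)  # univariate and multivariate instances
    X <- matrix(round(rnorm(n * p), 2), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    Y <- matrix(rnorm(n * q), n, q,
                dimnames = list(NULL, paste0("y", 1:q)))
    d <- tibble::as_tibble(cbind(X, Y))
    fit <- if (q == 1) {
      fit_tree(d, "y1", colnames(X), min_node = 2, max_depth = 1)
    } else {
      fit_mvtree(d, colnames(Y), colnames(X), min_node = 2,
                 max_depth = 1, standardize = FALSE)
    }
    oracle <- brute_force_split(X, Y, min_node = 2)
    root <- fit$nodes[[1]]
    if (is.null(oracle)) {
      expect_true(root$is_leaf)
    } else {
      expect_equal(root$split_var, colnames(X)[oracle$var])
      expect_equal(root$threshold, oracle$threshold)
    }
  }
})

test_that("split search agrees with rpart on a fixture", {
  skip_if_not_installed("rpart")
  set.seed(7)
  d <- tibble::tibble(x1 = rnorm(80), x2 = rnorm(80), x3 = runif(80))
  d$y <- 3 * (d$x1 > 0.4) + d$x2 + rnorm(80, sd = 0.3)
  mine <- fit_tree(d, "y", c("x1", "x2", "x3"), min_node = 10)
  ref <- rpart::rpart(y ~ x1 + x2 + x3, d,
                      control = rpart::rpart.control(
                        minsplit = 20, minbucket = 10, cp = 0, xval = 0,
                        maxcompete = 0, maxsurrogate = 0))
  expect_equal(mine$nodes[[1]]$split_var,
               as.character(ref$frame$var[1]))
  expect_equal(mine$nodes[[1]]$threshold,
               unname(ref$splits[1, "index"]), tolerance = 1e-8)
})

test_that("the SS decomposition holds at every split", {
  study <- default_study(seed = 12)
  fit <- fit_tree(study$coarse, "iv", min_node = 5)
  for (nd in fit$nodes) {
    if (nd$is_leaf) next
    l <- fit$nodes[[nd$left]]
    r <- fit$nodes[[nd$right]]
    expect_equal(nd$n, l$n + r$n)
    between <- l$n * sum((l$mean - nd$mean)^2) +
      r$n * sum((r$mean - nd$mean)^2)
    expect_equal(nd$ss, l$ss + r$ss + between, tolerance = 1e-9)
    expect_lte(l$ss + r$ss, nd$ss + 1e-9)
    expect_equal(nd$improve, nd$ss - l$ss - r$ss, tolerance = 1e-9)
  }
})

test_that("pruning walks a nested path down to the root", {
  study <- default_study(seed = 13)
  fit <- fit_tree(study$coarse, "iv", min_node = 5)
  full_leaves <- sum(vapply(fit$nodes, function(n) n$is_leaf, TRUE))
  expect_gt(full_leaves, 8)

  p1 <- prune_to_leaves(fit, 1)
  expect_equal(length(p1$nodes), 1)
  expect_equal(p1$nodes[[1]]$n, nrow(study$coarse))

  same <- prune_to_leaves(fit, full_leaves)
  expect_equal(length(same$nodes), length(fit$nodes))

  expect_warning(prune_to_leaves(p1, 5), "unchanged")

  # nestedness and monotone deviance along the cost-complexity path
  seq_k <- seq(full_leaves, 1)
  dev <- numeric(0)
  prev_rules <- NULL
  for (k in seq_k) {
    pk <- prune_to_leaves(fit, k)
    nl <- sum(vapply(pk$nodes, function(n) n$is_leaf, TRUE))
    expect_lte(nl, k)
    dev <- c(dev, deviance_explained(pk))
    splits <- tidy(pk) |>
      dplyr::filter(!is_leaf) |>
      dplyr::mutate(key = paste(split_var, signif(threshold, 12)))
    if (!is.null(prev_rules)) {
      expect_true(all(splits$key %in% prev_rules))
    }
    prev_rules <- splits$key
  }
  expect_true(all(diff(dev) <= 1e-9))  # deviance non-decreasing in k
  expect_error(prune_to_leaves(fit, 0), "at least 1")
})

test_that("response standardization round-trips and drops constants", {
  Y <- cbind(iv = runif(20, 0, 60), pm = runif(20, 0, 40),
             sc = rpois(20, 4))
  Ys <- standardize_responses(Y)
  expect_lt(max(abs(colMeans(Ys))), 1e-9)
  expect_equal(unname(apply(Ys, 2, sd)), rep(1, 3))
  expect_equal(unstandardize(Ys), Y, ignore_attr = TRUE)
  expect_warning(S <- standardize_responses(cbind(Y, k = 1)), "zero-variance")
  expect_equal(colnames(S), colnames(Y))
})

test_that("a multivariate tree with constant extra columns matches the univariate tree", {
  study <- default_study(seed = 14)
  cells <- dplyr::filter(study$coarse, !is.na(pm))
  cells$c1 <- 1
  cells$c2 <- 2
  uni <- prune_to_leaves(fit_tree(cells, "iv", min_node = 5), 6)
  mv <- suppressWarnings(
    fit_mvtree(cells, c("iv", "c1", "c2"), min_node = 5, max_leaves = 6))
  expect_equal(
    tidy(mv)[c("node", "split_var", "threshold", "n")],
    tidy(uni)[c("node", "split_var", "threshold", "n")])
})

test_that("a multivariate tree separates two response clusters on one predictor", {
  set.seed(5)
  n <- 40
  grp <- rep(0:1, each = n / 2)
  d <- tibble::tibble(
    x1 = grp + runif(n, -0.3, 0.3),
    x2 = rnorm(n),
    iv = 10 + 30 * grp + rnorm(n, sd = 0.5),
    pm = 40 - 25 * grp + rnorm(n, sd = 0.5),
    sc = 5 + 10 * grp + rnorm(n, sd = 0.5))
  mv <- fit_mvtree(d, c("iv", "pm", "sc"), c("x1", "x2"), min_node = 5,
                   max_leaves = 2)
  root <- mv$nodes[[1]]
  expect_equal(root$split_var, "x1")
  left <- predict(mv, type = "leaf") == root$left
  expect_equal(sort(which(left)), which(grp == 0))
  rep <- mvtree_report(mv)
  expect_equal(nrow(rep), 2)
  expect_equal(sum(rep$n), n)
  expect_equal(rep$mean_iv, c(10, 40), tolerance = 0.05)
  expect_equal(rep$mean_pm, c(40, 15), tolerance = 0.05)
})

test_that("mvtree_report on a root-only tree returns the column means", {
  d <- tibble::tibble(x = rnorm(12), iv = 5, pm = 3, sc = 1)
  mv <- suppressWarnings(fit_mvtree(d, c("iv", "pm", "sc"), "x",
                                    min_node = 5, standardize = FALSE))
  rep <- mvtree_report(mv)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$rule, "TRUE")
  expect_equal(rep$mean_iv, 5)
  expect_equal(rep$n, 12)
})

test_that("trees serialize to JSON and reload with identical predictions", {
  study <- default_study(seed = 15)
  fit <- prune_to_leaves(fit_tree(study$coarse, "iv", min_node = 5), 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(fit, path)
  back <- read_tree_json(path)
  expect_equal(predict(back, study$coarse), predict(fit, study$coarse))
  expect_equal(extract_rules(back)$rule, extract_rules(fit)$rule)
})

test_that("missing predictor values are rejected", {
  d <- tibble::tibble(x = c(1, NA, 3, 4), y = 1:4)
  expect_error(fit_tree(d, "y", "x", min_node = 1), "Missing values")
})
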