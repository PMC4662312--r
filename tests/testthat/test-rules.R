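test_that("a root-only tree yields one universal rule", {
  d <- tibble::tibble(x = rnorm(12), y = 1)
  fit <- fit_tree(d, "y", "x", min_node = 2)
  rules <- extract_rules(fit)
  expect_equal(nrow(rules), 1)
  expect_equal(rules$rule, "TRUE")
  cl <- apply_rules(rules, tibble::tibble(x = rnorm(50)))
  expect_true(all(cl$class == 1))
})

test_that("an eight-leaf tree yields eight exhaustive rule paths", {
  study <- default_study(seed = 21)
  fit <- prune_to_leaves(fit_tree(study$coarse, "iv", min_node = 5), 8)
  rules <- extract_rules(fit)
  expect_equal(nrow(rules), 8)
  expect_equal(rules$class_id, 1:8)
  expect_equal(sum(rules$n), nrow(study$coarse))
})

test_that("extract-then-apply reproduces the tree's own leaf assignment", {
  study <- default_study(seed = 22)
  fit <- prune_to_leaves(fit_tree(study$coarse, "iv", min_node = 5), 8)
  rules <- extract_rules(fit)
  cl <- apply_rules(rules, study$coarse)
  native_leaf <- predict(fit, study$coarse, type = "leaf")
  expect_equal(rules$node[cl$class], native_leaf)
  # and on the fine grid every cell gets exactly one class
  clf <- apply_rules(rules, study$landscape$fine)
  expect_true(all(!is.na(clf$class)))
  expect_setequal(unique(clf$class), 1:8)
})

test_that("refinement factor 1 reproduces the coarse class map", {
  land <- small_landscape(seed = 23, refinement = 1)
  scen <- demography_scenario(breakpoints = hemlock_bp(), seed = 24)
  plots <- generate_plots(land, scen)
  coarse <- aggregate_to_grid(plots, land, "coarse")
  fit <- prune_to_leaves(fit_tree(coarse, "iv", min_node = 5), 6)
  rules <- extract_rules(fit)
  on_coarse <- apply_rules(rules, land$coarse)
  on_fine <- apply_rules(rules, land$fine)
  expect_equal(on_fine$class, on_coarse$class)
})

test_that("most fine cells inherit their coarse parent's class on a smooth landscape", {
  study <- default_study(seed = 25)
  fit <- prune_to_leaves(fit_tree(study$coarse, "iv", min_node = 5), 8)
  rules <- extract_rules(fit)
  fine_cl <- apply_rules(rules, study$landscape$fine)
  coarse_cl <- apply_rules(rules, study$landscape$coarse)
  parent_class <- coarse_cl$class[match(fine_cl$coarse_cell,
                                        coarse_cl$cell)]
  mismatch <- mean(fine_cl$class != parent_class)
  expect_lt(mismatch, 0.2)
  # per-cell oracle: evaluate every predicate directly
  for (i in sample(nrow(fine_cl), 25)) {
    cell <- fine_cl[i, ]
    hit <- vapply(seq_len(nrow(rules)), function(r) {
      pred <- rules$predicates[[r]]
      all(vapply(seq_len(nrow(pred)), function(j) {
        v <- cell[[pred$predictor[j]]]
        if (pred$op[j] == "<") v < pred$threshold[j] else v >= pred$threshold[j]
      }, TRUE))
    }, TRUE)
    expect_equal(sum(hit), 1)
    expect_equal(rules$class_id[hit], cell$class)
  }
})

test_that("predicates on one predictor collapse to the tightest interval", {
  # hand-built tree: x < 10 then x < 4 keeps only the tighter bound
  d <- tibble::tibble(x = c(1, 2, 3, 5, 6, 8, 11, 12),
                      y = c(0, 0, 0, 5, 5, 5, 9, 9))
  fit <- fit_tree(d, "y", "x", min_node = 1)
  rules <- extract_rules(fit)
  for (i in seq_len(nrow(rules))) {
    pred <- rules$predicates[[i]]
    expect_lte(nrow(pred), 2 * dplyr::n_distinct(pred$predictor))
    expect_false(any(duplicated(pred[c("predictor", "op")])))
  }
})

test_that("rules rank by terminal mean with the stated tie-breaks", {
  rules <- tibble::tibble(
    class_id = 1:4, node = c(3, 4, 6, 7), n = c(10, 30, 20, 20),
    mean_iv = c(5, 12, 12, 3),
    predicates = replicate(4, tibble::tibble(), simplify = FALSE),
    rule = "r")
  class(rules) <- c("zd_rules", class(rules))
  attr(rules, "responses") <- "iv"
  ranked <- rank_rules_by_abundance(rules)
  expect_equal(ranked$class_id, c(2, 3, 1, 4))  # mean desc, then n desc
  expect_equal(rank_rules_by_abundance(rules, top = 1)$class_id, 2)

  # on a fitted tree the top rule region has the highest empirical mean
  study <- default_study(seed = 26)
  fit <- prune_to_leaves(fit_tree(study$coarse, "iv", min_node = 5), 8)
  fitted_rules <- extract_rules(fit)
  cl <- apply_rules(fitted_rules, study$coarse)
  regional <- dplyr::summarise(dplyr::group_by(cl, class),
                               m = mean(iv), .groups = "drop")
  top <- rank_rules_by_abundance(fitted_rules)$class_id[1]
  expect_equal(top, regional$class[which.max(regional$m)])
})

test_that("a missing predictor layer is a clear error", {
  study <- default_study(seed = 27)
  fit <- prune_to_leaves(fit_tree(study$coarse, "iv", min_node = 5), 4)
  rules <- extract_rules(fit)
  used <- unique(unlist(purrr::map(rules$predicates, "predictor")))
  grid <- dplyr::select(study$landscape$fine, -dplyr::all_of(used[1]))
  expect_error(apply_rules(rules, grid), used[1])
})
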