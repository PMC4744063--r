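# Boosted regression trees: hand-computed toys, exhaustive-search oracle
# equivalence, importance accounting, stopping and determinism.

test_that("a perfectly aligned binary split is found with improvement 4", {
  X <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "x1"))
  r <- c(-1, -1, 1, 1)
  tree <- fit_regression_tree(X, r, max_terminal_nodes = 2, min_node_size = 1)
  sp <- tree_splits(tree)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$var, 1)
  expect_equal(sp$thresh, 0.5)
  expect_equal(sp$improvement, 4)
  expect_equal(sort(unique(predict(tree, X))), c(-1, 1))
})

test_that("constant residuals give a single-leaf tree", {
  X <- matrix(rnorm(20), ncol = 2)
  tree <- fit_regression_tree(X, rep(0.25, 10), max_terminal_nodes = 4,
                              min_node_size = 1)
  expect_equal(nrow(tree_splits(tree)), 0)
  expect_equal(unique(predict(tree, X)), 0.25)
})

test_that("tree growth equals the exhaustive-search oracle on random toys", {
  set.seed(99)
  for (case in 1:60) {
    n <- sample(6:25, 1)
    p <- sample(1:3, 1)
    X <- matrix(round(rnorm(n * p), 2), n, p)
    r <- round(rnorm(n), 2)
    leaves <- sample(2:5, 1)
    mns <- sample(1:2, 1)
    got <- fit_regression_tree(X, r, max_terminal_nodes = leaves,
                               min_node_size = mns)
    want <- oracle_tree(X, r, max_leaves = leaves, min_node_size = mns)
    expect_equal(unname(predict(got, X)), want$fitted, tolerance = 1e-12,
                 info = paste("case", case))
    gs <- tree_splits(got)
    expect_equal(gs$var, want$splits$var, info = paste("case", case))
    expect_equal(gs$thresh, want$splits$thresh, tolerance = 1e-12)
    expect_equal(gs$improvement, want$splits$improvement, tolerance = 1e-9)
  }
})

test_that("missing split-variable cells are routed to the majority child", {
  X <- matrix(c(0, 0, 0, 1, 1, NA), ncol = 1, dimnames = list(NULL, "x1"))
  r <- c(-1, -1, -1, 1, 1, 5)
  tree <- fit_regression_tree(X, r, max_terminal_nodes = 2, min_node_size = 1)
  sp <- tree_splits(tree)
  expect_equal(sp$var, 1)
  # NA row joins the left (larger) child: leaf means are (-1-1-1+5)/4 and +1
  pr <- predict(tree, X)
  expect_equal(pr[6], pr[1])
  expect_equal(unname(pr[1]), 0.5)
  expect_equal(unname(pr[4]), 1)
})

test_that("one boosting iteration on the 4-point toy matches hand computation", {
  X <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "x1"))
  y <- c(0, 0, 1, 1)
  cfg <- boost_config(shrinkage = 1, bag_fraction = 1, max_terminal_nodes = 2,
                      max_iterations = 1, train_fraction = 1,
                      min_node_size = 1, seed = 1)
  m <- fit_boosted_trees(X, y, cfg)
  expect_equal(m$F0, 0)                         # log-odds of 0.5
  # residuals (+-0.5), Newton leaf = sum r / sum p(1-p) = 1/0.5 = 2
  p <- predict(m, X)
  expect_equal(unname(p), plogis(c(-2, -2, 2, 2)))
  # probabilities ordered consistently with residual signs
  expect_true(all(p[3:4] > p[1:2]))
  # pseudo-R2 matches the hand-computed likelihood ratio
  r2 <- pseudo_r2(m, X, y)
  expect_equal(r2, 1 - (4 * log(plogis(2))) / (4 * log(0.5)),
               tolerance = 1e-9)
  # importance: the only split variable carries 100%
  expect_equal(unname(m$importance["x1"]), 100)
})

test_that("vanishing shrinkage leaves predictions at the base rate", {
  set.seed(4)
  X <- matrix(rnorm(200), 100, 2)
  y <- rbinom(100, 1, 0.4)
  cfg <- boost_config(shrinkage = 1e-9, bag_fraction = 1,
                      max_iterations = 1, train_fraction = 1,
                      min_node_size = 5, seed = 2)
  m <- fit_boosted_trees(X, y, cfg)
  expect_equal(unname(predict(m, X)), rep(plogis(m$F0), 100),
               tolerance = 1e-6)
})

test_that("importance rescales proportionally and sums to 100", {
  set.seed(12)
  sim <- generate_collinear_sim("varying_betas", n = 1500, seed = 12)
  X <- sim$dataset$values[, predictor_names(sim$dataset)]
  y <- outcome_values(sim$dataset)
  m <- fit_boosted_trees(X, y, boost_config(shrinkage = 0.05,
                                            max_iterations = 80, seed = 3))
  expect_equal(sum(m$importance), 100, tolerance = 1e-9)
  expect_true(all(m$importance >= 0))
  raw <- variable_importance(m, normalize = FALSE)
  expect_equal(unname(100 * raw / sum(raw)), unname(m$importance),
               tolerance = 1e-12)
})

test_that("early stopping never keeps a model worse than the constant", {
  for (s in 1:5) {
    sim <- generate_collinear_sim("equal_betas", n = 800, seed = 200 + s)
    X <- sim$dataset$values[, predictor_names(sim$dataset)]
    y <- outcome_values(sim$dataset)
    m <- fit_boosted_trees(X, y, boost_config(shrinkage = 0.1,
                                              max_iterations = 60, seed = s))
    if (m$best_iteration > 0)
      expect_gte(m$valid_loglik[m$best_iteration], m$valid_loglik_start)
    expect_lte(m$best_iteration, m$n_iterations)
  }
})

test_that("boosting is deterministic given a seed and bags cover all rows", {
  sim <- generate_collinear_sim("equal_betas", n = 600, seed = 9)
  X <- sim$dataset$values[, predictor_names(sim$dataset)]
  y <- outcome_values(sim$dataset)
  cfg <- boost_config(shrinkage = 0.02, max_iterations = 200, patience = 200,
                      seed = 77)
  m1 <- fit_boosted_trees(X, y, cfg, record_bags = TRUE)
  m2 <- fit_boosted_trees(X, y, cfg, record_bags = TRUE)
  expect_identical(m1$trees, m2$trees)
  expect_identical(m1$bags, m2$bags)
  expect_identical(m1$importance, m2$importance)
  # every training row eventually appears in some bag
  expect_setequal(sort(unique(unlist(m1$bags))), m1$train_rows)
})

test_that("predict validates columns and zero-tree models are constant", {
  X <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "x1"))
  y <- c(0, 1, 0, 1)  # no signal: stumps cannot improve
  cfg <- boost_config(shrinkage = 1, bag_fraction = 1, max_terminal_nodes = 2,
                      max_iterations = 3, train_fraction = 1,
                      min_node_size = 1, seed = 5)
  suppressWarnings(m <- fit_boosted_trees(X, y, cfg))
  X2 <- matrix(1:4, ncol = 1, dimnames = list(NULL, "other"))
  expect_error(predict(m, X2), "lacks predictor")
  m$trees <- list()
  expect_equal(unname(predict(m, X)), rep(plogis(m$F0), 4))
})

test_that("degenerate inputs raise the documented errors", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_boosted_trees(X, rep(1, 20), boost_config(seed = 1)))
  m0 <- fit_boosted_trees(X, rep(c(0, 1), 10),
                          boost_config(shrinkage = 1e-9, bag_fraction = 1,
                                       max_iterations = 1, train_fraction = 1,
                                       min_node_size = 10, seed = 1))
  expect_error(pseudo_r2(m0, X, rep(1, 20)), "single-class")
})
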