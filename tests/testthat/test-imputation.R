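# Chained-equation multiple imputation: preservation, determinism, stacking
# arithmetic, statistical recovery, convergence traces, grouped chains.

ds_small_group <- function(ds, g) {
  keep <- c(which(g == 0), which(g == 1)[1:10])
  out <- ds
  out$values <- ds$values[keep, ]
  out$mask <- ds$mask[keep, ]
  out$weights <- ds$weights[keep]
  out$strata <- ds$strata[keep]
  out$psu <- ds$psu[keep]
  out$ids <- ds$ids[keep]
  out
}

make_missing_study <- function(n = 800, seed = 1, fraction = 0.2) {
  st <- generate_survey_study(sim_config(n = n, p = 4,
                                         betas = c(0.5, 0.3, 0, 0),
                                         target_prevalence = 0.2, seed = seed,
                                         missingness = list(mechanism = "MCAR",
                                                            fraction = fraction)))
  st$dataset
}

test_that("observed cells are preserved bit-exactly and chains are deterministic", {
  ds <- make_missing_study(seed = 2)
  cfg <- imputation_config(m = 3, burn_in = 5, seed = 10)
  mi <- fit_chained_imputation(ds, cfg)
  expect_length(mi$completed, 3)
  for (d in mi$completed) {
    expect_true(all(d$mask))
    expect_identical(d$values[ds$mask], ds$values[ds$mask])
  }
  mi2 <- fit_chained_imputation(ds, cfg)
  for (i in 1:3)
    expect_identical(mi$completed[[i]]$values, mi2$completed[[i]]$values)
})

test_that("a dataset with no missing cells yields identical completed copies", {
  st <- generate_survey_study(sim_config(n = 200, p = 3, betas = rep(0, 3),
                                         seed = 4))
  mi <- fit_chained_imputation(st$dataset, imputation_config(m = 2, seed = 1))
  for (d in mi$completed)
    expect_identical(d$values, st$dataset$values)
  expect_equal(nrow(convergence_diagnostics(mi)), 0)
})

test_that("stacking produces n x (m + 1) rows with set indices 0..m", {
  st <- generate_survey_study(sim_config(n = 10, p = 4, betas = rep(0, 4),
                                         target_prevalence = 0.4,
                                         n_strata = 1, psus_per_stratum = 1,
                                         seed = 6,
                                         missingness = list(mechanism = "MCAR",
                                                            fraction = 0.3)))
  ds <- st$dataset
  mi <- fit_chained_imputation(ds, imputation_config(m = 1, burn_in = 3,
                                                     seed = 2))
  stk <- stack_imputations(mi)
  expect_equal(nrow(stk), 20)
  expect_equal(sort(unique(stk$`_mi_id`)), c(0, 1))
  expect_equal(unname(table(stk$`_mi_id`)), rep(10L, 2),
               ignore_attr = TRUE)

  ds2 <- make_missing_study(n = 150, seed = 7)
  mi2 <- fit_chained_imputation(ds2, imputation_config(m = 4, burn_in = 3,
                                                       seed = 3))
  stk2 <- stack_imputations(mi2)
  expect_equal(nrow(stk2), 150 * 5)
  expect_equal(as.vector(table(stk2$`_mi_id`)), rep(150L, 5))
  # original rows keep their missing cells; imputed sets are complete
  expect_true(anyNA(stk2[stk2$`_mi_id` == 0, ]))
  expect_false(anyNA(stk2[stk2$`_mi_id` > 0, ]))
})

test_that("imputed binary cells are 0/1", {
  set.seed(8)
  n <- 300
  x1 <- rnorm(n)
  xb <- rbinom(n, 1, plogis(x1))
  y <- rbinom(n, 1, 0.3)
  vals <- cbind(y = y, x1 = x1, xb = xb)
  meta <- data.frame(name = c("y", "x1", "xb"),
                     kind = c("binary", "continuous", "binary"),
                     role = c("outcome", "predictor", "predictor"))
  ds <- survey_dataset(vals, meta)
  ds$values[sample(n, 60), "xb"] <- NA
  ds$values[sample(n, 40), "x1"] <- NA
  ds$mask <- !is.na(ds$values)
  mi <- fit_chained_imputation(ds, imputation_config(m = 3, burn_in = 5,
                                                     seed = 5))
  for (d in mi$completed)
    expect_true(all(d$values[, "xb"] %in% c(0, 1)))
})

test_that("imputation recovers a known correlation after MCAR deletion", {
  set.seed(20)
  n <- 5000
  Z <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, 0.7, 0.7, 1), 2))
  colnames(Z) <- c("x1", "x2")
  truth_cor <- cor(Z)[1, 2]
  y <- rbinom(n, 1, 0.2)
  meta <- data.frame(name = c("y", "x1", "x2"),
                     kind = c("binary", "continuous", "continuous"),
                     role = c("outcome", "predictor", "predictor"))
  ds <- survey_dataset(cbind(y = y, Z), meta)
  ds$values[sample(n, round(0.3 * n)), "x2"] <- NA
  ds$mask <- !is.na(ds$values)
  mi <- fit_chained_imputation(ds, imputation_config(m = 10, burn_in = 8,
                                                     seed = 12))
  cors <- vapply(mi$completed,
                 function(d) cor(d$values[, "x1"], d$values[, "x2"]), 1.0)
  expect_lt(abs(mean(cors) - truth_cor), 0.05)
  # imputed marginal means stay near the observed-data means
  obs_mean <- mean(ds$values[ds$mask[, "x2"], "x2"])
  obs_se <- sd(ds$values[ds$mask[, "x2"], "x2"]) / sqrt(sum(ds$mask[, "x2"]))
  imp_means <- vapply(mi$completed, function(d) mean(d$values[, "x2"]), 1.0)
  expect_lt(abs(mean(imp_means) - obs_mean), 3 * obs_se)
})

test_that("the drift flag stays quiet on settled chains and fires on drifting ones", {
  # settled: well-specified MCAR at adequate n -> few flags over seeds
  flag_rate <- mean(sapply(1:6, function(s) {
    ds <- make_missing_study(n = 3000, seed = 600 + s, fraction = 0.25)
    mi <- fit_chained_imputation(ds, imputation_config(m = 2, burn_in = 10,
                                                       seed = s))
    cd <- convergence_diagnostics(mi)
    mean(cd$flagged)
  }))
  expect_lte(flag_rate, 0.10)

  # drifting: a trace whose last three cycle means still move by more than
  # 0.2 pooled SDs must be flagged
  drifting <- data.frame(variable = "x1", cycle = 1:10,
                         mean = seq(0, 2.7, length.out = 10), sd = 1)
  fake_mi <- list(traces = list(drifting))
  cd <- convergence_diagnostics(fake_mi)
  expect_true(cd$flagged)
  # and the same trace with a settled tail is not
  settled <- drifting
  settled$mean[8:10] <- c(2.70, 2.71, 2.70)
  cd2 <- convergence_diagnostics(list(traces = list(settled)))
  expect_false(cd2$flagged)
})

test_that("grouped chains impute independently per level and validate size", {
  set.seed(30)
  n <- 200
  g <- rep(c(0, 1), each = n / 2)
  x1 <- rnorm(n, mean = 3 * g)     # group shifts the marginal strongly
  x2 <- rnorm(n)
  y <- rbinom(n, 1, 0.3)
  meta <- data.frame(name = c("y", "x1", "x2", "g"),
                     kind = c("binary", "continuous", "continuous", "binary"),
                     role = c("outcome", "predictor", "predictor", "group"))
  ds <- survey_dataset(cbind(y = y, x1 = x1, x2 = x2, g = g), meta)
  ds$values[sample(n, 50), "x1"] <- NA
  ds$mask <- !is.na(ds$values)
  mi <- fit_chained_imputation(
    ds, imputation_config(m = 2, burn_in = 5,
                          predictors = c("x1", "x2"), group_by = "g",
                          seed = 9))
  d <- mi$completed[[1]]
  imp_cells <- !ds$mask[, "x1"]
  m0 <- mean(d$values[imp_cells & g == 0, "x1"])
  m1 <- mean(d$values[imp_cells & g == 1, "x1"])
  expect_gt(m1 - m0, 1.5)          # group levels keep their own marginals

  # a level below the minimum size is rejected
  ds_small <- ds_small_group(ds, g)
  expect_error(
    fit_chained_imputation(ds_small,
                           imputation_config(m = 1,
                                             predictors = c("x1", "x2"),
                                             group_by = "g", seed = 1)),
    "fewer than 30")
})

test_that("a variable with zero observed values is a configuration error", {
  ds <- make_missing_study(n = 100, seed = 40)
  ds$values[, "x3"] <- NA
  ds$mask <- !is.na(ds$values)
  expect_error(fit_chained_imputation(ds, imputation_config(m = 1, seed = 1)),
               "zero observed")
})
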