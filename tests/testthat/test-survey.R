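# Design-based logistic regression, Rubin pooling, the design-adjusted
# goodness-of-fit test.

# a 15-strata / 31-PSU design (one stratum has 3 PSUs), the shape used for
# the goodness-of-fit degrees-of-freedom checks
make_15_31 <- function(n = 1500, seed = 1, betas = c(0.5, 0.3)) {
  set.seed(seed)
  p <- length(betas)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  strata <- rep(1:15, length.out = n)
  psu <- rep(1:2, each = 15, length.out = n)
  extra <- which(strata == 1)
  psu[extra[seq(1, length(extra), 3)]] <- 3L     # stratum 1 gains a third PSU
  y <- rbinom(n, 1, plogis(-1 + X %*% betas))
  w <- exp(rnorm(n, 0, 0.4))
  meta <- data.frame(name = c("y", colnames(X)),
                     kind = c("binary", rep("continuous", p)),
                     role = c("outcome", rep("predictor", p)))
  survey_dataset(cbind(y = y, X), meta, weights = w, strata = strata,
                 psu = psu)
}

test_that("with a degenerate design the fit equals ordinary logistic MLE", {
  set.seed(5)
  n <- 400
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * X[, 1]))
  fit <- svy_logit(X, y)
  ml <- glm(y ~ X, family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(ml)), tolerance = 1e-8)

  # SEs within a factor sqrt(n/(n-1)) of the HC0 sandwich
  Xi <- cbind(1, X)
  p <- fitted(ml)
  A <- crossprod(Xi * (p * (1 - p)), Xi)
  meat <- crossprod(Xi * (y - p))
  hc0 <- sqrt(diag(solve(A) %*% meat %*% solve(A)))
  ratio <- fit$se / hc0
  expect_true(all(ratio > 0.999 & ratio < sqrt(n / (n - 1)) + 1e-3))

  # weighted score is zero at the solution
  u <- colSums(Xi * (y - logistic(drop(Xi %*% fit$coefficients))))
  expect_lt(max(abs(u)), 1e-6)
})

test_that("rescaling all weights leaves coefficients and SEs unchanged", {
  ds <- make_15_31(seed = 2)
  f1 <- fit_survey_logistic(ds, c("x1", "x2"))
  ds2 <- ds
  ds2$weights <- 2 * ds$weights
  f2 <- fit_survey_logistic(ds2, c("x1", "x2"))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
  # covariance is symmetric positive semi-definite
  ev <- eigen(f1$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(f1$design_df, 31 - 15)
})

test_that("subpopulation estimation matches the domain's coefficients and keeps the design", {
  ds <- make_15_31(n = 2000, seed = 3)
  dom <- ds$ids[seq(1, 2000, 2)]
  f_dom <- fit_survey_logistic(ds, c("x1", "x2"), subpop = dom)
  sub_rows <- ds$ids %in% dom
  ml <- glm(outcome_values(ds)[sub_rows] ~ ds$values[sub_rows, c("x1", "x2")],
            weights = ds$weights[sub_rows], family = quasibinomial)
  expect_equal(unname(f_dom$coefficients), unname(coef(ml)), tolerance = 1e-6)
  expect_equal(f_dom$design_df, 16)    # full design retained
  expect_equal(f_dom$n, length(dom))
})

test_that("single-PSU strata error by default and can be collapsed", {
  ds <- make_15_31(n = 1500, seed = 4)
  # orphan one stratum: relabel so stratum 15 has a single PSU
  one <- which(ds$strata == 15 & ds$psu == 2)
  ds$strata[one] <- 16L
  expect_error(fit_survey_logistic(ds, "x1"), "single PSU")
  expect_message(f <- fit_survey_logistic(ds, "x1",
                                          collapse_single_psu = TRUE),
                 "collapsed")
  expect_s3_class(f, "svy_logit_fit")
})

test_that("separation and single-class domains raise informative errors", {
  set.seed(6)
  x <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1,
              dimnames = list(NULL, "x1"))
  y <- rep(c(0, 1), each = 20)
  expect_error(svy_logit(x, y), "separation")
  expect_error(svy_logit(x, rep(1, 40)), "both outcome classes")
})

test_that("Rubin pooling reproduces closed-form toy arithmetic", {
  mk <- function(b, s, terms = "t1") {
    structure(list(coefficients = setNames(b, terms),
                   se = setNames(s, terms), design_df = 16),
              class = "svy_logit_fit")
  }
  pooled <- pool_rubin(list(mk(1, 1), mk(3, 1)), complete_data_df = 16)
  expect_equal(unname(pooled$qbar), 2)
  expect_equal(unname(pooled$W), 1)
  expect_equal(unname(pooled$B), 2)
  expect_equal(unname(pooled$T), 4)

  # m identical fits: B = 0, T = W, estimate unchanged, df = nu_obs
  same <- pool_rubin(list(mk(1.2, 0.4), mk(1.2, 0.4), mk(1.2, 0.4)),
                     complete_data_df = 16)
  expect_equal(unname(same$B), 0)
  expect_equal(unname(same$T), unname(same$W))
  expect_equal(unname(same$qbar), 1.2)

  # permutation invariance
  fits <- list(mk(0.5, 0.3), mk(0.9, 0.25), mk(0.2, 0.35))
  p1 <- pool_rubin(fits, 16)
  p2 <- pool_rubin(fits[c(3, 1, 2)], 16)
  expect_equal(p1$qbar, p2$qbar)
  expect_equal(p1$T, p2$T)
  expect_equal(p1$df, p2$df)

  # pooled df never exceeds the complete-data df or the large-sample
  # (infinite complete-data df) value, which it approaches as that df grows
  for (Bv in c(0.01, 0.1, 1, 10, 100)) {
    m <- 5
    fits <- lapply(seq_len(m), function(i)
      mk(qnorm(i / (m + 1)) * sqrt(Bv * (m - 1) / m) * 1.2, 1))
    pl <- pool_rubin(fits, complete_data_df = 16)
    expect_lte(unname(pl$df), 16 + 1e-9)
    r <- (1 + 1 / m) * pl$B / pl$W
    nu_large <- (m - 1) * (1 + 1 / r)^2
    expect_lte(unname(pl$df), unname(nu_large) + 1e-9)
    pl_big <- pool_rubin(fits, complete_data_df = 1e10)
    expect_equal(unname(pl_big$df), unname(nu_large), tolerance = 1e-4)
  }

  expect_error(pool_rubin(list(mk(1, 1), mk(1, 1, terms = "other"))),
               "same terms")
})

test_that("the design-adjusted GOF test has df (g-1, design_df-g+2)", {
  ds <- make_15_31(n = 1500, seed = 8)
  fit <- fit_survey_logistic(ds, c("x1", "x2"))
  expect_equal(fit$design_df, 16)
  gof <- gof_design_adjusted(fit, g = 10)
  expect_equal(gof$df1, 9)
  expect_equal(gof$df2, 8)
  expect_gte(gof$F, 0)
  expect_true(gof$p.value >= 0 && gof$p.value <= 1)

  gof5 <- gof_design_adjusted(fit, g = 5)
  expect_equal(gof5$df1, 4)
  expect_equal(gof5$df2, 13)
})

test_that("a saturated two-group model gives F near zero", {
  set.seed(9)
  n <- 800
  x <- rep(c(0, 1), each = n / 2)
  y <- rbinom(n, 1, ifelse(x == 1, 0.6, 0.2))
  meta <- data.frame(name = c("y", "x1"), kind = c("binary", "binary"),
                     role = c("outcome", "predictor"))
  ds <- survey_dataset(cbind(y = y, x1 = x), meta,
                       weights = rep(1, n), strata = rep(1:10, length.out = n),
                       psu = rep(1:4, each = 10, length.out = n))
  fit <- fit_survey_logistic(ds, "x1")
  gof <- suppressWarnings(gof_design_adjusted(fit, g = 2))
  expect_lt(gof$F, 1e-10)
})
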