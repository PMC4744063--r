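#' Simulation configuration for survey-structured synthetic studies
#'
#' Describes a synthetic epidemiological survey with correlated continuous
#' predictors, a sparse logistic outcome model, a stratified two-stage design
#' with unequal weights and PSU-level random intercepts, optional missingness,
#' and an optional mediation triple. Defaults emulate the structure of a
#' national health-examination survey: a few thousand records, modestly
#' correlated biomarkers, low outcome prevalence, and a
#' two-PSUs-per-stratum design.
#'
#' @param n record count.
#' @param p predictor count.
#' @param betas length-`p` vector of log-odds coefficients (on standardized
#'   predictors); zeros define the null variables.
#' @param target_prevalence marginal outcome prevalence; the intercept is
#'   solved by root finding. Ignored when `intercept` is given.
#' @param intercept fixed intercept, overrides `target_prevalence`.
#' @param correlation either a full p x p correlation matrix, or a list with
#'   `background_range = c(lo, hi)` (pairwise correlations drawn uniformly)
#'   and optional `collinear_pair_r` forcing `cor(X1, X2)`.
#' @param n_strata,psus_per_stratum survey design shape.
#' @param weight_dispersion coefficient of variation of the survey weights
#'   (log-normal); 0 gives equal weights.
#' @param cluster_sd SD of the PSU-level random intercept on the logit scale.
#' @param missingness optional list: `mechanism` (`"MCAR"`/`"MAR"`),
#'   `fraction` (per-variable, recycled), `vars` (names; default all
#'   predictors), `driver` (MAR driver column, default the outcome).
#' @param mediation optional mediation triple: the first predictor becomes a
#'   driver that affects the outcome only through the second (the mediator);
#'   a list with `strength` (driver -> mediator slope, default 0.8).
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 5000, p = 20, betas = NULL,
                       target_prevalence = 0.077, intercept = NULL,
                       correlation = list(background_range = c(0.05, 0.30)),
                       n_strata = 15, psus_per_stratum = 2,
                       weight_dispersion = 0.5, cluster_sd = 0.2,
                       missingness = NULL, mediation = NULL, seed = NULL) {
  if (is.null(betas)) betas <- rep(0, p)
  stopifnot(length(betas) == p, n >= 1, p >= 1)
  if (!is.null(missingness)) {
    fr <- missingness$fraction
    stopifnot(all(fr >= 0), all(fr < 1))
  }
  if (psus_per_stratum < 2 && n_strata > 1)
    warning("fewer than 2 PSUs per stratum: design variance df will be degenerate")
  structure(list(n = n, p = p, betas = betas,
                 target_prevalence = target_prevalence, intercept = intercept,
                 correlation = correlation, n_strata = n_strata,
                 psus_per_stratum = psus_per_stratum,
                 weight_dispersion = weight_dispersion, cluster_sd = cluster_sd,
                 missingness = missingness, mediation = mediation, seed = seed),
            class = "sim_config")
}

# Assemble a p x p correlation matrix from a background range and optional
# forced pair; redraws the background until positive definite.
build_correlation <- function(p, spec, max_tries = 100) {
  if (is.matrix(spec)) {
    if (!isSymmetric(spec) || min(eigen(spec, symmetric = TRUE,
                                        only.values = TRUE)$values) <= 1e-10)
      stop("correlation matrix must be symmetric positive-definite")
    return(spec)
  }
  rng <- spec$background_range %||% c(0.05, 0.30)
  pair_r <- spec$collinear_pair_r
  for (try in seq_len(max_tries)) {
    R <- diag(p)
    off <- stats::runif(p * (p - 1) / 2, rng[1], rng[2])
    R[upper.tri(R)] <- off
    R <- R + t(R) - diag(diag(R))
    diag(R) <- 1
    if (!is.null(pair_r) && p >= 2) R[1, 2] <- R[2, 1] <- pair_r
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > 1e-8)
      return(R)
  }
  stop("failed to assemble a positive-definite correlation matrix in ",
       max_tries, " attempts")
}

# Multivariate normal draws via Cholesky (standardized margins).
rmvnorm_chol <- function(n, R) {
  p <- ncol(R)
  matrix(stats::rnorm(n * p), n, p) %*% chol(R)
}

# Solve the intercept giving a target marginal prevalence for a logistic model
# with linear predictor offset `eta` (1-d root finding).
solve_intercept <- function(eta, target) {
  stats::uniroot(function(b0) mean(logistic(b0 + eta)) - target,
                 interval = c(-30, 30), tol = 1e-10)$root
}

#' Generate a survey-structured synthetic study with known truth
#'
#' Draws correlated standard-normal predictors, a binary outcome from a sparse
#' logistic model (with PSU-level random intercepts inducing within-cluster
#' correlation), stratified cluster design labels, unequal log-normal weights,
#' and optional missingness. If `cfg$mediation` is set, predictor 1 (the
#' driver) has its direct outcome effect forced to zero and instead feeds
#' predictor 2 (the mediator), so the driver affects the outcome only through
#' the mediator.
#'
#' @param cfg a [sim_config].
#' @return A list with `dataset` (a [survey_dataset]) and `truth` (the
#'   generating betas, intercept, true support, and mediation triple if any).
#' @export
generate_survey_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n; p <- cfg$p
    R <- build_correlation(p, cfg$correlation)
    X <- rmvnorm_chol(n, R)
    colnames(X) <- paste0("x", seq_len(p))
    betas <- cfg$betas
    mediation <- NULL
    if (!is.null(cfg$mediation)) {
      if (p < 2) stop("a mediation triple needs at least 2 predictors")
      strength <- cfg$mediation$strength %||% 0.8
      # Driver x1 -> mediator x2 -> outcome; no direct x1 -> outcome path.
      X[, 2] <- strength * X[, 1] + sqrt(max(1 - strength^2, 0.05)) * stats::rnorm(n)
      betas[1] <- 0
      if (betas[2] == 0) betas[2] <- 0.8
      mediation <- list(driver = "x1", mediator = "x2", strength = strength)
    }
    srs <- cfg$n_strata == 1 && cfg$psus_per_stratum <= 1
    if (srs) {
      # simple random sample: one stratum, each record its own PSU
      strata <- rep(1L, n)
      psu_within <- seq_len(n)
      cluster_eff <- rep(0, n)
    } else {
      n_psu <- cfg$n_strata * cfg$psus_per_stratum
      strata <- rep(seq_len(cfg$n_strata), length.out = n)
      psu_within <- rep(seq_len(cfg$psus_per_stratum), each = cfg$n_strata,
                        length.out = n)
      psu_global <- (strata - 1L) * cfg$psus_per_stratum + psu_within
      cluster_eff <- stats::rnorm(n_psu, 0, cfg$cluster_sd)[psu_global]
    }

    eta <- drop(X %*% betas) + cluster_eff
    b0 <- if (!is.null(cfg$intercept)) cfg$intercept
          else solve_intercept(eta, cfg$target_prevalence)
    y <- stats::rbinom(n, 1, logistic(b0 + eta))
    w <- if (cfg$weight_dispersion > 0) {
      s <- sqrt(log(1 + cfg$weight_dispersion^2))
      exp(stats::rnorm(n, -s^2 / 2, s))
    } else rep(1, n)

    meta <- data.frame(name = c("y", colnames(X)),
                       kind = c("binary", rep("continuous", p)),
                       role = c("outcome", rep("predictor", p)),
                       stringsAsFactors = FALSE)
    ds <- survey_dataset(cbind(y = y, X), meta, weights = w, strata = strata,
                         psu = psu_within)
    if (!is.null(cfg$missingness)) {
      ds <- inject_missingness(ds, cfg$missingness,
                               seed = derive_seed(cfg$seed, 7919L))
    }
    truth <- list(betas = stats::setNames(betas, colnames(X)), intercept = b0,
                  support = colnames(X)[betas != 0], mediation = mediation)
    list(dataset = ds, truth = truth)
  })
}

#' Generate the collinear-predictor validation simulation
#'
#' A simple random sample with six multivariate-normal predictors in which two
#' predictors are forced to correlation 0.8 (multicollinearity) while the
#' remaining pairwise correlations are drawn from a modest background range,
#' and a binary outcome follows a logistic model with either equal betas for
#' all six predictors or varying betas. Used to contrast boosted-tree
#' importance with backward stepwise selection under collinearity.
#'
#' @param variant `"equal_betas"` (all 0.3) or `"varying_betas"`
#'   (0.5, 0.4, 0.3, 0.2, 0.1, 0.05).
#' @param n sample size (default 5227).
#' @param betas optional override of the variant's coefficient vector.
#' @param intercept logistic intercept (default -1).
#' @param seed integer seed.
#' @return A list with `dataset` (simple-random-sample [survey_dataset]) and
#'   `truth`.
#' @export
generate_collinear_sim <- function(variant = c("equal_betas", "varying_betas"),
                                   n = 5227, betas = NULL, intercept = -1,
                                   seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(n >= 100)
  if (is.null(betas))
    betas <- if (variant == "equal_betas") rep(0.3, 6)
             else c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  stopifnot(length(betas) == 6)
  cfg <- sim_config(n = n, p = 6, betas = betas, intercept = intercept,
                    correlation = list(collinear_pair_r = 0.8,
                                       background_range = c(0.05, 0.30)),
                    n_strata = 1, psus_per_stratum = 1,
                    weight_dispersion = 0, cluster_sd = 0, seed = seed)
  generate_survey_study(cfg)
}

#' Delete cells under a specified missingness mechanism
#'
#' MCAR deletes cells independently with the given fraction. MAR deletes with
#' probability given by a logistic function of a fully observed driver column
#' (slope 1 per SD of the driver), with the intercept calibrated so the
#' marginal missing fraction matches the specification. Outcome and design
#' columns are never deleted.
#'
#' @param ds a [survey_dataset].
#' @param spec list with `mechanism` (`"MCAR"` or `"MAR"`), `fraction`
#'   (recycled over `vars`), `vars` (default: all predictors), and for MAR a
#'   `driver` column name (default: the outcome).
#' @param seed integer seed.
#' @return The dataset with cells deleted.
#' @export
inject_missingness <- function(ds, spec, seed = NULL) {
  mech <- toupper(spec$mechanism %||% "MCAR")
  vars <- spec$vars %||% predictor_names(ds)
  if (outcome_name(ds) %in% vars)
    stop("configuration error: the outcome cannot be made missing")
  stopifnot(all(vars %in% colnames(ds$values)))
  frac <- rep_len(spec$fraction, length(vars))
  stopifnot(all(frac >= 0), all(frac < 1))
  with_seed(seed, {
    vals <- ds$values
    n <- nrow(vals)
    if (mech == "MCAR") {
      for (j in seq_along(vars)) {
        if (frac[j] == 0) next
        del <- stats::runif(n) < frac[j]
        vals[del, vars[j]] <- NA_real_
      }
    } else if (mech == "MAR") {
      driver <- spec$driver %||% outcome_name(ds)
      if (anyNA(ds$values[, driver]))
        stop("MAR driver column has missing cells")
      z <- ds$values[, driver]
      s <- stats::sd(z)
      z <- if (is.na(s) || s == 0) rep(0, n) else (z - mean(z)) / s
      for (j in seq_along(vars)) {
        if (frac[j] == 0) next
        # calibrate the intercept so the marginal deletion rate hits frac[j]
        a <- solve_intercept(z, frac[j])
        del <- stats::runif(n) < logistic(a + z)
        vals[del, vars[j]] <- NA_real_
      }
    } else stop("unknown missingness mechanism: ", mech)
    ds_replace_values(ds, vals)
  })
}
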