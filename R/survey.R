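#' Design-based logistic regression with Taylor-linearized variance
#'
#' Fits a weighted logistic regression by pseudo-maximum likelihood (IRLS) and
#' estimates the coefficient covariance by Taylor linearization for a
#' stratified cluster sample: score totals are aggregated to primary sampling
#' units, centered within strata, and combined with the `n_h/(n_h - 1)`
#' small-sample factor (with-replacement first-stage approximation, no
#' finite-population correction). Inference uses the t distribution with
#' design degrees of freedom `#PSUs - #strata`.
#'
#' A subpopulation (domain) is handled the standard way: score contributions
#' outside the domain are zeroed while every PSU stays in the variance
#' computation, so domain estimation does not distort the design.
#'
#' @param x numeric model matrix (no intercept column; one is added).
#' @param y binary 0/1 response.
#' @param weights positive survey weights.
#' @param strata,psu design labels (PSUs nested in strata). Defaults describe
#'   a simple random sample.
#' @param domain optional logical subpopulation indicator.
#' @param collapse_single_psu if `TRUE`, strata containing a single PSU are
#'   merged into one combined stratum (with a message) instead of erroring.
#' @param max_iter,tol IRLS iteration cap and score-change tolerance.
#' @return An object of class `svy_logit_fit`: coefficients, linearized
#'   covariance, SEs, t-based p-values, odds ratios with 95% CIs, design df,
#'   fitted probabilities and convergence flag.
#' @export
svy_logit <- function(x, y, weights = NULL, strata = NULL, psu = NULL,
                      domain = NULL, collapse_single_psu = FALSE,
                      max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  n <- length(y)
  stopifnot(nrow(x) == n)
  weights <- weights %||% rep(1, n)
  strata <- strata %||% rep(1L, n)
  psu <- psu %||% seq_len(n)
  domain <- domain %||% rep(TRUE, n)
  stopifnot(length(weights) == n, length(strata) == n, length(psu) == n,
            length(domain) == n)

  X <- cbind(`(Intercept)` = 1, x)
  d <- as.numeric(domain)
  wd <- weights * d
  yy <- y[domain]
  if (all(yy == 1) || all(yy == 0))
    stop("both outcome classes must be present in the analysis domain")

  # constant columns within the domain are inestimable
  for (j in seq(2, ncol(X))) {
    v <- X[domain, j]
    if (max(v) == min(v))
      stop("term '", colnames(X)[j], "' is constant within the analysis domain")
  }

  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- logistic(eta)
    mu_w <- wd * p * (1 - p)
    score <- crossprod(X, wd * (y - p))
    info <- crossprod(X * mu_w, X)
    step <- tryCatch(solve(info, score), error = function(e)
      solve(info + diag(1e-8, ncol(X)), score))
    beta <- beta + drop(step)
    if (any(abs(beta) > 15))
      stop("separation detected: |coefficient| > 15 for term '",
           colnames(X)[which.max(abs(beta))], "'")
    if (max(abs(score)) < tol * max(1, sum(wd))) { converged <- TRUE; break }
  }
  if (!converged) stop("survey logistic regression did not converge in ",
                       max_iter, " iterations")

  eta <- drop(X %*% beta)
  p <- logistic(eta)
  u <- X * (wd * (y - p))                  # score contributions (0 off-domain)
  A <- crossprod(X * (wd * p * (1 - p)), X)

  # PSU totals of score contributions, centered within strata
  key <- paste(strata, psu, sep = "\r")
  z <- rowsum(u, key)
  z_str <- strata[match(rownames(z), key)]
  n_h <- table(z_str)
  if (any(n_h < 2)) {
    if (!collapse_single_psu)
      stop("stratum with a single PSU: variance is not estimable ",
           "(set collapse_single_psu = TRUE to merge such strata)")
    singles <- names(n_h)[n_h < 2]
    z_str[z_str %in% singles] <- "collapsed"
    message("collapsed ", length(singles), " single-PSU strata for variance")
    n_h <- table(z_str)
    if (any(n_h < 2)) stop("cannot collapse: only single-PSU strata present")
  }
  B <- matrix(0, ncol(X), ncol(X))
  for (h in names(n_h)) {
    zh <- z[z_str == h, , drop = FALSE]
    zc <- sweep(zh, 2, colMeans(zh))
    B <- B + (nrow(zh) / (nrow(zh) - 1)) * crossprod(zc)
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2

  design_df <- design_degrees_of_freedom(strata, psu)
  se <- sqrt(pmax(diag(V), 0))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = design_df)
  tcrit <- stats::qt(0.975, df = design_df)
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = V, se = stats::setNames(se, colnames(X)),
                 t = tval, p.value = stats::setNames(pval, colnames(X)),
                 or = exp(beta), ci_low = exp(beta - tcrit * se),
                 ci_high = exp(beta + tcrit * se),
                 design_df = design_df, n = sum(domain),
                 fitted = p, converged = converged,
                 strata = strata, psu = psu, weights = weights,
                 domain = as.logical(domain), y = y),
            class = "svy_logit_fit")
}

#' @export
print.svy_logit_fit <- function(x, ...) {
  cat("<svy_logit_fit> n =", x$n, " design df =", x$design_df, "\n")
  print(data.frame(OR = round(x$or, 4), SE = round(x$se, 4),
                   p = signif(x$p.value, 3),
                   ci_low = round(x$ci_low, 4), ci_high = round(x$ci_high, 4)))
  invisible(x)
}

# Build a model matrix from named terms over a survey_dataset's value table.
# A term is a column name or an `a:b` product of two columns.
term_matrix <- function(ds, terms) {
  vals <- ds$values
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% colnames(vals)))
      stop("unknown term component in '", tm, "'")
    Reduce(`*`, lapply(parts, function(p) vals[, p]))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  if (anyNA(m)) stop("terms contain missing cells; fit on completed data")
  m
}

#' Design-based logistic regression on a survey dataset
#'
#' Convenience wrapper around [svy_logit()] taking term names (column names,
#' or `a:b` interaction products) from a [survey_dataset].
#'
#' @param ds a completed [survey_dataset] (no missing cells among `terms`).
#' @param terms character vector of term names.
#' @param subpop optional logical domain indicator (length `n`), or a vector
#'   of record ids defining the domain.
#' @param ... passed to [svy_logit()].
#' @return A `svy_logit_fit`.
#' @export
fit_survey_logistic <- function(ds, terms, subpop = NULL, ...) {
  if (!is.null(subpop) && !is.logical(subpop)) subpop <- ds$ids %in% subpop
  svy_logit(term_matrix(ds, terms), outcome_values(ds), weights = ds$weights,
            strata = ds$strata, psu = ds$psu, domain = subpop, ...)
}

#' Pool design-based fits across imputations by Rubin's rules
#'
#' Combines `m` repeated-analysis fits: pooled coefficient `Q̄` (the mean),
#' within-imputation variance `W` (mean squared SE), between-imputation
#' variance `B`, total variance `T = W + (1 + 1/m) B`, and the
#' Barnard-Rubin small-sample degrees of freedom computed against
#' `complete_data_df` (by survey convention, the design df).
#'
#' @param fits list of `svy_logit_fit` objects sharing the same terms.
#' @param complete_data_df complete-data degrees of freedom; defaults to the
#'   common design df of the fits.
#' @return An object of class `pooled_fit` with per-term `qbar`, `W`, `B`,
#'   `T`, pooled df, SE, p-value, and OR with 95% CI.
#' @export
pool_rubin <- function(fits, complete_data_df = NULL) {
  m <- length(fits)
  stopifnot(m >= 1)
  terms <- names(fits[[1]]$coefficients)
  for (f in fits)
    if (!identical(names(f$coefficients), terms))
      stop("all fits must share the same terms")
  complete_data_df <- complete_data_df %||% fits[[1]]$design_df
  Q <- do.call(rbind, lapply(fits, function(f) f$coefficients))
  U <- do.call(rbind, lapply(fits, function(f) f$se^2))
  qbar <- colMeans(Q)
  W <- colMeans(U)
  B <- if (m > 1) apply(Q, 2, stats::var) else rep(0, length(qbar))
  Tv <- W + (1 + 1 / m) * B
  r <- ifelse(W > 0, (1 + 1 / m) * B / W, Inf)
  nu_large <- ifelse(r > 0, (m - 1) * (1 + 1 / r)^2, Inf)
  cdf <- complete_data_df
  nu_obs <- ((cdf + 1) / (cdf + 3)) * cdf * (1 / (1 + r))
  df <- ifelse(is.finite(nu_large), 1 / (1 / nu_large + 1 / nu_obs), nu_obs)
  if (m == 1) { Tv <- W; df <- rep(cdf, length(qbar)) }
  se <- sqrt(Tv)
  tval <- qbar / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  tcrit <- stats::qt(0.975, df = df)
  structure(list(terms = terms, qbar = qbar, W = W, B = B, T = Tv,
                 df = df, se = se, p.value = stats::setNames(pval, terms),
                 or = exp(qbar), ci_low = exp(qbar - tcrit * se),
                 ci_high = exp(qbar + tcrit * se), m = m,
                 complete_data_df = cdf),
            class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat("<pooled_fit> m =", x$m, " complete-data df =", x$complete_data_df, "\n")
  print(data.frame(OR = round(x$or, 4), SE = round(x$se, 4),
                   p = signif(x$p.value, 3), df = round(x$df, 1),
                   ci_low = round(x$ci_low, 4), ci_high = round(x$ci_high, 4),
                   row.names = x$terms))
  invisible(x)
}

#' Design-adjusted goodness-of-fit F test
#'
#' The survey analogue of the Hosmer-Lemeshow test: records are grouped into
#' `g` weighted quantile groups of predicted probability, the group mean
#' residuals are tested jointly with a design-based Wald statistic, and the
#' statistic is converted to an F with `(g - 1, design_df - g + 2)` degrees of
#' freedom.
#'
#' @param fit a `svy_logit_fit`.
#' @param g number of probability groups (default 10, giving the familiar
#'   9 numerator df).
#' @return An object of class `svy_gof`: `F`, `df1`, `df2`, `p.value`, `g`.
#' @export
gof_design_adjusted <- function(fit, g = 10) {
  stopifnot(g >= 2)
  dom <- fit$domain
  w <- fit$weights * dom
  p <- fit$fitted
  r <- fit$y - p
  design_df <- fit$design_df
  if (design_df - g + 2 < 1)
    stop("design df too small for ", g, " groups")

  # weighted quantile breaks of fitted probability within the domain
  ord <- order(p)
  cw <- cumsum(w[ord]) / sum(w)
  probs <- seq_len(g - 1) / g
  breaks <- p[ord][vapply(probs, function(q) which(cw >= q)[1], 1L)]
  breaks <- unique(c(-Inf, breaks, Inf))
  if (length(breaks) - 1 < g) {
    warning("empty probability group(s): reducing g to ", length(breaks) - 1)
    g <- length(breaks) - 1
    if (g < 2) stop("fewer than 2 distinct probability groups")
    if (design_df - g + 2 < 1) stop("design df too small after reducing g")
  }
  grp <- cut(p, breaks, labels = FALSE)

  # weighted mean residual in the first g-1 groups (the g-th is redundant:
  # weighted residuals sum to ~0 at the pseudo-MLE)
  k <- g - 1
  m <- numeric(k)
  W_k <- numeric(k)
  for (j in seq_len(k)) {
    sel <- grp == j
    W_k[j] <- sum(w[sel])
    m[j] <- sum(w[sel] * r[sel]) / W_k[j]
  }
  # linearized contributions of each group mean (ratio estimator)
  e <- matrix(0, length(r), k)
  for (j in seq_len(k)) {
    sel <- grp == j
    e[sel, j] <- w[sel] * (r[sel] - m[j]) / W_k[j]
  }
  key <- paste(fit$strata, fit$psu, sep = "\r")
  z <- rowsum(e, key)
  z_str <- fit$strata[match(rownames(z), key)]
  V <- matrix(0, k, k)
  for (h in unique(z_str)) {
    zh <- z[z_str == h, , drop = FALSE]
    zc <- sweep(zh, 2, colMeans(zh))
    V <- V + (nrow(zh) / (nrow(zh) - 1)) * crossprod(zc)
  }
  wald <- tryCatch(drop(t(m) %*% solve(V, m)), error = function(e) {
    if (max(abs(m)) < 1e-10) 0 else drop(t(m) %*% MASS_ginv(V) %*% m)
  })
  df1 <- k
  df2 <- design_df - g + 2
  Fstat <- wald * (design_df - k + 1) / (design_df * k)
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  structure(list(F = Fstat, df1 = df1, df2 = df2, p.value = pval, g = g,
                 group_residuals = m),
            class = "svy_gof")
}

#' @export
print.svy_gof <- function(x, ...) {
  cat(sprintf("<svy_gof> F(%d, %d) = %.3f, p = %.4f (g = %d groups)\n",
              x$df1, x$df2, x$F, x$p.value, x$g))
  invisible(x)
}

# Moore-Penrose pseudo-inverse (only used when the GOF covariance is singular
# with nonzero residual means).
MASS_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
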