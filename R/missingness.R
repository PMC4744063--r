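#' Missing-indicator association tests
#'
#' For each predictor with missing cells, creates a missingness indicator
#' (1 = missing, 0 = observed) and regresses it on the study outcome with a
#' design-based logistic regression. A significant association means the
#' probability of being missing depends on the outcome, i.e. the data are not
#' missing completely at random with respect to the outcome, supporting
#' imputation. Predictors with no missing cells (or with a constant
#' indicator) are reported as not applicable.
#'
#' These tests are run on the original (pre-imputation) data: diagnosing the
#' missingness mechanism after imputation would be circular.
#'
#' @param ds a [survey_dataset].
#' @param vars candidate predictors (default: all `predictor` columns).
#' @return A data frame with one row per candidate: missing fraction,
#'   outcome-coefficient estimate, SE, p-value, and an `applicable` flag.
#' @export
missing_indicator_tests <- function(ds, vars = NULL) {
  vars <- vars %||% predictor_names(ds)
  y <- outcome_values(ds)
  rows <- lapply(vars, function(v) {
    ind <- as.numeric(!ds$mask[, v])
    frac <- mean(ind)
    if (frac == 0 || frac == 1)
      return(data.frame(variable = v, missing_fraction = frac,
                        estimate = NA_real_, se = NA_real_, p.value = NA_real_,
                        applicable = FALSE))
    fit <- tryCatch(
      svy_logit(matrix(y, ncol = 1, dimnames = list(NULL, "outcome")),
                ind, weights = ds$weights, strata = ds$strata, psu = ds$psu),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(variable = v, missing_fraction = frac,
                        estimate = NA_real_, se = NA_real_, p.value = NA_real_,
                        applicable = FALSE))
    data.frame(variable = v, missing_fraction = frac,
               estimate = fit$coefficients["outcome"],
               se = fit$se["outcome"], p.value = fit$p.value["outcome"],
               applicable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Little's MCAR chi-squared test
#'
#' Tests the null hypothesis that the data are missing completely at random.
#' The grand mean and covariance are estimated by EM under multivariate
#' normality; records are grouped by missingness pattern, and the statistic
#' \deqn{d^2 = \sum_j n_j (\bar y_j - \hat\mu_j)^\top \hat\Sigma_j^{-1}
#'       (\bar y_j - \hat\mu_j)}
#' sums, over patterns, the Mahalanobis distance of the pattern's observed
#' means from the EM estimates restricted to the pattern's observed
#' coordinates, with degrees of freedom \eqn{\sum_j p_j - p}. A significant
#' result rejects MCAR.
#'
#' @param values numeric matrix (n records x p columns); `NA` marks missing.
#'   Binary 0/1 columns are treated as numeric.
#' @param tol relative log-likelihood convergence tolerance for EM.
#' @param max_iter EM iteration cap.
#' @return A list of class `little_mcar`: `d2`, `df`, `p.value`, EM estimates
#'   `mu` and `sigma`, `iterations`, `converged`.
#' @export
littles_mcar_test <- function(values, tol = 1e-8, max_iter = 500) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  p <- ncol(values)
  obs <- !is.na(values)
  keep <- rowSums(obs) > 0
  values <- values[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  n <- nrow(values)
  if (n < 2) stop("need at least 2 records with observed data")

  em <- em_mvnorm(values, obs, tol = tol, max_iter = max_iter)

  pat <- apply(obs, 1, function(o) paste(as.integer(o), collapse = ""))
  d2 <- 0
  df <- -p
  for (pt in unique(pat)) {
    rows <- pat == pt
    o <- obs[which(rows)[1], ]
    nj <- sum(rows)
    pj <- sum(o)
    df <- df + pj
    ybar <- colMeans(values[rows, o, drop = FALSE])
    diff <- ybar - em$mu[o]
    Soo <- em$sigma[o, o, drop = FALSE]
    Sinv <- tryCatch(solve(Soo), error = function(e) {
      warning("singular covariance sub-block: ridge-stabilized inverse used")
      solve(Soo + diag(1e-8 * mean(diag(Soo)), pj))
    })
    d2 <- d2 + nj * drop(t(diff) %*% Sinv %*% diff)
  }
  df <- max(df, 0L)
  pval <- if (df == 0) NA_real_ else stats::pchisq(d2, df, lower.tail = FALSE)
  structure(list(d2 = d2, df = df, p.value = pval, mu = em$mu,
                 sigma = em$sigma, iterations = em$iterations,
                 converged = em$converged, loglik = em$loglik),
            class = "little_mcar")
}

#' @export
print.little_mcar <- function(x, ...) {
  cat(sprintf("<little_mcar> d2 = %.3f, df = %d, p = %s (EM: %d iterations)\n",
              x$d2, x$df,
              if (is.na(x$p.value)) "NA" else sprintf("%.4g", x$p.value),
              x$iterations))
  invisible(x)
}

# EM for the mean and (ML) covariance of a multivariate normal with values
# missing at random. Initialization: complete-case moments, falling back to
# available-case moments when fewer than 10 complete cases. The observed-data
# log-likelihood is checked to be non-decreasing at every iteration.
em_mvnorm <- function(values, obs, tol = 1e-8, max_iter = 500) {
  n <- nrow(values); p <- ncol(values)
  complete <- rowSums(obs) == p
  if (sum(complete) >= 10) {
    mu <- colMeans(values[complete, , drop = FALSE])
    sigma <- stats::cov(values[complete, , drop = FALSE]) * (sum(complete) - 1) /
      sum(complete)
  } else {
    mu <- colMeans(values, na.rm = TRUE)
    sigma <- stats::cov(values, use = "pairwise.complete.obs")
    sigma[is.na(sigma)] <- 0
  }
  # guard a degenerate start
  if (any(!is.finite(mu))) mu[!is.finite(mu)] <- 0
  if (any(!is.finite(sigma))) sigma[!is.finite(sigma)] <- 0
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
    sigma <- sigma + diag(1e-6, p)

  pat <- apply(obs, 1, function(o) paste(as.integer(o), collapse = ""))
  pat_rows <- split(seq_len(n), pat)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    S1 <- numeric(p)
    S2 <- matrix(0, p, p)
    ll <- 0
    for (rows in pat_rows) {
      o <- obs[rows[1], ]
      Y <- values[rows, , drop = FALSE]
      nj <- length(rows)
      if (all(o)) {
        S1 <- S1 + colSums(Y)
        S2 <- S2 + crossprod(Y)
        ll <- ll + mvn_loglik(Y, mu, sigma)
        next
      }
      oo <- which(o); mm <- which(!o)
      Soo <- sigma[oo, oo, drop = FALSE]
      Som <- sigma[oo, mm, drop = FALSE]
      Smm <- sigma[mm, mm, drop = FALSE]
      Soo_inv <- solve_psd(Soo)
      Yo <- Y[, oo, drop = FALSE]
      ll <- ll + mvn_loglik(Yo, mu[oo], Soo)
      # conditional mean of the missing block given the observed block
      Ym <- matrix(mu[mm], nj, length(mm), byrow = TRUE) +
        sweep(Yo, 2, mu[oo]) %*% Soo_inv %*% Som
      C <- Smm - t(Som) %*% Soo_inv %*% Som     # conditional covariance
      Yfull <- matrix(0, nj, p)
      Yfull[, oo] <- Yo
      Yfull[, mm] <- Ym
      S1 <- S1 + colSums(Yfull)
      cp <- crossprod(Yfull)
      cp[mm, mm] <- cp[mm, mm] + nj * C
      S2 <- S2 + cp
    }
    mu_new <- S1 / n
    sigma_new <- S2 / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    if (ll < ll_old - 1e-8 * (abs(ll_old) + 1))
      stop("EM log-likelihood decreased: numerical failure")
    done <- is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)
    mu <- mu_new; sigma <- sigma_new
    if (done) { converged <- TRUE; break }
    if (it >= max_iter) break
    ll_old <- ll
  }
  if (!converged)
    stop("EM did not converge in ", max_iter,
         " iterations (last log-likelihood ", signif(ll, 8), ")")
  list(mu = mu, sigma = sigma, iterations = it, converged = converged,
       loglik = ll)
}

solve_psd <- function(S) {
  tryCatch(solve(S), error = function(e)
    solve(S + diag(1e-8 * (mean(diag(S)) + 1), ncol(S))))
}

mvn_loglik <- function(Y, mu, S) {
  k <- ncol(Y)
  ch <- tryCatch(chol(S), error = function(e) chol(S + diag(1e-8, k)))
  logdet <- 2 * sum(log(diag(ch)))
  Z <- sweep(Y, 2, mu) %*% backsolve(ch, diag(k))
  -0.5 * (nrow(Y) * (k * log(2 * pi) + logdet) + sum(Z^2))
}

#' Missingness report: indicator tests plus Little's MCAR test
#'
#' Convenience wrapper bundling [missing_indicator_tests()] and
#' [littles_mcar_test()] (run on the predictor columns) into one report.
#'
#' @param ds a [survey_dataset].
#' @param ... passed to [littles_mcar_test()].
#' @return A list of class `missingness_report` with `indicator_tests` and
#'   `little`.
#' @export
missingness_report <- function(ds, ...) {
  preds <- predictor_names(ds)
  vals <- ds$values[, preds, drop = FALSE]
  little <- if (sum(!ds$mask[, preds]) > 0)
    littles_mcar_test(vals, ...) else NULL
  structure(list(indicator_tests = missing_indicator_tests(ds),
                 little = little),
            class = "missingness_report")
}

#' @export
print.missingness_report <- function(x, ...) {
  cat("<missingness_report>\n")
  if (!is.null(x$little)) print(x$little) else cat("  no missing cells\n")
  tab <- x$indicator_tests
  tab <- tab[tab$applicable, , drop = FALSE]
  if (nrow(tab)) {
    cat("  indicator tests (missingness ~ outcome):",
        sum(tab$p.value < 0.05), "of", nrow(tab), "significant at 0.05\n")
  }
  invisible(x)
}
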