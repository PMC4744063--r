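#' Configuration for multiple imputation by chained equations
#'
#' @param m number of imputed datasets (default 20).
#' @param burn_in chained-equation cycles per imputation before a completed
#'   copy is emitted (default 10).
#' @param predictors variables used in the conditional imputation models
#'   (default: every `predictor` and `covariate` column). The outcome is not
#'   included by default.
#' @param group_by optional fully observed binary/categorical column; chains
#'   run separately within each level (e.g. imputing males and females
#'   separately).
#' @param ridge small ridge added to the conditional-model normal equations,
#'   stabilising near-collinear biomarker panels.
#' @param seed integer master seed; per-imputation seeds are derived from it.
#' @return A list of class `imputation_config`.
#' @export
imputation_config <- function(m = 20, burn_in = 10, predictors = NULL,
                              group_by = NULL, ridge = 1e-5, seed = NULL) {
  stopifnot(m >= 1, burn_in >= 1, ridge >= 0)
  structure(list(m = m, burn_in = burn_in, predictors = predictors,
                 group_by = group_by, ridge = ridge, seed = seed),
            class = "imputation_config")
}

#' Multiple imputation by chained equations
#'
#' Fills missing cells by cycling variable-wise conditional regressions
#' (fully conditional specification): Bayesian linear regression for
#' continuous variables, logistic regression with a posterior coefficient
#' draw for binary variables. Each imputation chain initialises missing cells
#' with random draws from the observed marginal, visits variables in
#' ascending missing-count order for `burn_in` cycles, and then emits a
#' completed copy. Parameter draws make the imputations "proper" so that
#' Rubin's rules give valid pooled inference. Chains are independent across
#' imputations and across `group_by` levels.
#'
#' @param ds a [survey_dataset].
#' @param cfg an [imputation_config].
#' @return An object of class `multiple_imputation`: the original dataset,
#'   `m` completed copies, per-chain trace summaries and the seeds used.
#' @export
fit_chained_imputation <- function(ds, cfg = imputation_config()) {
  stopifnot(inherits(cfg, "imputation_config"))
  preds <- cfg$predictors %||%
    ds$meta$name[ds$meta$role %in% c("predictor", "covariate")]
  stopifnot(all(preds %in% colnames(ds$values)))
  miss_count <- colSums(!ds$mask[, preds, drop = FALSE])
  impute_vars <- preds[miss_count > 0]
  zero_obs <- preds[colSums(ds$mask[, preds, drop = FALSE]) == 0]
  if (length(zero_obs))
    stop("configuration error: variable(s) with zero observed values: ",
         paste(zero_obs, collapse = ", "))
  visit_order <- impute_vars[order(miss_count[miss_count > 0])]

  groups <- if (is.null(cfg$group_by)) list(seq_len(n_records(ds))) else {
    gv <- ds$values[, cfg$group_by]
    if (anyNA(gv)) stop("group_by column has missing cells")
    gl <- split(seq_len(n_records(ds)), gv)
    small <- vapply(gl, length, 1L) < 30
    if (any(small))
      stop("group_by level(s) with fewer than 30 records: ",
           paste(names(gl)[small], collapse = ", "))
    gl
  }
  kinds <- stats::setNames(ds$meta$kind, ds$meta$name)

  completed <- vector("list", cfg$m)
  traces <- vector("list", cfg$m)
  seeds <- vapply(seq_len(cfg$m), function(i) derive_seed(cfg$seed, i) %||%
                    NA_integer_, 1L)
  for (i in seq_len(cfg$m)) {
    seed_i <- if (is.null(cfg$seed)) NULL else seeds[i]
    res <- with_seed(seed_i,
      run_chain(ds, preds, visit_order, groups, kinds, cfg$burn_in, cfg$ridge))
    completed[[i]] <- ds_replace_values(ds, res$values)
    traces[[i]] <- res$trace
  }
  structure(list(original = ds, completed = completed, traces = traces,
                 seeds = seeds, config = cfg, imputed_vars = visit_order),
            class = "multiple_imputation")
}

#' @export
print.multiple_imputation <- function(x, ...) {
  cat("<multiple_imputation> m =", length(x$completed), "| imputed variables:",
      length(x$imputed_vars), "| n =", n_records(x$original), "\n")
  invisible(x)
}

# One chained-equation run over all groups; returns the completed value matrix
# and a per-cycle trace of imputed-cell means/SDs.
run_chain <- function(ds, preds, visit_order, groups, kinds, burn_in, ridge) {
  vals <- ds$values
  mask <- ds$mask
  trace <- list()
  for (rows in groups) {
    V <- vals[rows, , drop = FALSE]
    M <- mask[rows, , drop = FALSE]
    # initialize missing cells by draws from the observed marginal
    for (v in visit_order) {
      mis <- !M[, v]
      if (!any(mis)) next
      obs_vals <- V[M[, v], v]
      V[mis, v] <- sample(obs_vals, sum(mis), replace = TRUE)
    }
    for (cycle in seq_len(burn_in)) {
      for (v in visit_order) {
        mis <- !M[, v]
        if (!any(mis)) next
        rhs <- setdiff(preds, v)
        X <- cbind(1, V[, rhs, drop = FALSE])
        yv <- V[, v]
        obs <- M[, v]
        V[mis, v] <- if (kinds[v] == "binary")
          impute_binary(X, yv, obs, mis, ridge)
        else impute_continuous(X, yv, obs, mis, ridge)
        trace[[length(trace) + 1L]] <- data.frame(
          variable = v, cycle = cycle,
          mean = mean(V[mis, v]), sd = stats::sd(V[mis, v]))
      }
    }
    vals[rows, ] <- V
  }
  tr <- if (length(trace)) do.call(rbind, trace) else
    data.frame(variable = character(), cycle = integer(),
               mean = double(), sd = double())
  # aggregate over groups: one row per (variable, cycle)
  if (nrow(tr)) {
    tr <- stats::aggregate(cbind(mean, sd) ~ variable + cycle, tr, mean)
  }
  list(values = vals, trace = tr)
}

# Bayesian linear regression draw: sigma^2 from the scaled inverse
# chi-squared, coefficients from a normal around the (ridge-stabilised)
# least-squares fit, imputations from the normal predictive distribution.
impute_continuous <- function(X, y, obs, mis, ridge) {
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  k <- ncol(Xo)
  XtX <- crossprod(Xo) + diag(ridge, k)
  XtX_inv <- tryCatch(solve(XtX), error = function(e) {
    warning("rank-deficient conditional model: extra ridge applied")
    solve(XtX + diag(1e-4 * (mean(diag(XtX)) + 1), k))
  })
  beta_hat <- drop(XtX_inv %*% crossprod(Xo, yo))
  df <- max(length(yo) - k, 1)
  rss <- sum((yo - drop(Xo %*% beta_hat))^2)
  sigma2 <- (rss + 1e-12) / stats::rchisq(1, df)
  Vchol <- tryCatch(chol(sigma2 * XtX_inv), error = function(e)
    chol(sigma2 * XtX_inv + diag(1e-10, k)))
  beta <- beta_hat + drop(t(Vchol) %*% stats::rnorm(k))
  drop(X[mis, , drop = FALSE] %*% beta) + stats::rnorm(sum(mis), 0, sqrt(sigma2))
}

# Logistic fit plus a normal coefficient draw around the MLE (approximate
# proper imputation), then Bernoulli draws at the drawn-coefficient
# probabilities.
impute_binary <- function(X, y, obs, mis, ridge) {
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  if (all(yo == yo[1])) return(rep(yo[1], sum(mis)))
  k <- ncol(Xo)
  beta <- rep(0, k)
  for (it in seq_len(50)) {
    p <- logistic(drop(Xo %*% beta))
    wgt <- pmax(p * (1 - p), 1e-8)
    info <- crossprod(Xo * wgt, Xo) + diag(ridge + 1e-8, k)
    score <- crossprod(Xo, yo - p)
    step <- drop(solve(info, score))
    beta <- beta + step
    beta <- pmin(pmax(beta, -20), 20)
    if (max(abs(step)) < 1e-8) break
  }
  p <- logistic(drop(Xo %*% beta))
  wgt <- pmax(p * (1 - p), 1e-8)
  Vinv <- crossprod(Xo * wgt, Xo) + diag(ridge + 1e-8, k)
  Vchol <- chol(tryCatch(solve(Vinv), error = function(e)
    solve(Vinv + diag(1e-6, k))))
  beta_draw <- beta + drop(t(Vchol) %*% stats::rnorm(k))
  pm <- logistic(drop(X[mis, , drop = FALSE] %*% beta_draw))
  stats::rbinom(sum(mis), 1, pm)
}

#' Stack the original and imputed datasets into one long table
#'
#' Concatenates the original dataset (set index 0) and the `m` completed
#' copies (indices 1..m) with a `_mi_id` set-index column and the original
#' record ids, giving `n * (m + 1)` rows.
#'
#' @param mi a `multiple_imputation`.
#' @return A data frame with columns `_mi_id`, `_row_id`, and every analysis
#'   variable.
#' @export
stack_imputations <- function(mi) {
  sets <- c(list(mi$original), mi$completed)
  out <- do.call(rbind, lapply(seq_along(sets), function(i) {
    d <- as.data.frame(sets[[i]]$values)
    cbind(`_mi_id` = i - 1L, `_row_id` = sets[[i]]$ids, d)
  }))
  rownames(out) <- NULL
  out
}

#' Chain convergence diagnostics
#'
#' Summarises the per-cycle trajectories of imputed-value means and SDs and
#' flags variables whose chain mean still drifts at the end of the burn-in:
#' the range of the last three cycle means exceeding 0.2 pooled (across-cycle)
#' SDs.
#'
#' @param mi a `multiple_imputation`.
#' @param drift_threshold flag threshold in pooled-SD units (default 0.2).
#' @return A data frame with one row per (imputation, variable): final mean,
#'   drift, pooled SD, and a logical `flagged`.
#' @export
convergence_diagnostics <- function(mi, drift_threshold = 0.2) {
  rows <- list()
  for (i in seq_along(mi$traces)) {
    tr <- mi$traces[[i]]
    if (!nrow(tr)) next
    for (v in unique(tr$variable)) {
      tv <- tr[tr$variable == v, ]
      tv <- tv[order(tv$cycle), ]
      last3 <- utils::tail(tv$mean, 3)
      pooled_sd <- mean(tv$sd, na.rm = TRUE)
      drift <- diff(range(last3))
      rows[[length(rows) + 1L]] <- data.frame(
        imputation = i, variable = v, final_mean = utils::tail(tv$mean, 1),
        drift = drift, pooled_sd = pooled_sd,
        flagged = is.finite(pooled_sd) && pooled_sd > 0 &&
          drift > drift_threshold * pooled_sd)
    }
  }
  if (!length(rows))
    return(data.frame(imputation = integer(), variable = character(),
                      final_mean = double(), drift = double(),
                      pooled_sd = double(), flagged = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
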