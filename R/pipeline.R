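# Step 3 of the hybrid methodology and the end-to-end pipeline: univariate
# survey-logistic screening on train/validation halves, collinearity and
# mediation elimination, the final confounder + interaction model, and the
# validation baselines (backward stepwise, L1 selection frequency).

# Pooled design-based fit of `terms` across the m completed datasets,
# optionally restricted to a subpopulation given as record ids.
pooled_subpop_fit <- function(mi, terms, subpop = NULL, ...) {
  fits <- lapply(mi$completed, fit_survey_logistic, terms = terms,
                 subpop = subpop, ...)
  pool_rubin(fits)
}

#' Univariate screening on training and validation halves
#'
#' For each candidate, fits a pooled subpopulation survey logistic regression
#' of the outcome on that candidate alone, separately on the training and the
#' validation half, and keeps candidates with pooled `p <= alpha` in both
#' halves. Boundary equality counts as significant (a candidate sitting
#' exactly at 0.05 is kept).
#'
#' @param mi a `multiple_imputation`.
#' @param candidates character vector of candidate predictors.
#' @param train_ids,validation_ids record ids from [split_train_validation()].
#' @param alpha screening level (default 0.05; no multiplicity correction, by
#'   design).
#' @return A list with `table` (per candidate: OR/SE/p in each half, decision)
#'   and `selected`.
#' @export
univariate_screen <- function(mi, candidates, train_ids, validation_ids,
                              alpha = 0.05) {
  stopifnot(length(candidates) > 0)
  rows <- lapply(candidates, function(v) {
    res <- lapply(list(train = train_ids, validation = validation_ids),
                  function(ids) {
      tryCatch(pooled_subpop_fit(mi, v, subpop = ids), error = function(e) e)
    })
    if (inherits(res$train, "error") || inherits(res$validation, "error")) {
      msg <- c(if (inherits(res$train, "error")) res$train$message,
               if (inherits(res$validation, "error")) res$validation$message)
      return(data.frame(variable = v, or_train = NA, p_train = NA,
                        or_validation = NA, p_validation = NA,
                        selected = FALSE,
                        reason = paste("fit failure:", msg[1])))
    }
    pt <- res$train$p.value[v]
    pv <- res$validation$p.value[v]
    sel <- pt <= alpha && pv <= alpha
    data.frame(variable = v,
               or_train = res$train$or[v], p_train = pt,
               or_validation = res$validation$or[v], p_validation = pv,
               selected = sel,
               reason = if (sel) "significant in both halves"
                        else "not significant in both halves")
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, selected = tab$variable[tab$selected])
}

# Pairwise weighted correlations averaged over the completed datasets.
pooled_weighted_cor <- function(mi, variables) {
  mats <- lapply(mi$completed, function(ds) {
    stats::cov.wt(ds$values[, variables, drop = FALSE], wt = ds$weights,
                  cor = TRUE)$cor
  })
  Reduce(`+`, mats) / length(mats)
}

#' Collinearity elimination
#'
#' Flags variable pairs whose pooled weighted correlation reaches
#' `r_threshold` in absolute value and, from each flagged pair, drops the
#' member with the lower mean boosting importance. Chains of mutually
#' collinear variables resolve transitively: flagged variables are removed in
#' ascending importance order until no flagged pair remains among the
#' retained set.
#'
#' @param mi a `multiple_imputation`.
#' @param variables candidate set.
#' @param importance named numeric of mean importances (used to decide which
#'   pair member is dropped); defaults to equal, dropping the later variable.
#' @param r_threshold flagging threshold (default 0.95).
#' @return A list with `pairs` (flagged pairs and r), `dropped`, `retained`.
#' @export
collinearity_check <- function(mi, variables, importance = NULL,
                               r_threshold = 0.95) {
  stopifnot(all(variables %in% colnames(mi$original$values)))
  if (length(variables) < 2)
    return(list(pairs = data.frame(), dropped = character(0),
                retained = variables))
  R <- pooled_weighted_cor(mi, variables)
  imp <- if (is.null(importance))
    stats::setNames(rev(seq_along(variables)), variables)
  else importance[variables]
  pairs <- which(abs(R) >= r_threshold & upper.tri(R), arr.ind = TRUE)
  flagged <- data.frame(
    var1 = variables[pairs[, 1]], var2 = variables[pairs[, 2]],
    r = R[pairs], stringsAsFactors = FALSE)
  retained <- variables
  dropped <- character(0)
  repeat {
    active <- flagged[flagged$var1 %in% retained & flagged$var2 %in% retained, ]
    if (!nrow(active)) break
    involved <- unique(c(active$var1, active$var2))
    worst <- involved[which.min(imp[involved])]
    dropped <- c(dropped, worst)
    retained <- setdiff(retained, worst)
  }
  list(pairs = flagged, dropped = dropped, retained = retained)
}

#' Mediation elimination
#'
#' Declares a variable X fully mediated by M when, on pooled survey fits:
#' (i) X is significant univariately (`p <= alpha`); (ii) in the joint model
#' of X and M, X is no longer significant while M is; and (iii) X and M are
#' associated (pooled weighted correlation at least `assoc_r` in absolute
#' value, or a cross-regression of X on M with `p <= alpha`). Mediated
#' variables are dropped. If two variables each appear mediated by the other,
#' neither is dropped and the pair is flagged for manual review.
#'
#' @param mi a `multiple_imputation`.
#' @param variables candidate set (>= 2 variables for a nontrivial check).
#' @param alpha significance level (default 0.05).
#' @param assoc_r association threshold for condition (iii) (default 0.3).
#' @return A list with `triples` (driver, mediator, evidence, action),
#'   `dropped`, `retained`, `circular`.
#' @export
mediation_check <- function(mi, variables, alpha = 0.05, assoc_r = 0.3) {
  if (length(variables) < 2)
    return(list(triples = data.frame(), dropped = character(0),
                retained = variables, circular = character(0)))
  uni_p <- vapply(variables, function(v)
    pooled_subpop_fit(mi, v)$p.value[v], 1.0)
  R <- pooled_weighted_cor(mi, variables)
  ds1 <- mi$completed[[1]]
  triples <- list()
  for (x in variables) {
    if (uni_p[x] > alpha) next                 # (i) fails
    for (m in setdiff(variables, x)) {
      joint <- tryCatch(pooled_subpop_fit(mi, c(x, m)),
                        error = function(e) NULL)
      if (is.null(joint)) next
      cond_ii <- joint$p.value[x] > alpha && joint$p.value[m] <= alpha
      if (!cond_ii) next
      assoc <- abs(R[x, m]) >= assoc_r
      if (!assoc) {
        cross <- stats::summary.lm(
          stats::lm(ds1$values[, x] ~ ds1$values[, m]))$coefficients
        assoc <- nrow(cross) > 1 && cross[2, 4] <= alpha
      }
      if (!assoc) next                         # (iii) fails
      triples[[length(triples) + 1L]] <- data.frame(
        driver = x, mediator = m, r = R[x, m],
        p_univariate = uni_p[x], p_joint_driver = joint$p.value[x],
        p_joint_mediator = joint$p.value[m], stringsAsFactors = FALSE)
    }
  }
  triples <- if (length(triples)) do.call(rbind, triples) else
    data.frame(driver = character(0), mediator = character(0))
  circular <- character(0)
  dropped <- character(0)
  if (nrow(triples)) {
    for (i in seq_len(nrow(triples))) {
      x <- triples$driver[i]; m <- triples$mediator[i]
      rev_hit <- any(triples$driver == m & triples$mediator == x)
      if (rev_hit) circular <- union(circular, c(x, m))
      else dropped <- union(dropped, x)
    }
    dropped <- setdiff(dropped, circular)
  }
  triples$action <- if (nrow(triples))
    ifelse(triples$driver %in% dropped, "drop",
           ifelse(triples$driver %in% circular, "circular: manual review",
                  "none")) else character(0)
  list(triples = triples, dropped = dropped,
       retained = setdiff(variables, dropped), circular = circular)
}

#' Final confounder-and-interaction model
#'
#' Fits the pooled survey logistic regression of the outcome on the retained
#' biomarkers plus covariates; screens each candidate covariate-by-biomarker
#' interaction one at a time (added to the base model), retains those with
#' pooled `p <= alpha`, and refits the joint model with the retained
#' interactions. If the joint model fails to converge, the weakest retained
#' interaction is dropped and the fit retried.
#'
#' @param mi a `multiple_imputation`.
#' @param biomarkers retained biomarker terms (nonempty).
#' @param covariates covariate terms (possibly empty).
#' @param interaction_candidates character vector of `a:b` product terms.
#' @param alpha retention level for interactions.
#' @param reference_levels optional named character vector (group label ->
#'   reference-level label) used to add explicit reference rows to the
#'   summary table.
#' @param subpop optional record ids restricting the fit.
#' @return A list with `fit` (a `pooled_fit`), `interactions` (retained),
#'   `interaction_screen` (per-candidate p), and a `summary` table (term, OR,
#'   SE, p, CI bounds; reference rows have OR 1).
#' @export
fit_final_model <- function(mi, biomarkers, covariates = character(0),
                            interaction_candidates = character(0),
                            alpha = 0.05, reference_levels = NULL,
                            subpop = NULL) {
  stopifnot(length(biomarkers) > 0)
  base_terms <- c(biomarkers, covariates)
  screen <- data.frame(term = character(0), p = double(0))
  retained <- character(0)
  for (ia in interaction_candidates) {
    fit <- tryCatch(pooled_subpop_fit(mi, c(base_terms, ia), subpop = subpop),
                    error = function(e) NULL)
    p <- if (is.null(fit)) NA_real_ else fit$p.value[ia]
    screen <- rbind(screen, data.frame(term = ia, p = p))
    if (!is.na(p) && p <= alpha) retained <- c(retained, ia)
  }
  fit <- NULL
  while (is.null(fit)) {
    fit <- tryCatch(
      pooled_subpop_fit(mi, c(base_terms, retained), subpop = subpop),
      error = function(e) NULL)
    if (is.null(fit)) {
      if (!length(retained))
        stop("final model failed to converge even without interactions")
      weakest <- retained[which.max(screen$p[match(retained, screen$term)])]
      message("final model did not converge: dropping interaction ", weakest)
      retained <- setdiff(retained, weakest)
    }
  }
  tab <- data.frame(term = fit$terms, OR = fit$or, SE = fit$se,
                    p = fit$p.value, ci_low = fit$ci_low,
                    ci_high = fit$ci_high, row.names = NULL)
  if (!is.null(reference_levels)) {
    for (g in names(reference_levels)) {
      ref_row <- data.frame(term = paste0(g, ": ", reference_levels[[g]],
                                          " (Reference)"),
                            OR = 1, SE = NA, p = NA, ci_low = NA, ci_high = NA)
      tab <- rbind(tab, ref_row)
    }
  }
  list(fit = fit, interactions = retained, interaction_screen = screen,
       summary = tab)
}

#' Backward stepwise logistic regression (baseline comparator)
#'
#' Ordinary (iid maximum-likelihood) logistic regression with backward
#' elimination: while any term's p-value exceeds `alpha_remove`, the term
#' with the largest p-value is removed. Included as the traditional baseline
#' the boosted-importance step is compared against; it is known to behave
#' erratically under strong collinearity.
#'
#' @param x predictor matrix with column names.
#' @param y binary 0/1 outcome.
#' @param alpha_remove removal threshold (default 0.05).
#' @return Character vector of surviving predictor names.
#' @export
backward_stepwise_logistic <- function(x, y, alpha_remove = 0.05) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  current <- colnames(x)
  repeat {
    if (!length(current)) return(character(0))
    df <- data.frame(y = y, x[, current, drop = FALSE], check.names = FALSE)
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    if (any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE))
      stop("separation detected in stepwise fit")
    ps <- stats::coef(summary(fit))[-1, 4]
    if (all(ps <= alpha_remove, na.rm = TRUE)) return(current)
    current <- setdiff(current, current[which.max(ps)])
  }
}

#' L1-penalized selection frequency (baseline comparator)
#'
#' For the original dataset (complete cases) and each completed copy: split
#' the rows 60:40 (or `split_fraction`), fit the L1-penalized logistic path
#' on the training part, choose the penalty minimizing held-out binomial
#' deviance, and record the variables with non-zero coefficients. The
#' frequency table counts, for each variable, in how many of the `m + 1`
#' datasets it was selected.
#'
#' @param mi a `multiple_imputation`.
#' @param vars candidate predictors (default: all `predictor` columns).
#' @param split_fraction training share (default 0.6).
#' @param penalty_grid optional decreasing positive lambda sequence (default:
#'   the glmnet path).
#' @param seed integer master seed (per-dataset seeds derived from it).
#' @return A list of class `l1_baseline`: `frequency` (named counts, max
#'   m + 1), `selected_sets`, `n_selected` per dataset, `failures`.
#' @export
l1_selection_frequency <- function(mi, vars = NULL, split_fraction = 0.6,
                                   penalty_grid = NULL, seed = NULL) {
  vars <- vars %||% predictor_names(mi$original)
  y_all <- outcome_values(mi$original)
  datasets <- c(list(mi$original), mi$completed)
  sets <- vector("list", length(datasets))
  failures <- character(0)
  for (k in seq_along(datasets)) {
    x <- datasets[[k]]$values[, vars, drop = FALSE]
    ok <- stats::complete.cases(x)
    xk <- x[ok, , drop = FALSE]
    yk <- y_all[ok]
    sel <- with_seed(derive_seed(seed, k - 1L), tryCatch({
      n <- nrow(xk)
      tr <- sort(sample(n, round(split_fraction * n)))
      te <- setdiff(seq_len(n), tr)
      fit <- glmnet::glmnet(xk[tr, , drop = FALSE], yk[tr],
                            family = "binomial", lambda = penalty_grid)
      pred <- stats::predict(fit, newx = xk[te, , drop = FALSE],
                             type = "response")
      eps <- 1e-12
      pp <- pmin(pmax(pred, eps), 1 - eps)
      dev <- -2 * colSums(yk[te] * log(pp) + (1 - yk[te]) * log(1 - pp))
      best <- which.min(dev)
      cf <- as.matrix(stats::coef(fit))[-1, best]
      names(cf)[cf != 0]
    }, error = function(e) e))
    if (inherits(sel, "error")) {
      failures <- c(failures, sprintf("dataset %d: %s", k - 1L, sel$message))
      sets[[k]] <- character(0)
    } else sets[[k]] <- sel
  }
  freq <- stats::setNames(
    vapply(vars, function(v) sum(vapply(sets, function(s) v %in% s, TRUE)), 1L),
    vars)
  structure(list(frequency = freq, selected_sets = sets,
                 n_selected = vapply(sets, length, 1L), failures = failures,
                 n_datasets = length(datasets)),
            class = "l1_baseline")
}

#' @export
print.l1_baseline <- function(x, ...) {
  cat("<l1_baseline>", x$n_datasets, "datasets | selections per dataset:",
      paste(range(x$n_selected), collapse = "-"), "\n")
  print(utils::head(sort(x$frequency, decreasing = TRUE), 10))
  invisible(x)
}

#' Run the full three-step selection pipeline
#'
#' Missingness diagnostics, chained imputation, boosted importance with the
#' inclusion cutoff, a participant-level train/validation split, univariate
#' screening in both halves, collinearity and mediation elimination, and the
#' final confounder + interaction model. Every stage's decisions and seeds
#' are recorded; re-running with the same configuration is reproducible.
#'
#' @param ds a [survey_dataset].
#' @param m number of imputations (default 20).
#' @param burn_in chained-equation cycles (default 10).
#' @param boost a [boost_config] (its seed is derived from `seed`).
#' @param cutoff_pct importance inclusion cutoff (default 2).
#' @param alpha screening / retention level (default 0.05).
#' @param split_fraction training share of the Step 3 split (default 0.5).
#' @param r_threshold collinearity flag threshold (default 0.95).
#' @param covariates,interaction_candidates,reference_levels passed to
#'   [fit_final_model()].
#' @param seed master seed; all stage seeds derive from it.
#' @return A list of class `selection_report` recording every stage, with
#'   `final_biomarkers` (the biomarkers in the final model) and
#'   `final_selected` (those still significant at `alpha` in that joint
#'   confounder-adjusted model — the method's selection).
#' @export
run_pipeline <- function(ds, m = 20, burn_in = 10, boost = boost_config(),
                         cutoff_pct = 2, alpha = 0.05, split_fraction = 0.5,
                         r_threshold = 0.95, covariates = character(0),
                         interaction_candidates = character(0),
                         reference_levels = NULL, seed = NULL) {
  report <- list(seed = seed, stages = list())
  fail <- function(stage, e) {
    report$error <- paste0(stage, ": ", conditionMessage(e))
    structure(report, class = "selection_report")
  }

  # Step 1: diagnostics + imputation
  diag <- tryCatch(missingness_report(ds), error = function(e) e)
  if (inherits(diag, "error")) return(fail("diagnostics", diag))
  report$stages$diagnostics <- diag

  mi <- tryCatch(fit_chained_imputation(
    ds, imputation_config(m = m, burn_in = burn_in,
                          seed = derive_seed(seed, 1L))),
    error = function(e) e)
  if (inherits(mi, "error")) return(fail("imputation", mi))
  report$stages$imputation <- list(m = m, seeds = mi$seeds,
                                   imputed_vars = mi$imputed_vars)

  # Step 2: boosted importance + inclusion rule
  boost$seed <- derive_seed(seed, 2L)
  im <- tryCatch(importance_across_datasets(mi, boost), error = function(e) e)
  if (inherits(im, "error")) return(fail("importance", im))
  sel <- select_by_importance(im, cutoff_pct)
  step2 <- sel$variable[sel$selected]
  report$stages$importance <- list(matrix = im, selection = sel,
                                   selected = step2,
                                   coverage = importance_coverage(im, step2))
  if (!length(step2)) return(fail("importance",
                                  simpleError("no variable passed the cutoff")))

  # Step 3: split, univariate screen, collinearity, mediation, final model
  split <- tryCatch(split_train_validation(ds, split_fraction,
                                           seed = derive_seed(seed, 3L)),
                    error = function(e) e)
  if (inherits(split, "error")) return(fail("split", split))
  report$stages$split <- split

  screen <- tryCatch(univariate_screen(mi, step2, split$train,
                                       split$validation, alpha),
                     error = function(e) e)
  if (inherits(screen, "error")) return(fail("screen", screen))
  report$stages$screen <- screen
  if (!length(screen$selected))
    return(fail("screen", simpleError("no variable passed the screen")))

  imp_means <- stats::setNames(im$summary$mean, im$summary$variable)
  col <- collinearity_check(mi, screen$selected, importance = imp_means,
                            r_threshold = r_threshold)
  report$stages$collinearity <- col

  med <- tryCatch(mediation_check(mi, col$retained, alpha),
                  error = function(e) e)
  if (inherits(med, "error")) return(fail("mediation", med))
  report$stages$mediation <- med

  final <- tryCatch(fit_final_model(mi, med$retained, covariates,
                                    interaction_candidates, alpha,
                                    reference_levels),
                    error = function(e) e)
  if (inherits(final, "error")) return(fail("final_model", final))
  report$stages$final <- final
  report$final_biomarkers <- med$retained
  # final selection: biomarkers still significant once modelled jointly with
  # the other retained biomarkers, covariates and interactions
  sig <- final$fit$p.value[med$retained] <= alpha
  report$final_selected <- med$retained[sig]
  report$removals <- data.frame(
    variable = c(screen$table$variable[!screen$table$selected],
                 col$dropped, med$dropped, med$retained[!sig]),
    stage = c(rep("univariate_screen",
                  sum(!screen$table$selected)),
              rep("collinearity", length(col$dropped)),
              rep("mediation", length(med$dropped)),
              rep("final_model_not_significant", sum(!sig))))
  structure(report, class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  if (!is.null(x$error)) {
    cat("  ABORTED at", x$error, "\n")
    return(invisible(x))
  }
  cat("  importance-selected:",
      paste(x$stages$importance$selected, collapse = ", "), "\n")
  cat("  after screen:       ",
      paste(x$stages$screen$selected, collapse = ", "), "\n")
  cat("  in final model:     ",
      paste(x$final_biomarkers, collapse = ", "), "\n")
  cat("  final selection:    ",
      paste(x$final_selected, collapse = ", "), "\n")
  invisible(x)
}
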