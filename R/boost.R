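#' Boosting configuration
#'
#' Tuning parameters of the stochastic gradient-boosted tree model. Defaults
#' follow common practice for biomarker panels: strong shrinkage
#' (`shrinkage = 0.001`), 50% bagging, a 60:40 train/validation split for
#' early stopping, and trees with at most 5 terminal nodes.
#'
#' @param shrinkage learning rate lambda in (0, 1]; each tree's contribution
#'   is multiplied by it.
#' @param bag_fraction proportion of training rows drawn (without
#'   replacement) to fit each tree.
#' @param max_terminal_nodes tree size cap (>= 2).
#' @param max_iterations iteration cap when validation never stops training.
#' @param train_fraction share of rows used for training; the rest form the
#'   validation set that drives early stopping. `1` disables validation.
#' @param min_node_size minimum rows per terminal node.
#' @param patience number of consecutive non-improving validation iterations
#'   tolerated before stopping (0 = stop at the first non-improvement, the
#'   strict rule). Strict stopping can end training at iteration 1 and keep
#'   zero trees when the first tree happens not to improve the validation
#'   fold; a small positive patience (e.g. 5) is recommended in pipelines.
#' @param seed integer seed controlling the train/validation split and all
#'   bag draws.
#' @return A list of class `boost_config`.
#' @export
boost_config <- function(shrinkage = 0.001, bag_fraction = 0.5,
                         max_terminal_nodes = 5, max_iterations = 10000,
                         train_fraction = 0.6, min_node_size = 10,
                         patience = 0, seed = NULL) {
  stopifnot(shrinkage > 0, shrinkage <= 1,
            bag_fraction > 0, bag_fraction <= 1,
            max_terminal_nodes >= 2, max_iterations >= 1,
            train_fraction > 0, train_fraction <= 1,
            min_node_size >= 1, patience >= 0)
  structure(list(shrinkage = shrinkage, bag_fraction = bag_fraction,
                 max_terminal_nodes = max_terminal_nodes,
                 max_iterations = max_iterations,
                 train_fraction = train_fraction,
                 min_node_size = min_node_size, patience = patience,
                 seed = seed),
            class = "boost_config")
}

#' Fit a single regression tree to residual targets
#'
#' Greedy best-first growth: the leaf whose best split most reduces the
#' residual sum of squares is split first, until `max_terminal_nodes` leaves
#' are reached or no admissible split remains. Split thresholds are midpoints
#' between adjacent distinct observed values; each split records its
#' squared-error improvement. Leaf values are the mean of the leaf's
#' residuals. Rows missing the candidate split variable are excluded from
#' that split's improvement and routed to the child with more observed rows.
#'
#' @param x numeric predictor matrix (NA allowed).
#' @param r numeric residual targets.
#' @param max_terminal_nodes leaf cap.
#' @param min_node_size minimum rows per child.
#' @return A list of class `regression_tree` (node arrays: `var`, `thresh`,
#'   `left`, `right`, `value`, `improvement`, `na_left`, `n_rows`).
#' @export
fit_regression_tree <- function(x, r, max_terminal_nodes = 5,
                                min_node_size = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(r), nrow(x) >= 2 * min_node_size)
  tree <- .cpp_grow_tree(x, as.double(r), as.integer(max_terminal_nodes),
                         as.integer(min_node_size))
  tree$predictors <- colnames(x)
  class(tree) <- "regression_tree"
  tree
}

#' @export
predict.regression_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  .cpp_tree_predict(unclass(object), newdata)
}

#' Fit a stochastic gradient-boosted tree model (Bernoulli loss)
#'
#' Rows are split into training and validation portions; the model starts at
#' the training log-odds `F0`, and each iteration (i) computes residuals
#' `y - p` on the training rows, (ii) draws a bag of rows without
#' replacement, (iii) fits a regression tree to the bag's residuals,
#' (iv) replaces each leaf value with the Newton step
#' `sum(r) / sum(p (1 - p))`, and (v) updates `F <- F + shrinkage * tree(x)`.
#' Training stops once the validation Bernoulli log-likelihood fails to
#' improve (`patience` consecutive times) or at `max_iterations`; trees
#' through the best validation iteration are retained.
#'
#' @param x numeric predictor matrix (NA allowed: such cells are skipped in
#'   split search and routed to the majority child).
#' @param y binary 0/1 outcome.
#' @param config a [boost_config].
#' @param record_bags keep the per-iteration bag row indices on the model
#'   (memory-heavy for long runs; mainly for auditing bagging behaviour).
#' @return An object of class `boost_model`: `F0`, retained `trees`,
#'   `shrinkage`, `best_iteration`, per-iteration validation log-likelihood,
#'   normalized `importance`, and the row split used.
#' @export
fit_boosted_trees <- function(x, y, config = boost_config(),
                              record_bags = FALSE) {
  stopifnot(inherits(config, "boost_config"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(length(y) == n, is_binary01(y))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  fit <- with_seed(config$seed, {
    if (config$train_fraction < 1) {
      train <- sort(sample(n, round(config$train_fraction * n)))
      valid <- setdiff(seq_len(n), train)
    } else {
      train <- seq_len(n)
      valid <- integer(0)
    }
    res <- .cpp_boost_fit(x, as.double(y), as.integer(train),
                          as.integer(valid), config$shrinkage,
                          config$bag_fraction,
                          as.integer(config$max_terminal_nodes),
                          as.integer(config$min_node_size),
                          as.integer(config$max_iterations),
                          as.integer(config$patience), record_bags)
    res$train <- train
    res$valid <- valid
    res
  })
  model <- structure(list(F0 = fit$F0,
                          trees = fit$trees[seq_len(fit$best_iteration)],
                          shrinkage = config$shrinkage,
                          best_iteration = fit$best_iteration,
                          valid_loglik = fit$valid_loglik,
                          valid_loglik_start = fit$valid_loglik_start,
                          n_iterations = fit$n_iterations,
                          predictors = colnames(x),
                          train_rows = fit$train, valid_rows = fit$valid,
                          bags = if (record_bags) fit$bags else NULL,
                          config = config),
                     class = "boost_model")
  model$importance <- tryCatch(variable_importance(model),
                               error = function(e) NULL)
  model
}

#' @export
print.boost_model <- function(x, ...) {
  cat("<boost_model> shrinkage", x$shrinkage, "|", x$best_iteration,
      "trees kept of", x$n_iterations, "grown\n")
  if (!is.null(x$importance)) {
    imp <- sort(x$importance, decreasing = TRUE)
    top <- utils::head(imp, 5)
    cat("  top importance:",
        paste(sprintf("%s %.1f%%", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
predict.boost_model <- function(object, newdata, type = c("response", "link"),
                                ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing_cols <- setdiff(object$predictors, colnames(newdata))
    if (length(missing_cols))
      stop("newdata lacks predictor column(s): ",
           paste(missing_cols, collapse = ", "))
    newdata <- newdata[, object$predictors, drop = FALSE]
  } else if (ncol(newdata) != length(object$predictors))
    stop("newdata must have ", length(object$predictors), " columns")
  storage.mode(newdata) <- "double"
  eta <- rep(object$F0, nrow(newdata))
  for (tr in object$trees)
    eta <- eta + object$shrinkage * .cpp_tree_predict(tr, newdata)
  if (type == "link") eta else logistic(eta)
}

#' Relative variable importance
#'
#' The raw importance of a variable is the sum, over the retained trees, of
#' the squared-error improvements of all splits on that variable, divided by
#' the number of retained trees; raw values are rescaled so the total is
#' exactly 100. Variables never split get 0.
#'
#' @param model a `boost_model`.
#' @param normalize rescale to percentages summing to 100 (default) or return
#'   raw average improvements.
#' @return Named numeric vector over the model's predictors.
#' @export
variable_importance <- function(model, normalize = TRUE) {
  stopifnot(inherits(model, "boost_model"))
  preds <- model$predictors
  raw <- stats::setNames(numeric(length(preds)), preds)
  if (length(model$trees) == 0)
    stop("model has no retained trees: importance undefined")
  for (tr in model$trees) {
    splits <- which(!is.na(tr$var))
    for (s in splits) raw[tr$var[s]] <- raw[tr$var[s]] + tr$improvement[s]
  }
  raw <- raw / length(model$trees)
  if (!normalize) return(raw)
  total <- sum(raw)
  if (total <= 0) {
    warning("no splits anywhere: importance cannot be normalized")
    return(raw)
  }
  100 * raw / total
}

#' Pseudo-R-squared of a boosted model
#'
#' `1 - loglik(model) / loglik(null)` with Bernoulli log-likelihoods on the
#' supplied rows; the null model predicts the outcome mean of those rows.
#'
#' @param model a `boost_model`.
#' @param x predictor matrix.
#' @param y binary 0/1 outcome.
#' @return A single number (1 for a perfect fit, 0 for no improvement).
#' @export
pseudo_r2 <- function(model, x, y) {
  stopifnot(is_binary01(y))
  ybar <- mean(y)
  if (ybar == 0 || ybar == 1) stop("single-class outcome: pseudo-R2 undefined")
  p <- predict(model, x)
  1 - bernoulli_loglik(y, p) / bernoulli_loglik(y, rep(ybar, length(y)))
}
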