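# Independent oracles and small fixture builders used across the suite.

# Exhaustive-search regression tree: same growth rules as the package tree
# (best-first, midpoint thresholds, ties to the lowest variable index then
# smallest threshold, then to the earliest-created leaf) but implemented by
# plain enumeration in R.
oracle_best_split <- function(X, r, rows, min_node_size) {
  best <- list(improvement = 0, valid = FALSE, var = NA, thresh = NA)
  for (v in seq_len(ncol(X))) {
    x <- X[rows, v]
    rr <- r[rows]
    ok <- !is.na(x)
    x <- x[ok]; rr <- rr[ok]
    nS <- length(x)
    if (nS < 2 * min_node_size) next
    o <- order(x)
    x <- x[o]; rr <- rr[o]
    sumS <- sum(rr)
    base <- sumS^2 / nS
    sumL <- 0
    for (i in seq_len(nS - 1)) {
      sumL <- sumL + rr[i]
      if (x[i] == x[i + 1]) next
      nL <- i; nR <- nS - i
      if (nL < min_node_size || nR < min_node_size) next
      imp <- sumL^2 / nL + (sumS - sumL)^2 / nR - base
      if (imp > best$improvement + 1e-12 || (imp > 0 && !best$valid))
        best <- list(improvement = imp, valid = TRUE, var = v,
                     thresh = (x[i] + x[i + 1]) / 2)
    }
  }
  best
}

oracle_tree <- function(X, r, max_leaves, min_node_size = 1) {
  X <- as.matrix(X)
  leaves <- list(list(rows = seq_len(nrow(X)),
                      cand = oracle_best_split(X, r, seq_len(nrow(X)),
                                               min_node_size)))
  splits <- list()
  while (length(leaves) < max_leaves) {
    best_imp <- 0
    pick <- -1
    for (i in seq_along(leaves)) {
      cnd <- leaves[[i]]$cand
      if (cnd$valid && cnd$improvement > best_imp + 1e-12) {
        best_imp <- cnd$improvement
        pick <- i
      }
    }
    if (pick < 0) break
    lf <- leaves[[pick]]
    sp <- lf$cand
    x <- X[lf$rows, sp$var]
    lrows <- lf$rows[!is.na(x) & x <= sp$thresh]
    rrows <- lf$rows[!is.na(x) & x > sp$thresh]
    narows <- lf$rows[is.na(x)]
    if (length(lrows) >= length(rrows)) lrows <- c(lrows, narows)
    else rrows <- c(rrows, narows)
    splits[[length(splits) + 1L]] <-
      data.frame(var = sp$var, thresh = sp$thresh, improvement = sp$improvement)
    leaves[[pick]] <- NULL
    # append children in left-then-right creation order
    leaves[[length(leaves) + 1L]] <-
      list(rows = lrows, cand = oracle_best_split(X, r, lrows, min_node_size))
    leaves[[length(leaves) + 1L]] <-
      list(rows = rrows, cand = oracle_best_split(X, r, rrows, min_node_size))
  }
  fitted <- numeric(nrow(X))
  for (lf in leaves) fitted[lf$rows] <- mean(r[lf$rows])
  splits <- if (length(splits)) do.call(rbind, splits) else
    data.frame(var = integer(), thresh = double(), improvement = double())
  list(fitted = fitted, splits = splits[order(splits$var, splits$thresh), ],
       n_leaves = length(leaves))
}

tree_splits <- function(tree) {
  keep <- !is.na(tree$var)
  out <- data.frame(var = tree$var[keep], thresh = tree$thresh[keep],
                    improvement = tree$improvement[keep])
  out[order(out$var, out$thresh), ]
}

# A small complete survey dataset built in code.
toy_dataset <- function(n = 40, seed = 1, p = 3, prevalence = 0.4) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- rbinom(n, 1, prevalence)
  if (all(y == y[1])) y[1:2] <- c(0, 1)
  meta <- data.frame(name = c("y", colnames(X)),
                     kind = c("binary", rep("continuous", p)),
                     role = c("outcome", rep("predictor", p)))
  survey_dataset(cbind(y = y, X), meta)
}

# write a tiny csv + config pair; returns both paths
write_toy_csv <- function(dir, df, roles) {
  tp <- file.path(dir, "toy.csv")
  cp <- file.path(dir, "toy.yml")
  write.csv(df, tp, row.names = FALSE, na = "")
  yaml::write_yaml(roles, cp)
  c(table = tp, config = cp)
}
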