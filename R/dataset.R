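#' Survey dataset container
#'
#' The central data structure: a participants-by-variables numeric table with
#' an explicit observation mask, per-variable metadata (kind and analysis
#' role), and the complex-survey design columns (weight, stratum, primary
#' sampling unit). Missing cells are stored as `NA` and flagged `FALSE` in the
#' mask; the mask is authoritative.
#'
#' Variable roles are `outcome` (exactly one, binary), `predictor`,
#' `covariate` and `group`; the design roles `weight`, `stratum`, `psu` and
#' `id` are held in dedicated fields rather than in the value table. When no
#' design columns are supplied the dataset defaults to a simple random sample:
#' unit weights, one stratum, each record its own PSU.
#'
#' @param values numeric matrix or data frame, one column per analysis
#'   variable (outcome, predictors, covariates, optional group).
#' @param meta data frame with columns `name`, `kind`
#'   (`"continuous"`/`"binary"`), `role`
#'   (`"outcome"`/`"predictor"`/`"covariate"`/`"group"`), one row per column
#'   of `values`.
#' @param weights positive survey weights (default 1).
#' @param strata integer/character stratum labels (default one stratum).
#' @param psu PSU labels, nested within strata (default one PSU per record).
#' @param ids unique record identifiers (default `1:n`).
#' @return An object of class `survey_dataset`.
#' @export
survey_dataset <- function(values, meta, weights = NULL, strata = NULL,
                           psu = NULL, ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (!is.data.frame(meta) || !all(c("name", "kind", "role") %in% names(meta)))
    stop("`meta` must be a data frame with columns name, kind, role")
  meta <- data.frame(name = as.character(meta$name),
                     kind = as.character(meta$kind),
                     role = as.character(meta$role),
                     stringsAsFactors = FALSE)
  if (nrow(meta) != ncol(values))
    stop("meta has ", nrow(meta), " rows but values has ", ncol(values),
         " columns")
  colnames(values) <- meta$name
  bad_kind <- setdiff(meta$kind, c("continuous", "binary"))
  if (length(bad_kind)) stop("unknown variable kind: ", bad_kind[1])
  bad_role <- setdiff(meta$role, c("outcome", "predictor", "covariate", "group"))
  if (length(bad_role)) stop("unknown variable role: ", bad_role[1])
  if (sum(meta$role == "outcome") != 1L)
    stop("exactly one variable must have role 'outcome'")
  out_col <- which(meta$role == "outcome")
  if (meta$kind[out_col] != "binary") stop("the outcome must be binary")
  if (anyNA(values[, out_col])) stop("the outcome column contains missing cells")
  if (!is_binary01(values[, out_col])) stop("the outcome must be coded 0/1")

  has_design <- !is.null(weights) || !is.null(strata) || !is.null(psu)
  weights <- if (is.null(weights)) rep(1, n) else as.double(weights)
  strata  <- if (is.null(strata)) rep(1L, n) else as.integer(factor(strata))
  psu     <- if (is.null(psu)) seq_len(n) else as.integer(factor(psu))
  ids     <- if (is.null(ids)) seq_len(n) else ids
  if (length(weights) != n || length(strata) != n || length(psu) != n ||
      length(ids) != n)
    stop("weights, strata, psu and ids must each have one entry per record")
  if (anyNA(weights) || anyNA(strata) || anyNA(psu))
    stop("design columns (weight, stratum, psu) must contain no missing cells")
  if (any(weights <= 0)) stop("weights must be strictly positive")
  if (anyDuplicated(ids)) stop("record ids must be unique")
  if (has_design) {
    ddf <- design_degrees_of_freedom(strata, psu)
    if (ddf < 1)
      stop("design degrees of freedom (#stratum-PSU pairs - #strata) must be >= 1")
  }

  structure(list(values = values,
                 mask = !is.na(values),
                 meta = meta,
                 weights = weights,
                 strata = strata,
                 psu = psu,
                 ids = ids),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset> ", nrow(x$values), " records x ", ncol(x$values),
      " variables\n", sep = "")
  cat("  outcome:   ", outcome_name(x), " (prevalence ",
      sprintf("%.3f", mean(outcome_values(x))), ")\n", sep = "")
  cat("  predictors:", sum(x$meta$role == "predictor"),
      "  covariates:", sum(x$meta$role == "covariate"), "\n")
  cat("  design:    ", length(unique(x$strata)), " strata, ",
      length(unique(paste(x$strata, x$psu))), " PSUs, design df ",
      design_degrees_of_freedom(x$strata, x$psu), "\n", sep = "")
  n_miss <- sum(!x$mask)
  cat("  missing cells: ", n_miss, " (",
      sprintf("%.1f%%", 100 * n_miss / length(x$mask)), ")\n", sep = "")
  invisible(x)
}

#' Design degrees of freedom
#'
#' Number of distinct stratum-PSU pairs minus the number of strata, the
#' reference degrees of freedom for design-based t and F inference.
#'
#' @param strata,psu design label vectors (PSUs nested in strata).
#' @return An integer.
#' @export
design_degrees_of_freedom <- function(strata, psu) {
  length(unique(paste(strata, psu, sep = "\r"))) - length(unique(strata))
}

#' Accessors for survey datasets
#'
#' Column names by role, outcome values, and the record count of a
#' [survey_dataset].
#'
#' @param ds a [survey_dataset].
#' @return Character vectors of names (or a numeric vector / count).
#' @name dataset-accessors
NULL

#' @rdname dataset-accessors
#' @export
outcome_name <- function(ds) ds$meta$name[ds$meta$role == "outcome"]
#' @rdname dataset-accessors
#' @export
outcome_values <- function(ds) ds$values[, outcome_name(ds)]
#' @rdname dataset-accessors
#' @export
predictor_names <- function(ds) ds$meta$name[ds$meta$role == "predictor"]
#' @rdname dataset-accessors
#' @export
covariate_names <- function(ds) ds$meta$name[ds$meta$role == "covariate"]
#' @rdname dataset-accessors
#' @export
n_records <- function(ds) nrow(ds$values)

# Row subset preserving all fields.
ds_subset <- function(ds, rows) {
  out <- ds
  out$values <- ds$values[rows, , drop = FALSE]
  out$mask <- ds$mask[rows, , drop = FALSE]
  out$weights <- ds$weights[rows]
  out$strata <- ds$strata[rows]
  out$psu <- ds$psu[rows]
  out$ids <- ds$ids[rows]
  out
}

# Replace the value table (e.g. with an imputed copy), keeping metadata and
# design fields; the mask is recomputed from NA cells.
ds_replace_values <- function(ds, values) {
  stopifnot(identical(dim(values), dim(ds$values)))
  out <- ds
  out$values <- values
  out$mask <- !is.na(values)
  out
}

#' Read a survey dataset from CSV plus a column-role configuration
#'
#' The CSV must be rectangular with a header row; empty cells and literal
#' `NA` are read as missing. The configuration (YAML or JSON) maps column
#' names to a role and, for analysis variables, a kind, e.g.
#' `phq9: {role: outcome, kind: binary}`. Columns not mentioned in the
#' configuration are ignored.
#'
#' @param table_path path to the CSV file.
#' @param config_path path to the YAML (`.yml`/`.yaml`) or JSON column-role
#'   configuration.
#' @return A [survey_dataset].
#' @export
read_survey_data <- function(table_path, config_path) {
  config <- read_role_config(config_path)
  tab <- utils::read.csv(table_path, check.names = FALSE,
                         na.strings = c("", "NA"), stringsAsFactors = FALSE)
  used <- names(config)
  missing_cols <- setdiff(used, names(tab))
  if (length(missing_cols))
    stop("configuration error: column(s) not in table: ",
         paste(missing_cols, collapse = ", "))
  roles <- vapply(config, function(x) x$role %||% NA_character_, "")
  if (anyNA(roles)) stop("configuration error: every column needs a role")
  if (!any(roles == "outcome"))
    stop("configuration error: no column has role 'outcome'")
  design <- list(weight = NULL, stratum = NULL, psu = NULL, id = NULL)
  for (r in names(design)) {
    hit <- used[roles == r]
    if (length(hit) > 1)
      stop("configuration error: role '", r, "' assigned more than once")
    if (length(hit) == 1) design[[r]] <- tab[[hit]]
  }
  var_cols <- used[roles %in% c("outcome", "predictor", "covariate", "group")]
  vals <- matrix(NA_real_, nrow(tab), length(var_cols),
                 dimnames = list(NULL, var_cols))
  for (v in var_cols) {
    col <- tab[[v]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop("parse error: non-numeric value '", col[bad[1]], "' in column '",
             v, "', row ", bad[1])
      col <- num
    }
    vals[, v] <- as.double(col)
  }
  meta <- data.frame(
    name = var_cols,
    kind = vapply(config[var_cols], function(x) x$kind %||% "continuous", ""),
    role = roles[var_cols],
    stringsAsFactors = FALSE)
  survey_dataset(vals, meta, weights = design$weight, strata = design$stratum,
                 psu = design$psu, ids = design$id)
}

read_role_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("configuration error: expected a named column -> {role, kind} map")
  lapply(cfg, function(x) if (is.character(x)) list(role = x) else x)
}

#' Write a survey dataset back to CSV (with a matching role configuration)
#'
#' Emits the analysis variables, the design columns and a `_row_id` column to
#' `table_path`, and (optionally) a YAML role configuration so the pair can be
#' read back with [read_survey_data()]. Missing cells are written as empty
#' fields.
#'
#' @param ds a [survey_dataset].
#' @param table_path output CSV path.
#' @param config_path optional output YAML path for the role configuration.
#' @return Invisibly, the paths written.
#' @export
write_survey_data <- function(ds, table_path, config_path = NULL) {
  df <- as.data.frame(ds$values)
  df$`_weight` <- ds$weights
  df$`_stratum` <- ds$strata
  df$`_psu` <- ds$psu
  df$`_row_id` <- ds$ids
  utils::write.csv(df, table_path, row.names = FALSE, na = "")
  if (!is.null(config_path)) {
    cfg <- stats::setNames(
      lapply(seq_len(nrow(ds$meta)),
             function(i) list(role = ds$meta$role[i], kind = ds$meta$kind[i])),
      ds$meta$name)
    cfg$`_weight` <- list(role = "weight")
    cfg$`_stratum` <- list(role = "stratum")
    cfg$`_psu` <- list(role = "psu")
    cfg$`_row_id` <- list(role = "id")
    yaml::write_yaml(cfg, config_path)
  }
  invisible(c(table_path, config_path))
}

#' Apply the record-exclusion filters
#'
#' Removes records with `max_missing` or more missing predictor cells, then
#' (optionally) records containing an extreme outlying value. The optional
#' outlier rule flags any record with a predictor value beyond `k` robust
#' standard deviations of its column, i.e. outside median +/- k * MAD/0.6745;
#' it exists to stabilise downstream imputation and is off by default.
#'
#' @param ds a [survey_dataset].
#' @param max_missing records with at least this many missing predictor cells
#'   are excluded.
#' @param outlier_rule `"none"` (default) or `"robust_sd"`.
#' @param k robust-SD multiplier for the outlier rule.
#' @return A list with elements `dataset` (the filtered [survey_dataset]) and
#'   `report` (counts and per-record reasons; class `exclusion_report`).
#' @export
apply_exclusions <- function(ds, max_missing, outlier_rule = c("none", "robust_sd"),
                             k = 8) {
  stopifnot(max_missing >= 0)
  outlier_rule <- match.arg(outlier_rule)
  preds <- predictor_names(ds)
  n <- n_records(ds)
  miss_count <- rowSums(!ds$mask[, preds, drop = FALSE])
  excl_missing <- miss_count >= max_missing

  excl_outlier <- rep(FALSE, n)
  if (outlier_rule == "robust_sd") {
    keep <- !excl_missing
    for (v in preds) {
      x <- ds$values[keep, v]
      med <- stats::median(x, na.rm = TRUE)
      sd_rob <- stats::mad(x, na.rm = TRUE)  # already scaled by 1/0.6745
      if (is.na(sd_rob) || sd_rob == 0) next
      out <- abs(ds$values[, v] - med) > k * sd_rob
      excl_outlier <- excl_outlier | (keep & !is.na(out) & out)
    }
  }
  keep <- !excl_missing & !excl_outlier
  if (!any(keep)) stop("all records excluded: empty dataset")
  reasons <- rep("retained", n)
  reasons[excl_missing] <- "missing"
  reasons[excl_outlier] <- "outlier"
  report <- structure(list(n_input = n,
                           n_excluded_missing = sum(excl_missing),
                           n_excluded_outlier = sum(excl_outlier),
                           n_final = sum(keep),
                           reasons = data.frame(id = ds$ids, reason = reasons)),
                      class = "exclusion_report")
  list(dataset = ds_subset(ds, keep), report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report> input", x$n_input, "| excluded", x$n_excluded_missing,
      "(missing) +", x$n_excluded_outlier, "(outlier) | final", x$n_final, "\n")
  invisible(x)
}

#' Split records into training and validation halves
#'
#' Participant-level split stratified on the outcome so each half keeps the
#' outcome prevalence of the whole; the same ids then fall in the same half of
#' every imputed copy of the dataset. Assignment within each outcome level is
#' a seeded permutation.
#'
#' @param ds a [survey_dataset].
#' @param fraction training fraction, in (0, 1).
#' @param seed integer seed for reproducibility.
#' @return A list with id vectors `train` and `validation`.
#' @export
split_train_validation <- function(ds, fraction = 0.5, seed = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  y <- outcome_values(ds)
  train <- logical(n_records(ds))
  with_seed(seed, {
    for (lev in unique(y)) {
      idx <- which(y == lev)
      n_tr <- round(fraction * length(idx))
      train[sample(idx)[seq_len(n_tr)]] <- TRUE
    }
  })
  for (half in list(train, !train)) {
    yy <- y[half]
    if (length(yy) == 0 || all(yy == 1) || all(yy == 0))
      stop("degenerate split: a half has zero cases or zero non-cases")
  }
  list(train = ds$ids[train], validation = ds$ids[!train])
}
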