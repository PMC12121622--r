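#' Assemble an analysis dataset for polyp-count modelling
#'
#' Builds the outcome vector and the two design matrices (count/odds
#' component and zero-inflation component) from a subject-level data frame.
#' Categorical covariates are dummy-coded against the first level in sorted
#' order so that fits are reproducible without a formula interface.
#'
#' @param data data frame with one row per subject.
#' @param outcome name of the non-negative integer count column (number of
#'   detected polyps).
#' @param group name of the binary exposure column (0/1, logical, or a
#'   two-level factor; coded 1 for the second sorted level).
#' @param covariates character vector of covariate names for the count
#'   (and, for single-part models, odds) component.
#' @param zero_covariates covariate names for the inflation component;
#'   defaults to `covariates`. May differ, e.g. when a covariate belongs
#'   only in the excess-zero part of the model.
#' @param topcode if non-`NULL`, counts at or above this value are merged
#'   into it before modelling (the case studies merge counts of six or
#'   more into a single category).
#' @return an object of class `polyp_data`: a list with elements `y`,
#'   `X` (count design, including intercept), `Z` (inflation design),
#'   `group` (column name), `n`.
#' @examples
#' d <- data.frame(polyps = c(0, 0, 2, 1, 0, 4), arm = rep(0:1, each = 3))
#' pd <- polyp_data(d, outcome = "polyps", group = "arm")
#' pd$n
#' @export
polyp_data <- function(data, outcome, group, covariates = character(),
                       zero_covariates = covariates, topcode = NULL) {
  stopifnot(is.data.frame(data))
  cols <- unique(c(outcome, group, covariates, zero_covariates))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  y <- data[[outcome]]
  bad <- which(!is.finite(y) | y < 0 | y != floor(y))
  if (length(bad))
    stop("outcome must be a non-negative integer count; offending rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  y <- as.integer(y)
  if (!is.null(topcode)) {
    stopifnot(topcode >= 1)
    y <- pmin(y, as.integer(topcode))
  }
  if (max(y) < 1)
    stop("all outcomes are zero; count models are not identifiable",
         call. = FALSE)

  g <- .binary_code(data[[group]], group)
  build <- function(covs) {
    df <- data.frame(`(Intercept)` = rep(1, nrow(data)), check.names = FALSE)
    df[[group]] <- g
    for (v in covs) {
      x <- data[[v]]
      if (is.numeric(x)) {
        df[[v]] <- x
      } else {
        x <- factor(x, levels = sort(unique(as.character(x))))
        for (lev in levels(x)[-1])
          df[[paste(v, lev, sep = ".")]] <- as.numeric(x == lev)
      }
    }
    m <- as.matrix(df)
    if (qr(m)$rank < ncol(m))
      stop("design matrix is rank deficient (columns: ",
           paste(colnames(m), collapse = ", "), ")", call. = FALSE)
    m
  }

  structure(list(y = y, X = build(covariates), Z = build(zero_covariates),
                 group = group, n = length(y)),
            class = "polyp_data")
}

.binary_code <- function(x, name) {
  if (is.logical(x)) return(as.numeric(x))
  u <- sort(unique(as.character(x[!is.na(x)])))
  if (length(u) != 2L)
    stop("group column '", name, "' must have exactly two levels, found: ",
         paste(u, collapse = ", "), call. = FALSE)
  if (all(u == c("0", "1"))) as.numeric(as.character(x))
  else as.numeric(as.character(x) == u[2])
}

#' @export
print.polyp_data <- function(x, ...) {
  cat(sprintf(
    "<polyp_data: %d subjects, %.1f%% zeros, mean count %.2f (var %.2f)>\n",
    x$n, 100 * mean(x$y == 0), mean(x$y), stats::var(x$y)))
  cat(sprintf("  count design: %s\n", paste(colnames(x$X), collapse = ", ")))
  if (!identical(colnames(x$Z), colnames(x$X)))
    cat(sprintf("  zero design:  %s\n", paste(colnames(x$Z), collapse = ", ")))
  invisible(x)
}

## Row subset preserving class and designs.
subset_polyp_data <- function(data, idx) {
  structure(list(y = data$y[idx], X = data$X[idx, , drop = FALSE],
                 Z = data$Z[idx, , drop = FALSE], group = data$group,
                 n = length(idx)),
            class = "polyp_data")
}

#' Read a subject-level CSV into a `polyp_data` object
#'
#' Applies complete-case filtering over the referenced columns (with a
#' message stating how many records were dropped, mirroring the reporting
#' convention of observational colonoscopy studies) and optional
#' topcoding.
#'
#' @param path CSV file with a header row, or a run-configuration list /
#'   YAML file (see Details).
#' @param outcome,group,covariates,zero_covariates,topcode as in
#'   [polyp_data()]; ignored when `path` is a configuration.
#' @details A configuration (list or YAML file) uses the keys
#'   `input_path`, `outcome_column`, `group_column`, `count_covariates`,
#'   `inflate_covariates`, `topcode_at`.
#' @return a `polyp_data` object; the number of dropped incomplete records
#'   is attached as attribute `n_dropped`.
#' @export
read_dataset <- function(path, outcome = NULL, group = NULL,
                         covariates = character(),
                         zero_covariates = covariates, topcode = NULL) {
  if (is.list(path) || (is.character(path) && grepl("[.]ya?ml$", path))) {
    cfg <- if (is.list(path)) path else yaml::read_yaml(path)
    return(read_dataset(cfg$input_path, outcome = cfg$outcome_column,
                        group = cfg$group_column,
                        covariates = as.character(cfg$count_covariates %||% character()),
                        zero_covariates =
                          as.character(cfg$inflate_covariates %||%
                                         cfg$count_covariates %||% character()),
                        topcode = cfg$topcode_at))
  }
  if (is.null(outcome) || is.null(group))
    stop("'outcome' and 'group' column names are required", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  used <- unique(c(outcome, group, covariates, zero_covariates))
  cc <- stats::complete.cases(df[, used, drop = FALSE])
  if (any(!cc))
    message(sum(!cc), " of ", nrow(df),
            " records dropped for missing data; ", sum(cc), " retained")
  out <- polyp_data(df[cc, , drop = FALSE], outcome = outcome, group = group,
                    covariates = covariates,
                    zero_covariates = zero_covariates, topcode = topcode)
  attr(out, "n_dropped") <- sum(!cc)
  out
}

#' Write a `polyp_data` object back to CSV
#'
#' Inverse of [read_dataset()] for datasets whose designs contain only the
#' intercept, group and numeric covariate columns (as produced by
#' [generate_dataset()]).
#'
#' @param data a `polyp_data` object.
#' @param path output CSV path.
#' @param outcome name to use for the outcome column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, outcome = "polyps") {
  stopifnot(inherits(data, "polyp_data"))
  covs <- setdiff(union(colnames(data$X), colnames(data$Z)), "(Intercept)")
  df <- data.frame(y = data$y)
  names(df) <- outcome
  for (v in covs)
    df[[v]] <- if (v %in% colnames(data$X)) data$X[, v] else data$Z[, v]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
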