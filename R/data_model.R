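#' Assemble a multi-source dataset from a data frame
#'
#' Bundles an outcome, a binary treatment, a binary source indicator
#' (1 = randomized trial, 0 = observational study), and covariates into the
#' validated container all estimators in cfrisk consume. Categorical
#' covariates are one-hot encoded deterministically (levels in lexicographic
#' order, first level dropped) so repeated loads of the same table give
#' byte-identical design matrices. The analysis is strictly complete-case:
#' any missing value is an error, never silently dropped.
#'
#' @param data A data frame with one row per participant.
#' @param outcome,treatment,source Column names (strings) of the outcome `Y`,
#'   treatment `A` (0/1), and source indicator `S` (1 = trial,
#'   0 = observational).
#' @param covariates Character vector of covariate column names; defaults to
#'   every column other than outcome/treatment/source.
#' @param xstar Character vector naming the covariate subset `X*` the
#'   prediction model consumes; defaults to all covariates (`X* = X`).
#'   Names refer to the original columns; encoded indicator columns derived
#'   from a categorical are included whenever the categorical is named.
#' @param categoricals Character vector of covariate names to treat as
#'   categorical (factors and character columns are always treated as such).
#'
#' @return An object of class `msdata` with elements `Y`, `A`, `S`
#'   (vectors), `X` (numeric matrix, encoded), `xstar_columns` (encoded
#'   column names), and counts `n0`, `n1`.
#' @examples
#' d <- data.frame(Y = rnorm(8), A = rep(0:1, 4), S = rep(0:1, each = 4),
#'                 age = rnorm(8))
#' ds <- multisource_data(d, outcome = "Y", treatment = "A", source = "S")
#' ds$n0
#' @export
multisource_data <- function(data, outcome = "Y", treatment = "A", source = "S",
                             covariates = NULL, xstar = NULL,
                             categoricals = NULL) {
  data <- as.data.frame(data)
  needed <- c(outcome, treatment, source, covariates, categoricals)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("column(s) not found in data: ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c(outcome, treatment, source))
  }
  if (length(covariates) == 0) stop_schema("no covariate columns available")
  used <- data[, c(outcome, treatment, source, covariates), drop = FALSE]
  if (anyNA(used)) {
    bad <- names(used)[vapply(used, anyNA, logical(1))]
    stop_completeness(paste0("missing values in column(s): ",
                             paste(bad, collapse = ", "),
                             " (complete-case contract)"))
  }

  Y <- data[[outcome]]
  if (!is.numeric(Y)) stop_domain("outcome must be numeric")
  A <- check_binary(data[[treatment]], treatment)
  S <- check_binary(data[[source]], source)

  enc <- encode_covariates(data[, covariates, drop = FALSE], categoricals)
  X <- enc$X
  if (is.null(xstar)) xstar <- covariates
  unknown <- setdiff(xstar, covariates)
  if (length(unknown) > 0) {
    stop_schema(paste0("xstar names not among covariates: ",
                       paste(unknown, collapse = ", ")))
  }
  xstar_columns <- unlist(enc$groups[xstar], use.names = FALSE)
  if (length(xstar_columns) == 0) stop_domain("xstar designation is empty")

  new_msdata(Y = as.numeric(Y), A = A, S = S, X = X,
             xstar_columns = xstar_columns)
}

# Low-level constructor: trusts its inputs. Used on resampled/simulated data
# where validation has already happened; keeps the bootstrap fast.
new_msdata <- function(Y, A, S, X, xstar_columns) {
  n0 <- sum(S == 0L)
  n1 <- sum(S == 1L)
  if (n0 < 1 || n1 < 1) {
    stop_domain("both sources must be present (n0 >= 1 and n1 >= 1)")
  }
  structure(
    list(Y = Y, A = A, S = S, X = X, xstar_columns = xstar_columns,
         n0 = n0, n1 = n1, n = n0 + n1),
    class = "msdata"
  )
}

check_binary <- function(v, name) {
  if (is.logical(v)) v <- as.integer(v)
  if (!is.numeric(v) || !all(v %in% c(0, 1))) {
    stop_domain(paste0("column '", name, "' must contain only 0/1 values"))
  }
  as.integer(v)
}

# One-hot encoding with deterministic level order. Returns the numeric matrix
# and, per original covariate, the encoded column names it expands to.
encode_covariates <- function(df, categoricals = NULL) {
  cols <- list()
  groups <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    is_cat <- nm %in% categoricals || is.character(v) || is.factor(v) ||
      is.logical(v)
    if (is_cat) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) < 2) {
        # constant categorical carries no information; keep a zero column so
        # the designation X* stays well-defined
        cols[[nm]] <- rep(0, nrow(df))
        groups[[nm]] <- nm
      } else {
        keep <- lev[-1]  # drop reference level for full-rank designs
        nms <- paste0(nm, keep)
        for (k in seq_along(keep)) {
          cols[[nms[k]]] <- as.numeric(as.character(v) == keep[k])
        }
        groups[[nm]] <- nms
      }
    } else {
      if (!is.numeric(v)) stop_domain(paste0("covariate '", nm, "' is not numeric"))
      cols[[nm]] <- as.numeric(v)
      groups[[nm]] <- nm
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  rownames(X) <- NULL
  list(X = X, groups = groups)
}

#' Read a multi-source dataset from a CSV file
#'
#' Reads an RFC-4180 CSV (header row required) and assembles it with
#' [multisource_data()]. The schema — which columns hold the outcome,
#' treatment, and source indicator, which are covariates, which of those are
#' categorical, and the `X*` designation — comes from a structured config:
#' either a named list or the path to a YAML/JSON file with keys
#' `outcome`, `treatment`, `source`, and optionally `covariates`, `xstar`,
#' `categoricals`.
#'
#' @param path Path to the CSV file.
#' @param config Named list or path to a YAML/JSON config file.
#' @return An `msdata` object (see [multisource_data()]).
#' @export
read_multisource <- function(path, config) {
  config <- load_config(config)
  for (key in c("outcome", "treatment", "source")) {
    if (is.null(config[[key]])) {
      stop_schema(paste0("config is missing required key '", key, "'"))
    }
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  multisource_data(
    data,
    outcome = config$outcome, treatment = config$treatment,
    source = config$source,
    covariates = config$covariates %||% NULL,
    xstar = config$xstar %||% NULL,
    categoricals = config$categoricals %||% NULL
  )
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_schema(paste0("config file not found: ", config))
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      config <- yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop_schema("config must be a named list or a file path")
  config
}

#' @export
print.msdata <- function(x, ...) {
  cat("<msdata> ", x$n, " rows (trial n1 = ", x$n1,
      ", observational n0 = ", x$n0, ")\n", sep = "")
  cat("  covariates: ", paste(colnames(x$X), collapse = ", "), "\n", sep = "")
  cat("  X*:         ", paste(x$xstar_columns, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method glance msdata
#' @export
glance.msdata <- function(x, ...) {
  tibble::tibble(n = x$n, n0 = x$n0, n1 = x$n1,
                 p_covariates = ncol(x$X),
                 p_xstar = length(x$xstar_columns))
}

#' Extract the X* columns of a dataset as a matrix
#' @param ds An `msdata` object.
#' @param rows Optional integer row indices.
#' @return Numeric matrix of the designated `X*` columns.
#' @export
xstar_matrix <- function(ds, rows = NULL) {
  m <- ds$X[, ds$xstar_columns, drop = FALSE]
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

#' Check that the data cells an analysis conditions on are non-empty
#'
#' The observational analysis fits its loss regression in the
#' `(S = 0, A = a)` cell; the transportability analysis in `(S = 1, A = a)`
#' (and averages over `S = 0`); the joint analysis pools all `A = a` rows and
#' averages over `S = 0`. An empty required cell makes the corresponding
#' estimand inestimable and raises an estimability error naming the cell.
#' The observational check deliberately never inspects trial rows.
#'
#' @param ds An `msdata` object.
#' @param a Treatment level (0 or 1).
#' @param analysis One of `"observational"`, `"transportability"`, `"joint"`.
#' @return Invisibly `TRUE` when all required cells are populated.
#' @export
validate_cells <- function(ds, a, analysis) {
  analysis <- match_analysis(analysis)
  stopifnot(a %in% c(0, 1))
  s0 <- ds$S == 0L
  has_cell <- function(s, msg) {
    if (!any(s)) stop_estimability(msg)
  }
  if (analysis == "observational") {
    has_cell(s0 & ds$A == a,
             paste0("empty cell (S=0, A=", a, ") required by the observational analysis"))
  } else if (analysis == "transportability") {
    has_cell(ds$S == 1L & ds$A == a,
             paste0("empty cell (S=1, A=", a, ") required by the transportability analysis"))
    has_cell(s0, "no observational (S=0) rows to average over")
  } else {
    has_cell(ds$A == a,
             paste0("empty pooled cell (A=", a, ") required by the joint analysis"))
    has_cell(s0, "no observational (S=0) rows to average over")
  }
  invisible(TRUE)
}
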