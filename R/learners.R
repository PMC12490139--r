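#' Declare a learner for nuisance and tailored-model regressions
#'
#' A learner is a small recipe object describing how a regression is fit.
#' Available kinds:
#'
#' * `"linear"` — least squares on raw polynomial terms of each column up to
#'   `degree` (default 1, i.e. main effects), with intercept.
#' * `"logistic"` — logistic regression on the same design; used for
#'   treatment propensities and the trial-participation model.
#' * `"saturated"` — cell means over the distinct rows of the design; the
#'   nonparametric choice for low-dimensional discrete covariates. Unseen
#'   cells fall back to the global mean.
#' * `"random_forest"` — [ranger::ranger()] regression (or probability)
#'   forest; deterministic given its `seed` hyperparameter.
#'
#' @param kind One of `"linear"`, `"logistic"`, `"saturated"`,
#'   `"random_forest"`.
#' @param ... Hyperparameters. `degree` for linear/logistic; `num.trees`,
#'   `mtry`, `min.node.size`, `seed` for the forest.
#' @return A `cfrisk_learner` recipe.
#' @seealso [user_learner()] to plug in an arbitrary fit/predict pair.
#' @export
learner <- function(kind = c("linear", "logistic", "saturated", "random_forest"),
                    ...) {
  kind <- match.arg(kind)
  hyper <- list(...)
  if (kind %in% c("linear", "logistic")) {
    hyper$degree <- as.integer(hyper$degree %||% 1L)
    if (hyper$degree < 0) stop_domain("degree must be >= 0")
  }
  if (kind == "random_forest") {
    hyper$num.trees <- hyper$num.trees %||% 500L
    hyper$seed <- hyper$seed %||% 1L
  }
  structure(list(kind = kind, hyperparameters = hyper),
            class = "cfrisk_learner")
}

#' Wrap user-supplied fit/predict functions as a learner
#'
#' @param fit Function `(X, y) -> fitted_state` where `X` is a numeric matrix.
#' @param predict Function `(fitted_state, X) -> numeric vector`.
#' @return A `cfrisk_learner` of kind `"user_supplied"`.
#' @export
user_learner <- function(fit, predict) {
  stopifnot(is.function(fit), is.function(predict))
  structure(list(kind = "user_supplied",
                 hyperparameters = list(fit = fit, predict = predict)),
            class = "cfrisk_learner")
}

is_learner <- function(x) inherits(x, "cfrisk_learner")

poly_design <- function(X, degree) {
  X <- as.matrix(X)
  if (degree == 0L || ncol(X) == 0) {
    return(matrix(1, nrow(X), 1, dimnames = list(NULL, "(Intercept)")))
  }
  blocks <- list(`(Intercept)` = rep(1, nrow(X)))
  for (j in seq_len(ncol(X))) {
    nm <- colnames(X)[j] %||% paste0("x", j)
    for (d in seq_len(degree)) {
      cn <- if (d == 1) nm else paste0(nm, "^", d)
      blocks[[cn]] <- X[, j]^d
    }
  }
  out <- do.call(cbind, blocks)
  colnames(out) <- names(blocks)
  out
}

# Fit a learner on a numeric matrix X and response y.
# family: "gaussian" for conditional means, "binomial" for probabilities.
fit_learner <- function(lrn, X, y, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (!all(is.finite(y))) stop_domain("non-finite response passed to learner")
  fitted <- switch(
    lrn$kind,
    linear = {
      D <- poly_design(X, lrn$hyperparameters$degree)
      fit <- lm.fit(D, y)
      list(coef = ifelse(is.na(fit$coefficients), 0, fit$coefficients),
           degree = lrn$hyperparameters$degree)
    },
    logistic = {
      D <- poly_design(X, lrn$hyperparameters$degree)
      fit <- suppressWarnings(
        glm.fit(D, y, family = binomial(), control = list(maxit = 50))
      )
      list(coef = ifelse(is.na(fit$coefficients), 0, fit$coefficients),
           degree = lrn$hyperparameters$degree)
    },
    saturated = {
      key <- apply(X, 1, paste, collapse = "\r")
      means <- tapply(y, key, mean)
      list(means = means, fallback = mean(y))
    },
    random_forest = {
      hp <- lrn$hyperparameters
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_len(ncol(X)))
      args <- list(x = df, y = y, num.trees = hp$num.trees,
                   seed = hp$seed, num.threads = 1)
      if (!is.null(hp$mtry)) args$mtry <- hp$mtry
      if (!is.null(hp$min.node.size)) args$min.node.size <- hp$min.node.size
      if (family == "binomial") {
        args$y <- factor(y, levels = c(0, 1))
        args$probability <- TRUE
      }
      list(forest = do.call(ranger::ranger, args), binomial = family == "binomial")
    },
    user_supplied = {
      list(state = lrn$hyperparameters$fit(X, y),
           predict = lrn$hyperparameters$predict)
    },
    stop_domain(paste0("unknown learner kind: ", lrn$kind))
  )
  structure(list(kind = lrn$kind, family = family, fitted = fitted,
                 colnames = colnames(X), n_fit = nrow(X)),
            class = "cfrisk_fitted_learner")
}

predict_learner <- function(fit, X) {
  X <- as.matrix(X)
  out <- switch(
    fit$kind,
    linear = drop(poly_design(X, fit$fitted$degree) %*% fit$fitted$coef),
    logistic = plogis(drop(poly_design(X, fit$fitted$degree) %*% fit$fitted$coef)),
    saturated = {
      key <- apply(X, 1, paste, collapse = "\r")
      v <- fit$fitted$means[key]
      v[is.na(v)] <- fit$fitted$fallback
      unname(v)
    },
    random_forest = {
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_len(ncol(X)))
      p <- predict(fit$fitted$forest, data = df, num.threads = 1)$predictions
      if (fit$fitted$binomial) p[, "1"] else p
    },
    user_supplied = as.numeric(fit$fitted$predict(fit$fitted$state, X))
  )
  if (!all(is.finite(out))) stop_domain("learner produced non-finite predictions")
  as.numeric(out)
}

#' @export
print.cfrisk_learner <- function(x, ...) {
  hp <- x$hyperparameters
  hp <- hp[!vapply(hp, is.function, logical(1))]
  cat("<learner: ", x$kind, "> ",
      paste(names(hp), unlist(hp, use.names = FALSE), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
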