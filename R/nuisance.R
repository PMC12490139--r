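# Nuisance functions: conditional-loss regressions h, treatment propensities
# e, and the trial-participation model p(X) = Pr(S=1|X) with its implied
# transport odds w(X) = Pr(S=0|X)/Pr(S=1|X).

#' Fit a conditional-loss regression h(X)
#'
#' Regresses the per-row loss `L(Y, g(X*))` on the full covariate vector `X`
#' within one estimation cell: `source = 0` fits on `(S=0, A=a)` rows,
#' `source = 1` on `(S=1, A=a)` rows, and `source = "pooled"` on all `A=a`
#' rows across both sources (the joint analysis's h, which omits `S` as a
#' predictor because under the joint assumptions the conditional losses are
#' equal across sources).
#'
#' @param ds An `msdata` object.
#' @param losses Numeric per-row loss vector (length `ds$n`), e.g. from
#'   [compute_losses()].
#' @param a Treatment level (0 or 1).
#' @param source `0`, `1`, or `"pooled"`.
#' @param learner A [learner()]; default main-effects linear regression.
#' @param include_source_diagnostic If `TRUE` and `source = "pooled"`, also
#'   fits a version with `S` added as a predictor, kept as a diagnostic for
#'   the equality of conditional losses across sources.
#' @return A `cfrisk_loss_model` with a [predict()] method taking covariate
#'   matrices/data frames with `ds`'s columns.
#' @export
fit_loss_regression <- function(ds, losses, a, source,
                                learner = cfrisk::learner("linear"),
                                include_source_diagnostic = FALSE) {
  stopifnot(inherits(ds, "msdata"), is_learner(learner))
  if (length(losses) != ds$n) stop_domain("losses must have one entry per row")
  if (!all(is.finite(losses))) stop_domain("losses contain non-finite values")
  idx <- cell_index(ds, a, source)
  if (length(idx) == 0) {
    stop_estimability(paste0("empty cell (source=", source, ", A=", a,
                             ") for the loss regression"))
  }
  fit <- fit_learner(learner, ds$X[idx, , drop = FALSE], losses[idx],
                     family = "gaussian")
  diagnostic <- NULL
  if (isTRUE(include_source_diagnostic) && identical(source, "pooled")) {
    Xs <- cbind(ds$X, S = ds$S)
    diagnostic <- fit_learner(learner, Xs[idx, , drop = FALSE], losses[idx],
                              family = "gaussian")
  }
  structure(list(fit = fit, a = a, source = source, rows = idx,
                 columns = colnames(ds$X), diagnostic = diagnostic),
            class = "cfrisk_loss_model")
}

cell_index <- function(ds, a, source) {
  if (identical(source, "pooled")) {
    which(ds$A == a)
  } else {
    which(ds$S == source & ds$A == a)
  }
}

#' @export
predict.cfrisk_loss_model <- function(object, newdata, ...) {
  predict_learner(object$fit, as_x_matrix(newdata, object$columns))
}

#' Fit a treatment-propensity model Pr(A=1 | X, S=source)
#'
#' @inheritParams fit_loss_regression
#' @param source Source stratum, 0 or 1.
#' @param learner A [learner()]; default main-effects logistic regression.
#' @param clip_bounds Probabilities are clipped into this interval at
#'   prediction time to stabilize inverse weights.
#' @return A `cfrisk_prob_model` with a [predict()] method returning clipped
#'   probabilities.
#' @export
fit_treatment_model <- function(ds, source,
                                learner = cfrisk::learner("logistic"),
                                clip_bounds = c(0.001, 0.999)) {
  stopifnot(inherits(ds, "msdata"), source %in% c(0, 1), is_learner(learner))
  idx <- which(ds$S == source)
  if (length(idx) == 0) stop_estimability(paste0("no rows with S=", source))
  av <- ds$A[idx]
  if (length(unique(av)) < 2) {
    stop_estimability(paste0("single treatment level in stratum S=", source,
                             "; propensity not estimable"))
  }
  fit <- fit_learner(learner, ds$X[idx, , drop = FALSE], av, family = "binomial")
  structure(list(fit = fit, source = source, rows = idx,
                 columns = colnames(ds$X), clip_bounds = clip_bounds),
            class = c("cfrisk_prob_model", "cfrisk_treatment_model"))
}

#' Fit the trial-participation model Pr(S=1 | X)
#'
#' Fitted on the combined sample; under the non-nested design the sampling
#' fractions are unknown, so only the odds
#' `w(X) = Pr(S=0|X) / Pr(S=1|X)` is identified up to a constant — a constant
#' that Hajek normalization absorbs. Use `predict_odds()` for `w(X)`.
#'
#' @inheritParams fit_treatment_model
#' @return A `cfrisk_prob_model`.
#' @export
fit_participation_model <- function(ds,
                                    learner = cfrisk::learner("logistic"),
                                    clip_bounds = c(0.001, 0.999)) {
  stopifnot(inherits(ds, "msdata"), is_learner(learner))
  fit <- fit_learner(learner, ds$X, ds$S, family = "binomial")
  structure(list(fit = fit, source = NULL, rows = seq_len(ds$n),
                 columns = colnames(ds$X), clip_bounds = clip_bounds),
            class = c("cfrisk_prob_model", "cfrisk_participation_model"))
}

#' @export
predict.cfrisk_prob_model <- function(object, newdata, ...) {
  clip_prob(predict_learner(object$fit, as_x_matrix(newdata, object$columns)),
            object$clip_bounds)
}

#' Transport odds w(X) implied by a participation model
#' @param object A fitted participation model.
#' @param newdata Covariate rows.
#' @return `Pr(S=0|X)/Pr(S=1|X)` with clipped probabilities.
#' @export
predict_odds <- function(object, newdata) {
  p <- predict(object, newdata)
  (1 - p) / p
}

as_x_matrix <- function(newdata, columns) {
  if (inherits(newdata, "msdata")) newdata <- newdata$X
  m <- as.matrix(as.data.frame(newdata))
  if (!is.null(colnames(m)) && !all(grepl("^V[0-9]+$", colnames(m)))) {
    if (!all(columns %in% colnames(m))) {
      stop_schema(paste0("newdata is missing required column(s): ",
                         paste(setdiff(columns, colnames(m)), collapse = ", ")))
    }
    m <- m[, columns, drop = FALSE]
  } else if (ncol(m) != length(columns)) {
    stop_schema("newdata columns do not match the model's covariates")
  }
  storage.mode(m) <- "double"
  m
}

#' Fit the full nuisance set an estimator grid needs
#'
#' Fits only the components the requested analyses and estimators consume:
#' conditional-loss regressions `h_{a,0}`, `h_{a,1}`, pooled `h_a`; treatment
#' propensities per source; and the participation model. Per-row predictions
#' for every fitted component are stored so the estimators are pure
#' arithmetic. Optional K-fold cross-fitting replaces each fitting row's own
#' prediction with an out-of-fold one (recommended for flexible learners such
#' as forests; off by default, matching main-effects parametric nuisances).
#'
#' @inheritParams fit_loss_regression
#' @param analyses Character subset of
#'   `c("observational", "transportability", "joint")`.
#' @param estimators Character subset of `c("om", "ipw", "dr")`.
#' @param loss_learner Learner for the conditional-loss regressions.
#' @param propensity_learner Learner for the treatment and participation
#'   models.
#' @param clip_bounds Probability clipping interval, default
#'   `c(0.001, 0.999)`.
#' @param trial_assignment_prob If the trial randomization probability is
#'   known (e.g. 0.5), it is used directly for the trial propensity instead
#'   of an estimate.
#' @param cross_fit Integer number of folds K; `0` (default) disables
#'   cross-fitting.
#' @param seed Seed for the fold assignment when `cross_fit > 0`.
#' @return A `nuisance_set` holding fitted models and per-row prediction
#'   vectors (`h0`, `h1`, `hp`, `e0`, `e1`, `p`, `w`), the treatment level
#'   `a`, and bookkeeping.
#' @export
fit_nuisances <- function(ds, losses, a,
                          analyses = c("observational", "transportability", "joint"),
                          estimators = c("om", "ipw", "dr"),
                          loss_learner = cfrisk::learner("linear"),
                          propensity_learner = cfrisk::learner("logistic"),
                          clip_bounds = c(0.001, 0.999),
                          trial_assignment_prob = NULL,
                          cross_fit = 0L, seed = NULL) {
  stopifnot(inherits(ds, "msdata"))
  analyses <- vapply(analyses, match_analysis, character(1))
  estimators <- vapply(estimators, match_estimator, character(1))

  need_h0 <- "observational" %in% analyses && any(c("om", "dr") %in% estimators)
  need_h1 <- "transportability" %in% analyses && any(c("om", "dr") %in% estimators)
  need_hp <- "joint" %in% analyses && any(c("om", "dr") %in% estimators)
  weighted <- any(c("ipw", "dr") %in% estimators)
  need_e0 <- weighted && any(c("observational", "joint") %in% analyses)
  need_e1 <- weighted && any(c("transportability", "joint") %in% analyses)
  need_p <- weighted && any(c("transportability", "joint") %in% analyses)

  K <- as.integer(cross_fit)
  out <- list(a = a, clip_bounds = clip_bounds, cross_fit = K,
              models = list(), pred = list(), n = ds$n)

  fit_h <- function(source) {
    m <- fit_loss_regression(ds, losses, a, source, learner = loss_learner)
    pr <- crossfit_predictions(
      full_model = m, refit = function(rows) {
        fit_learner(loss_learner, ds$X[rows, , drop = FALSE], losses[rows],
                    family = "gaussian")
      },
      fit_rows = m$rows, X = ds$X, K = K, seed = seed, clip = NULL
    )
    list(model = m, pred = pr)
  }
  fit_prob <- function(fitter, fit_rows, yvec) {
    m <- fitter()
    pr <- crossfit_predictions(
      full_model = m, refit = function(rows) {
        fit_learner(propensity_learner, ds$X[rows, , drop = FALSE], yvec[rows],
                    family = "binomial")
      },
      fit_rows = fit_rows, X = ds$X, K = K, seed = seed, clip = clip_bounds
    )
    list(model = m, pred = pr)
  }

  if (need_h0) {
    r <- fit_h(0); out$models$h0 <- r$model; out$pred$h0 <- r$pred
  }
  if (need_h1) {
    r <- fit_h(1); out$models$h1 <- r$model; out$pred$h1 <- r$pred
  }
  if (need_hp) {
    r <- fit_h("pooled"); out$models$hp <- r$model; out$pred$hp <- r$pred
  }
  if (need_e0) {
    r <- fit_prob(function() fit_treatment_model(ds, 0, propensity_learner, clip_bounds),
                  which(ds$S == 0L), ds$A)
    out$models$e0 <- r$model; out$pred$e0 <- r$pred
  }
  if (need_e1) {
    if (!is.null(trial_assignment_prob)) {
      out$pred$e1 <- rep(clip_prob(trial_assignment_prob, clip_bounds), ds$n)
      out$models$e1 <- "known_randomization_probability"
    } else {
      r <- fit_prob(function() fit_treatment_model(ds, 1, propensity_learner, clip_bounds),
                    which(ds$S == 1L), ds$A)
      out$models$e1 <- r$model; out$pred$e1 <- r$pred
    }
  }
  if (need_p) {
    r <- fit_prob(function() fit_participation_model(ds, propensity_learner, clip_bounds),
                  seq_len(ds$n), ds$S)
    out$models$p <- r$model; out$pred$p <- r$pred
    out$pred$w <- (1 - r$pred) / r$pred
  }
  structure(out, class = "nuisance_set")
}

# Per-row predictions for all rows of X; with K >= 2 the rows the model was
# fit on get out-of-fold predictions instead of in-sample ones.
crossfit_predictions <- function(full_model, refit, fit_rows, X, K, seed,
                                 clip = NULL) {
  pred <- if (inherits(full_model, "cfrisk_loss_model") ||
              inherits(full_model, "cfrisk_prob_model")) {
    predict(full_model, X)
  } else {
    stop_state("unfittable nuisance component")
  }
  if (K >= 2L && length(fit_rows) >= 2L * K) {
    folds <- with_seed_if(seed %||% 0L,
                          sample(rep_len(seq_len(K), length(fit_rows))))
    for (k in seq_len(K)) {
      hold <- fit_rows[folds == k]
      train <- fit_rows[folds != k]
      fk <- refit(train)
      pk <- predict_learner(fk, X[hold, , drop = FALSE])
      if (!is.null(clip)) pk <- clip_prob(pk, clip)
      pred[hold] <- pk
    }
  }
  pred
}

#' @export
print.nuisance_set <- function(x, ...) {
  cat("<nuisance_set> a = ", x$a, "; components: ",
      paste(names(x$pred), collapse = ", "),
      if (x$cross_fit >= 2) paste0("; cross-fit K=", x$cross_fit) else "",
      "\n", sep = "")
  invisible(x)
}
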