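#' Fit a model tailored to the counterfactual outcome in the target population
#'
#' A *tailored model* estimates `mu_a(X*) = E[Y^a | X*, S = 0]`, the
#' conditional mean of the potential outcome under treatment `a`, given the
#' reduced covariate set `X*`, in the population underlying the observational
#' study. Identification gives an iterated expectation
#' `E[ E[Y | X, cell] | X*, S = 0 ]` whose inner cell depends on the
#' analysis, so estimation is a two-step procedure:
#'
#' 1. regress `Y` on the full covariate vector `X` within the analysis cell —
#'    `(S=0, A=a)` for the observational analysis, `(S=1, A=a)` for the
#'    transportability analysis, all `A=a` rows for the joint analysis;
#' 2. predict from that model for **every** observational (`S=0`) row
#'    regardless of its actual treatment, and regress those predictions on
#'    `X*` among the `S=0` rows (squared-error regression throughout).
#'
#' @param ds An `msdata` object.
#' @param a Treatment level (0 or 1).
#' @param analysis `"observational"`, `"transportability"`, or `"joint"`.
#' @param learner1 Learner for step 1 (full-`X` outcome regression).
#' @param learner2 Learner for step 2 (`X*` regression among `S=0`).
#' @return A `cfr_tailored` object with a [predict()] method taking `X*`
#'   rows.
#' @examples
#' cfg <- sim_config(n0 = 400, n1 = 400, seed = 2)
#' sim <- simulate_multisource(cfg)
#' m <- fit_tailored(sim$observed, a = 1, analysis = "joint")
#' predict(m, data.frame(X = c(-1, 0, 1)))
#' @export
fit_tailored <- function(ds, a, analysis,
                         learner1 = cfrisk::learner("linear"),
                         learner2 = cfrisk::learner("linear")) {
  stopifnot(inherits(ds, "msdata"), is_learner(learner1), is_learner(learner2))
  analysis <- match_analysis(analysis)
  validate_cells(ds, a, analysis)
  if (length(ds$xstar_columns) == 0) stop_domain("xstar designation is empty")

  idx <- switch(analysis,
                observational = which(ds$S == 0L & ds$A == a),
                transportability = which(ds$S == 1L & ds$A == a),
                joint = which(ds$A == a))
  step1 <- fit_learner(learner1, ds$X[idx, , drop = FALSE], ds$Y[idx],
                       family = "gaussian")
  s0 <- which(ds$S == 0L)
  pred1 <- predict_learner(step1, ds$X[s0, , drop = FALSE])
  step2 <- fit_learner(learner2, xstar_matrix(ds, s0), pred1,
                       family = "gaussian")
  structure(
    list(a = a, analysis = analysis, step1_model = step1, step2_model = step2,
         xstar_columns = ds$xstar_columns, columns = colnames(ds$X),
         n_cell = length(idx), n_target = length(s0),
         fitted_values = predict_learner(step2, xstar_matrix(ds, s0))),
    class = "cfr_tailored"
  )
}

#' Predict from a tailored model
#' @param object A `cfr_tailored` model.
#' @param newdata Data frame or matrix whose columns include the model's
#'   `X*` columns (extra columns are ignored; a column mismatch is a schema
#'   error).
#' @param ... Unused.
#' @return Numeric vector of `mu_a(x*)` predictions, in row order.
#' @export
predict.cfr_tailored <- function(object, newdata, ...) {
  m <- as_x_matrix(newdata, object$xstar_columns)
  predict_learner(object$step2_model, m)
}

#' @export
print.cfr_tailored <- function(x, ...) {
  cat("<tailored model> mu_", x$a, "(X*) via ", x$analysis, " analysis\n",
      "  step-1 cell n = ", x$n_cell, "; step-2 target n = ", x$n_target, "\n",
      "  X*: ", paste(x$xstar_columns, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy cfr_tailored
#' @export
tidy.cfr_tailored <- function(x, ...) {
  if (x$step2_model$kind %in% c("linear", "logistic")) {
    co <- x$step2_model$fitted$coef
    tibble::tibble(term = names(co), estimate = unname(co))
  } else {
    tibble::tibble(term = character(0), estimate = numeric(0))
  }
}

#' @method glance cfr_tailored
#' @export
glance.cfr_tailored <- function(x, ...) {
  tibble::tibble(a = x$a, analysis = x$analysis,
                 n_cell = x$n_cell, n_target = x$n_target,
                 step1 = x$step1_model$kind, step2 = x$step2_model$kind)
}
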