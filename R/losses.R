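#' Wrap an arbitrary prediction model g(X*)
#'
#' The model under evaluation is opaque to cfrisk: anything that maps rows of
#' the designated covariate subset `X*` to a numeric prediction. The contract
#' requires deterministic predictions and that the data used to train `g` be
#' disjoint from the rows used to evaluate it (recorded, not enforced, via
#' `training_provenance`).
#'
#' @param predict_fn Function taking a data frame (or matrix) of `X*` columns
#'   and returning a numeric vector of predictions.
#' @param description Free-text description.
#' @param training_provenance Identifier for the data `g` was trained on.
#' @return A `prediction_model`.
#' @examples
#' g <- prediction_model(function(x) 1 + x[["X"]], "true outcome model")
#' @export
prediction_model <- function(predict_fn, description = "",
                             training_provenance = NA_character_) {
  stopifnot(is.function(predict_fn))
  structure(list(predict = predict_fn, description = description,
                 training_provenance = training_provenance),
            class = "prediction_model")
}

#' @export
print.prediction_model <- function(x, ...) {
  cat("<prediction_model> ", x$description, "\n", sep = "")
  invisible(x)
}

#' @export
predict.prediction_model <- function(object, newdata, ...) {
  p <- as.numeric(object$predict(as.data.frame(newdata)))
  if (length(p) != nrow(as.data.frame(newdata))) {
    stop_domain("prediction model returned the wrong number of predictions")
  }
  p
}

loss_fun <- function(loss) {
  loss <- rlang::arg_match0(loss, c("squared_error", "brier", "absolute"))
  switch(loss,
         squared_error = function(y, g) (y - g)^2,
         absolute = function(y, g) abs(y - g),
         brier = function(y, g) (y - g)^2)
}

#' Per-row losses L(Y, g(X*)) for every row of a dataset
#'
#' Evaluates the prediction model on each row's `X*` and applies the loss.
#' Squared error and Brier loss are `(y - g)^2` (Brier additionally requires
#' a binary outcome and predictions in `[0, 1]`); absolute loss is
#' `|y - g|`.
#'
#' @param ds An `msdata` object.
#' @param model A [prediction_model()].
#' @param loss One of `"squared_error"`, `"brier"`, `"absolute"`.
#' @return Numeric vector of length `ds$n`, in row order.
#' @export
compute_losses <- function(ds, model, loss = "squared_error") {
  stopifnot(inherits(ds, "msdata"), inherits(model, "prediction_model"))
  f <- loss_fun(loss)
  g <- predict(model, as.data.frame(xstar_matrix(ds)))
  if (!all(is.finite(g))) stop_domain("prediction model produced non-finite values")
  if (loss == "brier") {
    if (!all(ds$Y %in% c(0, 1))) {
      stop_domain("Brier loss requires a binary (0/1) outcome")
    }
    if (any(g < 0 | g > 1)) {
      stop_domain("Brier loss requires predictions in [0, 1]")
    }
  }
  f(ds$Y, g)
}
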