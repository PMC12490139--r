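#' Estimate the counterfactual risk of a prediction model
#'
#' Estimates `psi(a) = E[L(Y^a, g(X*)) | S = 0]`, the expected loss of the
#' model `g` in the population underlying the observational study had
#' everyone received treatment `a`, under one of three analyses:
#'
#' * **observational** — identifies `psi(a)` through the conditional loss in
#'   the observational study, `E[E[L | X, S=0, A=a] | S=0]`, relying on no
#'   unmeasured confounding within the observational source.
#' * **transportability** — identifies it through the trial,
#'   `E[E[L | X, S=1, A=a] | S=0]`, relying on exchangeability of the two
#'   populations given `X`; it never uses outcome or treatment information
#'   from the observational rows.
#' * **joint** — pools both sources, `E[E[L | X, A=a] | S=0]`, valid when
#'   both assumption sets hold, in which case it is the most efficient.
#'
#' Three estimator families are available: outcome-model (`"om"`, a plug-in
#' average of the fitted conditional-loss regression over the target sample),
#' inverse-probability weighting (`"ipw"`), and doubly robust (`"dr"`, the
#' augmented combination, consistent if either the loss regression or the
#' weight models are correctly specified).
#'
#' @param ds An `msdata` object.
#' @param model A [prediction_model()]. Alternatively supply `losses`
#'   directly.
#' @param loss Loss name, see [compute_losses()].
#' @param a Treatment level (0 or 1).
#' @param analysis `"observational"`, `"transportability"`, or `"joint"`.
#' @param estimator `"om"`, `"ipw"`, or `"dr"`.
#' @param normalization `"hajek"` (default; divides weighted sums by the sum
#'   of the weights, so a constant loss is recovered exactly and estimates
#'   are bounded by the loss range) or `"ht"` (Horvitz–Thompson `1/n0`
#'   scaling, the form in which the estimators are usually displayed).
#' @param nuis Optional pre-fitted `nuisance_set` (must match `a`); fitted
#'   on the fly otherwise.
#' @param losses Optional per-row loss vector, bypassing `model`/`loss`.
#' @param joint_residuals For the joint doubly robust estimator: use residual
#'   corrections from `"both"` sources (default) or from the `"trial"` only.
#' @param ... Passed to [fit_nuisances()] when `nuis` is `NULL`
#'   (e.g. `loss_learner`, `propensity_learner`, `clip_bounds`,
#'   `trial_assignment_prob`, `cross_fit`, `seed`).
#' @return A one-row tibble with columns `a`, `analysis`, `estimator`,
#'   `normalization`, `estimate`, and `n_target` (= `n0`).
#' @examples
#' cfg <- sim_config(n0 = 300, n1 = 300, seed = 1)
#' sim <- simulate_multisource(cfg)
#' g <- true_outcome_model(cfg, a = 1)
#' estimate_risk(sim$observed, g, a = 1, analysis = "transportability")
#' @export
estimate_risk <- function(ds, model = NULL, loss = "squared_error", a = 1,
                          analysis = "observational", estimator = "om",
                          normalization = "hajek", nuis = NULL, losses = NULL,
                          joint_residuals = "both", ...) {
  analysis <- match_analysis(analysis)
  estimator <- match_estimator(estimator)
  normalization <- match_normalization(normalization)
  validate_cells(ds, a, analysis)
  if (is.null(losses)) {
    if (is.null(model)) stop_domain("supply either `model` or `losses`")
    losses <- compute_losses(ds, model, loss)
  }
  if (is.null(nuis)) {
    nuis <- fit_nuisances(ds, losses, a, analyses = analysis,
                          estimators = estimator, ...)
  } else if (!identical(nuis$a, a)) {
    stop_state("nuisance set was fitted for a different treatment level")
  }
  value <- risk_point(ds, losses, a, analysis, estimator, normalization, nuis,
                      joint_residuals)
  tibble::tibble(a = a, analysis = analysis, estimator = estimator,
                 normalization = normalization, estimate = value,
                 n_target = ds$n0)
}

# Pure arithmetic on the per-row nuisance predictions. The transportability
# branch only ever indexes losses and treatment at trial rows, so replacing
# Y/A on observational rows cannot change its output.
risk_point <- function(ds, losses, a, analysis, estimator, normalization, nuis,
                       joint_residuals = "both") {
  s0 <- ds$S == 0L
  n0 <- ds$n0
  pred <- nuis$pred
  need <- function(nm) {
    v <- pred[[nm]]
    if (is.null(v)) stop_state(paste0("nuisance component '", nm,
                                      "' was not fitted"))
    v
  }
  e_for <- function(e) if (a == 1) e else 1 - e

  om_term <- function(h) mean(h[s0])

  weights_for <- function() {
    switch(analysis,
      observational = {
        idx <- which(s0 & ds$A == a)
        list(idx = idx, w = 1 / clip_prob(e_for(need("e0"))[idx],
                                          nuis$clip_bounds))
      },
      transportability = {
        idx <- which(ds$S == 1L & ds$A == a)
        list(idx = idx,
             w = need("w")[idx] / clip_prob(e_for(need("e1"))[idx],
                                            nuis$clip_bounds))
      },
      joint = {
        idx <- which(ds$A == a)
        es <- ifelse(s0, need("e0"), need("e1"))
        mult <- ifelse(s0, 1, need("w"))
        list(idx = idx,
             w = mult[idx] / clip_prob(e_for(es)[idx], nuis$clip_bounds))
      })
  }

  check_clipping <- function(idx) {
    probs <- switch(analysis,
                    observational = e_for(need("e0"))[idx],
                    transportability = e_for(need("e1"))[idx],
                    joint = e_for(ifelse(s0, need("e0"), need("e1")))[idx])
    at_bound <- probs <= nuis$clip_bounds[1] | probs >= nuis$clip_bounds[2]
    if (length(idx) > 0 && mean(at_bound) > 0.10) {
      warn(paste0(round(100 * mean(at_bound)), "% of weighted rows have a ",
                  "propensity at the clipping bound; weights may be unstable"))
    }
  }

  if (estimator == "om") {
    h <- switch(analysis, observational = need("h0"),
                transportability = need("h1"), joint = need("hp"))
    return(om_term(h))
  }

  wl <- weights_for()
  check_clipping(wl$idx)
  if (estimator == "ipw") {
    sw <- sum(wl$w)
    if (normalization == "hajek") {
      if (sw <= 0) stop_estimability("zero weight sum in Hajek normalization")
      return(sum(wl$w * losses[wl$idx]) / sw)
    }
    return(sum(wl$w * losses[wl$idx]) / n0)
  }

  # doubly robust
  h <- switch(analysis, observational = need("h0"),
              transportability = need("h1"), joint = need("hp"))
  if (analysis == "joint" && identical(joint_residuals, "trial")) {
    keep <- ds$S[wl$idx] == 1L
    wl$idx <- wl$idx[keep]
    wl$w <- wl$w[keep]
  }
  resid <- losses[wl$idx] - h[wl$idx]
  corr <- if (normalization == "hajek") {
    sw <- sum(wl$w)
    if (sw <= 0) stop_estimability("zero weight sum in Hajek normalization")
    sum(wl$w * resid) / sw
  } else {
    sum(wl$w * resid) / n0
  }
  om_term(h) + corr
}

#' Estimate a grid of counterfactual risks
#'
#' Computes the full crossing of treatment levels, analyses, and estimator
#' families (up to 2 x 3 x 3 = 18 estimates) from shared nuisance fits — one
#' nuisance set per treatment level. Cells that fail (e.g. an empty
#' conditioning cell) are reported with `NA` and the error message rather
#' than aborting the rest of the grid.
#'
#' @inheritParams estimate_risk
#' @param a_levels Treatment levels, default `c(0, 1)`.
#' @param analyses Analyses to run.
#' @param estimators Estimator families to run.
#' @param nuis Optional named list of pre-fitted nuisance sets, one per
#'   treatment level (names `"0"`/`"1"`).
#' @return A tibble with one row per grid cell: `a`, `analysis`,
#'   `estimator`, `normalization`, `estimate`, `n_target`, `error`
#'   (`NA` on success).
#' @export
estimate_risk_table <- function(ds, model = NULL, loss = "squared_error",
                                a_levels = c(0, 1),
                                analyses = c("transportability", "observational", "joint"),
                                estimators = c("om", "ipw", "dr"),
                                normalization = "hajek", nuis = NULL,
                                losses = NULL, joint_residuals = "both", ...) {
  analyses <- vapply(analyses, match_analysis, character(1))
  estimators <- vapply(estimators, match_estimator, character(1))
  if (is.null(losses)) {
    if (is.null(model)) stop_domain("supply either `model` or `losses`")
    losses <- compute_losses(ds, model, loss)
  }
  rows <- list()
  for (a in a_levels) {
    na <- nuis[[as.character(a)]]
    if (is.null(na)) {
      na <- tryCatch(
        fit_nuisances(ds, losses, a, analyses = analyses,
                      estimators = estimators, ...),
        cfrisk_error = function(e) e
      )
    }
    for (an in analyses) for (est in estimators) {
      res <- tryCatch({
        if (inherits(na, "condition")) stop(na)
        validate_cells(ds, a, an)
        list(value = risk_point(ds, losses, a, an, est, normalization, na,
                                joint_residuals),
             err = NA_character_)
      }, error = function(e) list(value = NA_real_, err = conditionMessage(e)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        a = a, analysis = an, estimator = est, normalization = normalization,
        estimate = res$value, n_target = ds$n0, error = res$err
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cfr_risk_table", class(out))
  out
}
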