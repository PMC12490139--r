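#' Bundle a full risk-estimation recipe
#'
#' A `risk_spec` captures everything needed to recompute a risk estimate on
#' new data — the prediction model, loss, treatment level, analysis,
#' estimator family, normalization, and nuisance learner settings — so the
#' bootstrap can refit all nuisances inside every replicate.
#'
#' @inheritParams estimate_risk
#' @param loss_learner,propensity_learner,clip_bounds,trial_assignment_prob,cross_fit
#'   Passed to [fit_nuisances()] at (re)fit time.
#' @return A `cfr_risk_spec`.
#' @export
risk_spec <- function(model, loss = "squared_error", a = 1,
                      analysis = "observational", estimator = "om",
                      normalization = "hajek",
                      loss_learner = cfrisk::learner("linear"),
                      propensity_learner = cfrisk::learner("logistic"),
                      clip_bounds = c(0.001, 0.999),
                      trial_assignment_prob = NULL,
                      cross_fit = 0L, joint_residuals = "both") {
  structure(list(
    model = model, loss = loss, a = a,
    analysis = match_analysis(analysis),
    estimator = match_estimator(estimator),
    normalization = match_normalization(normalization),
    loss_learner = loss_learner, propensity_learner = propensity_learner,
    clip_bounds = clip_bounds, trial_assignment_prob = trial_assignment_prob,
    cross_fit = cross_fit, joint_residuals = joint_residuals
  ), class = "cfr_risk_spec")
}

# Evaluate a spec on a dataset: refit nuisances, return the point estimate.
eval_risk_spec <- function(spec, ds, losses = NULL) {
  if (is.null(losses)) losses <- compute_losses(ds, spec$model, spec$loss)
  nuis <- fit_nuisances(ds, losses, spec$a, analyses = spec$analysis,
                        estimators = spec$estimator,
                        loss_learner = spec$loss_learner,
                        propensity_learner = spec$propensity_learner,
                        clip_bounds = spec$clip_bounds,
                        trial_assignment_prob = spec$trial_assignment_prob,
                        cross_fit = spec$cross_fit)
  risk_point(ds, losses, spec$a, spec$analysis, spec$estimator,
             spec$normalization, nuis, spec$joint_residuals)
}

# Source-stratified resample: n0 rows drawn with replacement from S=0 and n1
# from S=1, so every replicate preserves the non-nested design's per-source
# sample sizes exactly.
resample_stratified <- function(ds) {
  i0 <- which(ds$S == 0L)
  i1 <- which(ds$S == 1L)
  idx <- c(i0[sample.int(length(i0), replace = TRUE)],
           i1[sample.int(length(i1), replace = TRUE)])
  subset_msdata(ds, idx)
}

subset_msdata <- function(ds, idx) {
  new_msdata(ds$Y[idx], ds$A[idx], ds$S[idx], ds$X[idx, , drop = FALSE],
             ds$xstar_columns)
}

#' Bootstrap a risk estimate
#'
#' Nonparametric bootstrap stratified by source: each replicate resamples
#' `n0` observational and `n1` trial rows with replacement, refits every
#' nuisance model, and recomputes the estimate. A replicate that fails for
#' estimability reasons (e.g. an empty resampled cell) is retried with a
#' fresh resample up to `max_retries` times, then counted as failed.
#'
#' @param ds An `msdata` object.
#' @param spec A [risk_spec()].
#' @param B Number of bootstrap replicates (default 500).
#' @param seed Integer seed; `(seed, B, data)` fully determine the output.
#' @param ci_method `"wald"` (point estimate ± z · bootstrap SE, the default)
#'   or `"percentile"` (empirical quantiles of the replicates).
#' @param level Nominal coverage, default 0.95.
#' @param max_retries Resample retries per failed replicate (default 10).
#' @return A `cfr_boot` object: `point_estimate`, `replicate_values`, `se`,
#'   `ci`, `ci_method`, `level`, `B`, `seed`, `n_failed`. Has [tidy()] and
#'   [glance()] methods.
#' @export
bootstrap_estimate <- function(ds, spec, B = 500, seed = 1,
                               ci_method = c("wald", "percentile"),
                               level = 0.95, max_retries = 10) {
  stopifnot(inherits(ds, "msdata"), inherits(spec, "cfr_risk_spec"))
  ci_method <- match.arg(ci_method)
  point <- eval_risk_spec(spec, ds)
  reps <- with_seed_if(seed, boot_replicates(
    ds, B, max_retries, function(d) eval_risk_spec(spec, d)
  ))
  finalize_boot(point, reps, B, seed, ci_method, level)
}

# Shared replicate engine: fun(resampled ds) -> numeric (scalar or vector).
boot_replicates <- function(ds, B, max_retries, fun) {
  vals <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try in seq_len(max_retries + 1L)) {
      v <- tryCatch(fun(resample_stratified(ds)), cfrisk_error = function(e) NULL)
      if (!is.null(v) && all(is.finite(v))) { ok <- TRUE; break }
    }
    if (!ok) {
      n_failed <- n_failed + 1L
      v <- NULL
    }
    vals[[b]] <- v
  }
  list(values = vals, n_failed = n_failed)
}

finalize_boot <- function(point, reps, B, seed, ci_method, level) {
  vals <- unlist(reps$values[!vapply(reps$values, is.null, logical(1))])
  if (reps$n_failed > 0.05 * B) {
    warn(paste0(reps$n_failed, " of ", B,
                " bootstrap replicates failed after retries"))
  }
  se <- sd(vals)
  alpha <- 1 - level
  ci <- if (ci_method == "wald") {
    point + c(-1, 1) * qnorm(1 - alpha / 2) * se
  } else {
    unname(quantile(vals, c(alpha / 2, 1 - alpha / 2), type = 7))
  }
  structure(list(point_estimate = point, replicate_values = vals, se = se,
                 ci = ci, ci_method = ci_method, level = level, B = B,
                 seed = seed, n_failed = reps$n_failed),
            class = "cfr_boot")
}

#' @export
print.cfr_boot <- function(x, ...) {
  cat("<bootstrap estimate> ", signif(x$point_estimate, 5),
      "  (se ", signif(x$se, 4), ")\n",
      "  ", 100 * x$level, "% ", x$ci_method, " CI: [",
      signif(x$ci[1], 5), ", ", signif(x$ci[2], 5), "]  B = ", x$B,
      if (x$n_failed > 0) paste0("  (", x$n_failed, " failed)") else "",
      "\n", sep = "")
  invisible(x)
}

#' @method tidy cfr_boot
#' @export
tidy.cfr_boot <- function(x, ...) {
  tibble::tibble(estimate = x$point_estimate, std.error = x$se,
                 conf.low = x$ci[1], conf.high = x$ci[2],
                 conf.level = x$level, ci_method = x$ci_method)
}

#' @method glance cfr_boot
#' @export
glance.cfr_boot <- function(x, ...) {
  tibble::tibble(B = x$B, n_failed = x$n_failed, seed = x$seed)
}

#' Benchmark the observational analysis against the transportability analysis
#'
#' Benchmarking compares the estimate built from the observational study
#' against the estimate transported from the trial. Concordance (a
#' confidence interval for their difference containing zero) supports — but
#' can never prove — the identifying assumptions, since both analyses could
#' be biased in the same direction by a similar amount. The paired
#' difference `delta = psi_obs - psi_tr` is bootstrapped with both analyses
#' computed on the *same* resampled rows within each replicate, so the CI
#' reflects only estimator disagreement.
#'
#' @inheritParams bootstrap_estimate
#' @param model A [prediction_model()].
#' @param loss Loss name.
#' @param a Treatment level.
#' @param estimator Estimator family used for both analyses.
#' @param normalization Weight normalization for `ipw`/`dr`.
#' @param ... Passed to [risk_spec()] (learners, clipping, ...).
#' @return A `cfr_benchmark`: `delta`, `psi_obs`, `psi_tr`, `ci`,
#'   `concordant` (CI contains 0), `level`, plus the bootstrap metadata.
#' @export
benchmark <- function(ds, model, loss = "squared_error", a = 1,
                      estimator = "om", normalization = "hajek",
                      B = 500, seed = 1, level = 0.95,
                      ci_method = c("wald", "percentile"), max_retries = 10,
                      ...) {
  ci_method <- match.arg(ci_method)
  spec_obs <- risk_spec(model, loss, a, "observational", estimator,
                        normalization, ...)
  spec_tr <- risk_spec(model, loss, a, "transportability", estimator,
                       normalization, ...)
  pair <- function(d) {
    losses <- compute_losses(d, model, loss)
    eval_risk_spec(spec_obs, d, losses) - eval_risk_spec(spec_tr, d, losses)
  }
  losses0 <- compute_losses(ds, model, loss)
  psi_obs <- eval_risk_spec(spec_obs, ds, losses0)
  psi_tr <- eval_risk_spec(spec_tr, ds, losses0)
  delta <- psi_obs - psi_tr
  reps <- with_seed_if(seed, boot_replicates(ds, B, max_retries, pair))
  boot <- finalize_boot(delta, reps, B, seed, ci_method, level)
  structure(list(delta = delta, psi_obs = psi_obs, psi_tr = psi_tr,
                 ci = boot$ci, se = boot$se,
                 concordant = boot$ci[1] <= 0 && 0 <= boot$ci[2],
                 level = level, ci_method = ci_method, B = B, seed = seed,
                 n_failed = boot$n_failed,
                 replicate_values = boot$replicate_values,
                 narrative = paste(
                   "Concordance between the observational and transportability",
                   "estimates supports the identifying assumptions but does not",
                   "guarantee validity: both could be biased in the same",
                   "direction by similar amounts. Judgment should also draw on",
                   "subject-matter knowledge.")),
            class = "cfr_benchmark")
}

#' @export
print.cfr_benchmark <- function(x, ...) {
  cat("<benchmark> psi_obs - psi_tr = ", signif(x$delta, 5), "\n",
      "  psi_obs = ", signif(x$psi_obs, 5), ", psi_tr = ",
      signif(x$psi_tr, 5), "\n",
      "  ", 100 * x$level, "% ", x$ci_method, " CI: [", signif(x$ci[1], 5),
      ", ", signif(x$ci[2], 5), "]  -> ",
      if (x$concordant) "concordant" else "NOT concordant", "\n", sep = "")
  cat("  note: ", x$narrative, "\n", sep = "")
  invisible(x)
}

#' @method tidy cfr_benchmark
#' @export
tidy.cfr_benchmark <- function(x, ...) {
  tibble::tibble(delta = x$delta, psi_obs = x$psi_obs, psi_tr = x$psi_tr,
                 std.error = x$se, conf.low = x$ci[1], conf.high = x$ci[2],
                 conf.level = x$level, concordant = x$concordant)
}

#' @method glance cfr_benchmark
#' @export
glance.cfr_benchmark <- function(x, ...) {
  tibble::tibble(B = x$B, n_failed = x$n_failed, seed = x$seed,
                 ci_method = x$ci_method)
}
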