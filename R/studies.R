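# Simulation studies: bias quadrants under selective assumption violations,
# the joint-analysis efficiency comparison, and an end-to-end demonstration
# on a binary outcome with a fitted random-forest model.

cfg_with <- function(cfg, ...) {
  do.call(sim_config, modifyList(unclass(cfg), list(...)))
}

draw_subseeds <- function(seed, n) {
  with_seed_if(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Truth for a study cell: closed form when available, MC oracle otherwise.
study_truth <- function(cfg, model, loss, a, seed, n_mc = 2e5) {
  if (is.null(model) && loss == "squared_error" && a == 1) {
    tibble::tibble(true_risk = closed_form_mse(cfg), mc_se = 0, n_mc = Inf)
  } else {
    true_risk(cfg, model, loss, a, n_mc = n_mc, seed = seed)
  }
}

# One simulated replicate -> named vector of estimates for the requested
# analyses. Shares one nuisance fit across analyses; uses the known trial
# randomization probability.
sim_estimates <- function(cfg, rep_seed, model, loss, a, analyses, estimator,
                          normalization = "hajek",
                          loss_learner = learner("linear"),
                          propensity_learner = learner("logistic")) {
  sim <- simulate_multisource(cfg_with(cfg, seed = rep_seed))
  ds <- sim$observed
  g <- model %||% true_outcome_model(cfg, a)
  losses <- compute_losses(ds, g, loss)
  nuis <- fit_nuisances(ds, losses, a, analyses = analyses,
                        estimators = estimator,
                        loss_learner = loss_learner,
                        propensity_learner = propensity_learner,
                        trial_assignment_prob = cfg$trial_assignment_prob)
  vapply(analyses, function(an) {
    risk_point(ds, losses, a, an, estimator, normalization, nuis)
  }, numeric(1))
}

#' Bias study across assumption-violation cases
#'
#' For each configuration in the case grid, simulates `n_sims` datasets,
#' computes the observational and transportability risk estimates, and
#' reports their relative bias `(mean estimate - truth) / truth` against the
#' oracle truth. [autoplot()] renders the quadrant scatter (transportability
#' bias on the x-axis, observational bias on the y-axis).
#'
#' @param case_grid Named list of [sim_config()]s, e.g. [canonical_cases()].
#' @param n_sims Simulated datasets per case (default 500).
#' @param estimator Estimator family (`"om"`, `"ipw"`, `"dr"`).
#' @param model Optional [prediction_model()]; default is each case's true
#'   outcome model, for which the truth is closed-form.
#' @param loss,a Loss and treatment level.
#' @param seed Master seed; replicate seeds are derived from it.
#' @param loss_learner,propensity_learner Nuisance learners.
#' @return A `cfr_bias_grid` tibble: one row per case with `truth`,
#'   `mean_obs`, `mean_tr`, `rel_bias_obs`, `rel_bias_tr`, Monte-Carlo
#'   standard errors of the relative biases, and failure counts.
#' @export
run_bias_grid <- function(case_grid, n_sims = 500, estimator = "om",
                          model = NULL, loss = "squared_error", a = 1,
                          seed = 1,
                          loss_learner = cfrisk::learner("linear"),
                          propensity_learner = cfrisk::learner("logistic")) {
  stopifnot(is.list(case_grid), length(case_grid) > 0)
  if (is.null(names(case_grid))) {
    names(case_grid) <- paste0("case", seq_along(case_grid))
  }
  seeds <- matrix(draw_subseeds(seed, n_sims * length(case_grid)),
                  ncol = length(case_grid))
  rows <- purrr::imap(case_grid, function(cfg, nm) {
    j <- match(nm, names(case_grid))
    tr <- study_truth(cfg, model, loss, a, seed = seeds[1, j])
    est <- matrix(NA_real_, n_sims, 2)
    failed <- 0L
    for (i in seq_len(n_sims)) {
      v <- tryCatch(
        sim_estimates(cfg, seeds[i, j], model, loss, a,
                      c("observational", "transportability"), estimator,
                      loss_learner = loss_learner,
                      propensity_learner = propensity_learner),
        cfrisk_error = function(e) NULL)
      if (is.null(v)) failed <- failed + 1L else est[i, ] <- v
    }
    ok <- stats::complete.cases(est)
    m <- colMeans(est[ok, , drop = FALSE])
    se <- apply(est[ok, , drop = FALSE], 2, sd) / sqrt(sum(ok))
    tibble::tibble(
      case = nm, n0 = cfg$n0, n1 = cfg$n1, n_sims = sum(ok),
      n_failed = failed, truth = tr$true_risk,
      mean_obs = m[1], mean_tr = m[2],
      rel_bias_obs = (m[1] - tr$true_risk) / tr$true_risk,
      rel_bias_tr = (m[2] - tr$true_risk) / tr$true_risk,
      mc_se_rel_obs = se[1] / tr$true_risk,
      mc_se_rel_tr = se[2] / tr$true_risk
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cfr_bias_grid", class(out))
  out
}

#' Efficiency comparison of the three analyses
#'
#' Under a configuration where all identifying assumptions hold, simulates
#' `n_sims` datasets at each `(n0, n1)` in the grid and reports the
#' empirical mean, bias, and variance of the observational,
#' transportability, and joint estimators. When the assumptions hold the
#' joint analysis uses strictly more data for its conditional-loss
#' regression and its variance is expected to be no larger than either
#' single-source analysis.
#'
#' @param cfg A [sim_config()] whose violation knobs are all zero (a config
#'   with violations triggers a warning unless `allow_violations = TRUE`).
#' @param n_sims Replicates per grid cell (default 500).
#' @param sample_size_grid List of `c(n0, n1)` pairs.
#' @inheritParams run_bias_grid
#' @param allow_violations Set `TRUE` to suppress the no-violation check.
#' @return A `cfr_variance_study` tibble: one row per cell and analysis with
#'   `mean`, `bias`, `variance`.
#' @export
run_variance_study <- function(cfg, n_sims = 500,
                               sample_size_grid = list(c(1000, 1000)),
                               estimator = "om", model = NULL,
                               loss = "squared_error", a = 1, seed = 1,
                               allow_violations = FALSE,
                               loss_learner = cfrisk::learner("linear"),
                               propensity_learner = cfrisk::learner("logistic")) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!allow_violations &&
      (cfg$beta_AU != 0 || cfg$mu_YU != 0 || cfg$sigma_YU != 0)) {
    warn("variance study config has non-zero violation knobs; estimator means may be biased")
  }
  analyses <- c("observational", "transportability", "joint")
  seeds <- matrix(draw_subseeds(seed, n_sims * length(sample_size_grid)),
                  ncol = length(sample_size_grid))
  rows <- purrr::imap(sample_size_grid, function(nn, j) {
    cfg_j <- cfg_with(cfg, n0 = nn[1], n1 = nn[2])
    tr <- study_truth(cfg_j, model, loss, a, seed = seeds[1, j])
    est <- matrix(NA_real_, n_sims, 3)
    for (i in seq_len(n_sims)) {
      v <- tryCatch(
        sim_estimates(cfg_j, seeds[i, j], model, loss, a, analyses, estimator,
                      loss_learner = loss_learner,
                      propensity_learner = propensity_learner),
        cfrisk_error = function(e) NULL)
      if (!is.null(v)) est[i, ] <- v
    }
    ok <- stats::complete.cases(est)
    tibble::tibble(
      n0 = nn[1], n1 = nn[2], analysis = analyses, n_sims = sum(ok),
      truth = tr$true_risk,
      mean = colMeans(est[ok, , drop = FALSE]),
      bias = colMeans(est[ok, , drop = FALSE]) - tr$true_risk,
      variance = apply(est[ok, , drop = FALSE], 2, var)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cfr_variance_study", class(out))
  out
}

#' End-to-end demonstration: random-forest model, Brier risk, full grid
#'
#' Mirrors a realistic deployment evaluation on a binary endpoint: the
#' simulated outcome is dichotomized at `threshold`; the observational rows
#' are split 50/50 into a training and an evaluation half; a random forest
#' `g(X*)` is fit on the training half; and the full grid of
#' 2 treatments x 3 analyses x 3 estimator families is computed on the
#' evaluation half plus all trial rows, each with a stratified-bootstrap
#' Wald confidence interval (one shared set of `B` resamples for the whole
#' grid). [autoplot()] renders the forest plot.
#'
#' @param cfg A [sim_config()] for the source data.
#' @param seed Seed controlling the split, forest, and bootstrap.
#' @param B Bootstrap replicates (default 500).
#' @param train_frac Fraction of observational rows used to train `g`.
#' @param threshold Dichotomization threshold for the outcome (default 1,
#'   near the overall median of the default generator).
#' @param num.trees Trees in the random forest.
#' @param level Confidence level.
#' @return A `cfr_cass_demo`: tibble grid with `estimate`, `se`,
#'   `conf.low`, `conf.high` per cell, plus attributes recording the setup.
#' @export
run_cass_style_demo <- function(cfg, seed = 1, B = 500, train_frac = 0.5,
                                threshold = 1, num.trees = 500,
                                level = 0.95) {
  stopifnot(inherits(cfg, "sim_config"))
  sim <- binarize_sim(simulate_multisource(cfg_with(cfg, seed = seed)),
                      threshold)
  ds <- sim$observed
  i0 <- which(ds$S == 0L)
  n_train <- floor(train_frac * length(i0))
  train_idx <- with_seed_if(seed, sample(i0, n_train))
  eval_idx <- sort(c(setdiff(i0, train_idx), which(ds$S == 1L)))

  rf <- fit_learner(learner("random_forest", num.trees = num.trees,
                            seed = seed),
                    xstar_matrix(ds, train_idx), ds$Y[train_idx],
                    family = "binomial")
  g <- prediction_model(
    function(x) predict_learner(rf, as.matrix(x)),
    description = "random forest fit on the observational training half",
    training_provenance = "S=0 training split"
  )
  eval_ds <- subset_msdata(ds, eval_idx)

  grid_fun <- function(d) {
    tab <- estimate_risk_table(
      d, model = g, loss = "brier", a_levels = c(0, 1),
      trial_assignment_prob = cfg$trial_assignment_prob
    )
    setNames(tab$estimate, paste(tab$a, tab$analysis, tab$estimator, sep = "."))
  }
  point <- grid_fun(eval_ds)
  reps <- with_seed_if(seed, boot_replicates(eval_ds, B, 10, grid_fun))
  mat <- do.call(rbind, reps$values[!vapply(reps$values, is.null, logical(1))])
  se <- apply(mat, 2, sd)
  z <- qnorm(1 - (1 - level) / 2)

  key <- do.call(rbind, strsplit(names(point), ".", fixed = TRUE))
  out <- tibble::tibble(
    a = as.integer(key[, 1]), analysis = key[, 2], estimator = key[, 3],
    estimate = unname(point), se = unname(se),
    conf.low = unname(point - z * se), conf.high = unname(point + z * se)
  )
  attr(out, "setup") <- list(seed = seed, B = B, level = level,
                             threshold = threshold, train_frac = train_frac,
                             n_eval0 = eval_ds$n0, n_trial = eval_ds$n1,
                             n_train = n_train, n_failed = reps$n_failed)
  class(out) <- c("cfr_cass_demo", class(out))
  out
}
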