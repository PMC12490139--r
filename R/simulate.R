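#' Configuration of the two-source synthetic data generator
#'
#' The generator emulates a randomized trial (`S=1`) alongside an
#' observational study (`S=0`) whose covariate distribution is shifted, with
#' an unmeasured covariate `U` whose role is controlled by three knobs that
#' selectively violate the identifying assumptions:
#'
#' * `beta_AU` — effect of `U` on the treatment log-odds in the
#'   observational source only. With `mu_YU > 0` this breaks conditional
#'   exchangeability of treatment groups in the observational study (no
#'   unmeasured confounding), biasing the observational analysis.
#' * `mu_YU` — effect of `U` on the mean of both potential outcomes, in both
#'   sources. On its own it is harmless extra outcome noise.
#' * `sigma_YU` — inflates the noise of `Y^1` through `U`, in the
#'   observational source only (`sd = sqrt(sigma_eps^2 + sigma_YU^2 U^2)`),
#'   breaking exchangeability of the two populations for the squared-error
#'   risk functional and biasing the transportability analysis downward.
#'
#' Per row of source `s`: `X ~ N(mu_X0 * I(s=0), 1)`, `U ~ N(0,1)`
#' independent of `X`; `A ~ Bernoulli(trial_assignment_prob)` in the trial,
#' else `Bernoulli(plogis(alpha_0 + alpha_X X + beta_AU U))`;
#' `Y^1 = gamma_0 + gamma_X X + mu_YU U + e1`,
#' `Y^0 = delta_0 + delta_X X + mu_YU U + e0` with `e0 ~ N(0, sigma_eps)`;
#' `Y = A Y^1 + (1-A) Y^0` (consistency holds by construction).
#'
#' @param n0,n1 Per-source sample sizes.
#' @param beta_AU,mu_YU,sigma_YU Violation knobs, all default 0 (no
#'   violations).
#' @param sigma_eps Baseline outcome noise SD (default 1).
#' @param mu_X0 Mean shift of `X` in the observational source (default 0.5;
#'   trial mean 0), making transport weighting non-trivial; 0 gives
#'   identical populations.
#' @param alpha_0,alpha_X Observational treatment-model intercept and `X`
#'   slope (defaults 0 and 0.3).
#' @param gamma_0,gamma_X Mean coefficients of `Y^1` (defaults 1, 1).
#' @param delta_0,delta_X Mean coefficients of `Y^0` (defaults 0, 1).
#' @param trial_assignment_prob Trial randomization probability (default
#'   0.5).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n0 = 2000, n1 = 2000, beta_AU = 0, mu_YU = 0,
                       sigma_YU = 0, sigma_eps = 1, mu_X0 = 0.5,
                       alpha_0 = 0, alpha_X = 0.3, gamma_0 = 1, gamma_X = 1,
                       delta_0 = 0, delta_X = 1, trial_assignment_prob = 0.5,
                       seed = 1) {
  cfg <- list(n0 = as.integer(n0), n1 = as.integer(n1), beta_AU = beta_AU,
              mu_YU = mu_YU, sigma_YU = sigma_YU, sigma_eps = sigma_eps,
              mu_X0 = mu_X0, alpha_0 = alpha_0, alpha_X = alpha_X,
              gamma_0 = gamma_0, gamma_X = gamma_X, delta_0 = delta_0,
              delta_X = delta_X,
              trial_assignment_prob = trial_assignment_prob,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n0 < 1 || cfg$n1 < 1) stop_domain("n0 and n1 must both be >= 1")
  if (cfg$sigma_eps <= 0) stop_domain("sigma_eps must be > 0")
  if (cfg$sigma_YU < 0) stop_domain("sigma_YU must be >= 0")
  if (cfg$trial_assignment_prob <= 0 || cfg$trial_assignment_prob >= 1) {
    stop_domain("trial_assignment_prob must be in (0, 1)")
  }
  invisible(cfg)
}

#' Simulate a two-source dataset
#'
#' Draws one dataset from the generator described in [sim_config()]. The
#' observed part is returned as a validated [multisource_data()] container
#' holding only `(Y, A, S, X)`; the latent `U` and both potential outcomes
#' live in a separate `oracle` tibble that no estimator code path can reach
#' through the dataset object.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_dataset`: list with `observed` (`msdata`), `oracle`
#'   (tibble with `U`, `Y0`, `Y1`), and `config`.
#' @export
simulate_multisource <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  with_seed_if(cfg$seed, {
    n <- cfg$n0 + cfg$n1
    S <- c(rep(0L, cfg$n0), rep(1L, cfg$n1))
    X <- rnorm(n, mean = cfg$mu_X0 * (S == 0L), sd = 1)
    U <- rnorm(n)
    pA <- ifelse(S == 1L, cfg$trial_assignment_prob,
                 expit(cfg$alpha_0 + cfg$alpha_X * X + cfg$beta_AU * U))
    A <- rbinom(n, 1L, pA)
    sd1 <- sqrt(cfg$sigma_eps^2 + cfg$sigma_YU^2 * U^2 * (S == 0L))
    Y1 <- cfg$gamma_0 + cfg$gamma_X * X + cfg$mu_YU * U + rnorm(n, 0, sd1)
    Y0 <- cfg$delta_0 + cfg$delta_X * X + cfg$mu_YU * U +
      rnorm(n, 0, cfg$sigma_eps)
    Y <- A * Y1 + (1L - A) * Y0
    Xm <- matrix(X, ncol = 1, dimnames = list(NULL, "X"))
    structure(
      list(observed = new_msdata(Y, as.integer(A), S, Xm, "X"),
           oracle = tibble::tibble(U = U, Y0 = Y0, Y1 = Y1),
           config = cfg),
      class = "sim_dataset"
    )
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> knobs: beta_AU=", x$config$beta_AU,
      ", mu_YU=", x$config$mu_YU, ", sigma_YU=", x$config$sigma_YU,
      "; seed=", x$config$seed, "\n", sep = "")
  print(x$observed)
  invisible(x)
}

#' The generator's true conditional outcome model
#'
#' Returns `E[Y^a | X]` as a [prediction_model()] — the default `g` for the
#' bias and efficiency studies, for which the squared-error counterfactual
#' risk has the closed form [closed_form_mse()].
#'
#' @param cfg A [sim_config()].
#' @param a Treatment level.
#' @return A `prediction_model`.
#' @export
true_outcome_model <- function(cfg, a = 1) {
  stopifnot(inherits(cfg, "sim_config"), a %in% c(0, 1))
  b0 <- if (a == 1) cfg$gamma_0 else cfg$delta_0
  b1 <- if (a == 1) cfg$gamma_X else cfg$delta_X
  prediction_model(function(x) b0 + b1 * x[["X"]],
                   description = paste0("true E[Y^", a, " | X]"))
}

#' Closed-form counterfactual MSE of the true outcome model
#'
#' For squared error, `a = 1`, and `g(x) = gamma_0 + gamma_X x`, the risk in
#' the target population is `mu_YU^2 + sigma_eps^2 + sigma_YU^2`, since `U`
#' has unit variance and `E[U^2] = 1`.
#'
#' @param cfg A [sim_config()].
#' @return The true risk (a number).
#' @export
closed_form_mse <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$mu_YU^2 + cfg$sigma_eps^2 + cfg$sigma_YU^2
}

#' Oracle counterfactual risk by Monte Carlo
#'
#' Draws fresh rows from the target (`S=0`) arm of the generator, evaluates
#' the loss against the *potential outcome* `Y^a` directly, and returns the
#' Monte-Carlo mean and its standard error. This is the ground truth the
#' estimator studies compare against; for the special case covered by
#' [closed_form_mse()] the two agree.
#'
#' @param cfg A [sim_config()].
#' @param model A [prediction_model()]; default the true outcome model.
#' @param loss Loss name.
#' @param a Treatment level.
#' @param n_mc Number of Monte-Carlo draws (default 1e5).
#' @param seed Seed for the oracle draws.
#' @return A one-row tibble with `true_risk`, `mc_se`, `n_mc`.
#' @export
true_risk <- function(cfg, model = NULL, loss = "squared_error", a = 1,
                      n_mc = 1e5, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  if (is.null(model)) model <- true_outcome_model(cfg, a)
  f <- loss_fun(loss)
  with_seed_if(seed, {
    X <- rnorm(n_mc, mean = cfg$mu_X0, sd = 1)
    U <- rnorm(n_mc)
    if (a == 1) {
      sd1 <- sqrt(cfg$sigma_eps^2 + cfg$sigma_YU^2 * U^2)
      Ya <- cfg$gamma_0 + cfg$gamma_X * X + cfg$mu_YU * U + rnorm(n_mc, 0, sd1)
    } else {
      Ya <- cfg$delta_0 + cfg$delta_X * X + cfg$mu_YU * U +
        rnorm(n_mc, 0, cfg$sigma_eps)
    }
    g <- predict(model, data.frame(X = X))
    l <- f(Ya, g)
    tibble::tibble(true_risk = mean(l), mc_se = sd(l) / sqrt(n_mc),
                   n_mc = n_mc)
  })
}

#' The four canonical assumption-violation cases
#'
#' A ready-made case grid for [run_bias_grid()]:
#'
#' * **Case 1** — no violations (`beta_AU = mu_YU = sigma_YU = 0`): both
#'   analyses unbiased.
#' * **Case 2** — `sigma_YU = 1` only: the trial misses the target
#'   population's extra `Y^1` noise, so the transportability analysis
#'   underestimates the MSE by `sigma_YU^2 / (sigma_eps^2 + sigma_YU^2)`
#'   relative; the observational analysis is unbiased.
#' * **Case 3** — `beta_AU = 2, mu_YU = 2`: unmeasured confounding in the
#'   observational source biases the observational analysis; the
#'   transportability analysis is unbiased.
#' * **Case 4** — all three knobs on: both analyses biased.
#'
#' All four cases share an asymmetric confounded-treatment intercept
#' `alpha_0 = -1.5` (treatment uncommon, P(A=1) about 0.31, and selectively
#' taken up), chosen so that when confounding is switched on it moves the
#' second moment of `U` among the treated and produces a material
#' observational bias; a symmetric intercept would leave the squared-error
#' risk almost unbiased even under strong confounding.
#'
#' @param n0,n1 Per-source sample sizes for every case.
#' @param seed Base seed stored in each config.
#' @return Named list of four [sim_config()]s.
#' @export
canonical_cases <- function(n0 = 2000, n1 = 2000, seed = 1) {
  base <- function(...) sim_config(n0 = n0, n1 = n1, alpha_0 = -1.5,
                                   seed = seed, ...)
  list(
    case1 = base(),
    case2 = base(sigma_YU = 1),
    case3 = base(beta_AU = 2, mu_YU = 2),
    case4 = base(beta_AU = 2, mu_YU = 2, sigma_YU = 1)
  )
}

# Dichotomize a simulated dataset's outcome (and oracle potential outcomes)
# at a threshold, for Brier-loss analyses of a binary endpoint.
binarize_sim <- function(sim, threshold = 1) {
  obs <- sim$observed
  ds <- new_msdata(as.numeric(obs$Y > threshold), obs$A, obs$S, obs$X,
                   obs$xstar_columns)
  oracle <- tibble::tibble(U = sim$oracle$U,
                           Y0 = as.numeric(sim$oracle$Y0 > threshold),
                           Y1 = as.numeric(sim$oracle$Y1 > threshold))
  structure(list(observed = ds, oracle = oracle, config = sim$config,
                 threshold = threshold),
            class = "sim_dataset")
}
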