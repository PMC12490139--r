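# Fixtures are built in code. Losses throughout use g == 0 with squared
# error, so a loss of v is produced by an outcome of sqrt(v).

g_zero <- prediction_model(function(x) rep(0, nrow(x)), "constant zero")

# Discrete toy with known group means:
#   S=0 X-counts {X=0: 3, X=1: 2}; (S=0, A=1) losses: {1,3} at X=0, {5} at X=1
#   (S=1, A=1) losses: {1} at X=0, {4} at X=1
# so saturated fits give h_{1,0} = (2, 5) and h_{1,1} = (1, 4), and the
# plug-in risks are psi_obs = (3*2 + 2*5)/5 = 3.2, psi_tr = (3*1 + 2*4)/5 = 2.2.
make_toy_discrete <- function() {
  d <- data.frame(
    Y = c(1, sqrt(3), 0, sqrt(5), 0,   1, 0, 2, 0),
    A = c(1, 1, 0, 1, 0,   1, 0, 1, 0),
    S = c(0, 0, 0, 0, 0,   1, 1, 1, 1),
    X = c(0, 0, 0, 1, 1,   0, 0, 1, 1)
  )
  multisource_data(d)
}

# Constant-loss dataset: Y == y0 everywhere, so with g == y0 - sqrt(c) every
# squared-error loss equals c exactly. All cells populated in both sources.
make_constant_loss <- function(c_loss = 2.5, n_half = 6) {
  y0 <- 1
  d <- data.frame(
    Y = rep(y0, 4 * n_half),
    A = rep(c(0, 1), 2 * n_half),
    S = rep(c(0, 1), each = 2 * n_half),
    X = rep(c(0, 1, 1, 0), n_half)
  )
  list(ds = multisource_data(d),
       g = prediction_model(function(x) rep(y0 - sqrt(c_loss), nrow(x))),
       c_loss = c_loss)
}

# Brute-force plug-in of the identification formulas on fully discrete data:
# group-by means of the loss within the conditioning cell, averaged over the
# empirical X distribution of the S=0 rows.
brute_force_plugin <- function(ds, losses, a, analysis) {
  key <- apply(ds$X, 1, paste, collapse = "|")
  cell <- switch(analysis,
                 observational = ds$S == 0 & ds$A == a,
                 transportability = ds$S == 1 & ds$A == a,
                 joint = ds$A == a)
  h <- tapply(losses[cell], key[cell], mean)
  mean(h[key[ds$S == 0]])
}

# Random fully-discrete dataset guaranteed to populate every (S, A, X) cell.
random_discrete_ds <- function(seed, n_extra = 30) {
  withr::with_seed(seed, {
    base <- expand.grid(S = 0:1, A = 0:1, X = 0:1)
    extra <- data.frame(S = sample(0:1, n_extra, TRUE),
                        A = sample(0:1, n_extra, TRUE),
                        X = sample(0:1, n_extra, TRUE))
    d <- rbind(base, extra)
    d$Y <- rnorm(nrow(d))
    multisource_data(d)
  })
}

quick_sim <- function(seed = 1, n0 = 500, n1 = 500, ...) {
  simulate_multisource(sim_config(n0 = n0, n1 = n1, seed = seed, ...))
}

# Replicate-level estimates for simulation studies used in the tests.
replicate_estimates <- function(cfg, n_sims, analyses, estimator = "om",
                                model = NULL, master_seed = 1,
                                loss_learner = learner("linear"),
                                propensity_learner = learner("logistic")) {
  seeds <- withr::with_seed(master_seed, sample.int(2^31 - 2, n_sims))
  out <- matrix(NA_real_, n_sims, length(analyses),
                dimnames = list(NULL, analyses))
  for (i in seq_len(n_sims)) {
    cfg_i <- do.call(sim_config, modifyList(unclass(cfg),
                                            list(seed = seeds[i])))
    sim <- simulate_multisource(cfg_i)
    g <- if (is.null(model)) true_outcome_model(cfg, 1) else model
    L <- compute_losses(sim$observed, g)
    nuis <- fit_nuisances(sim$observed, L, 1, analyses = analyses,
                          loss_learner = loss_learner,
                          propensity_learner = propensity_learner,
                          trial_assignment_prob = cfg$trial_assignment_prob)
    for (an in analyses) {
      out[i, an] <- estimate_risk(sim$observed, losses = L, a = 1,
                                  analysis = an, estimator = estimator,
                                  nuis = nuis)$estimate
    }
  }
  out
}
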