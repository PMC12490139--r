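test_that("loss arithmetic matches hand values and enforces domains", {
  d <- data.frame(Y = c(2, 2), A = 0:1, S = 0:1, X = c(1, 1))
  ds <- multisource_data(d)
  g_half <- prediction_model(function(x) rep(0.5, nrow(x)))
  expect_equal(compute_losses(ds, g_half, "squared_error"), c(2.25, 2.25))
  expect_equal(compute_losses(ds, g_half, "absolute"), c(1.5, 1.5))
  db <- multisource_data(data.frame(Y = c(1, 0), A = 0:1, S = 0:1, X = c(1, 1)))
  g8 <- prediction_model(function(x) rep(0.8, nrow(x)))
  expect_equal(compute_losses(db, g8, "brier"), c(0.04, 0.64))
  expect_error(compute_losses(ds, g8, "brier"), class = "cfrisk_domain_error")
  g_big <- prediction_model(function(x) rep(1.2, nrow(x)))
  expect_error(compute_losses(db, g_big, "brier"), class = "cfrisk_domain_error")
})

test_that("outcome-model estimators match the worked discrete example", {
  ds <- make_toy_discrete()
  L <- compute_losses(ds, g_zero)
  nuis <- fit_nuisances(ds, L, 1, estimators = "om",
                        loss_learner = learner("saturated"))
  obs <- estimate_risk(ds, losses = L, a = 1, analysis = "observational",
                       estimator = "om", nuis = nuis)
  tr <- estimate_risk(ds, losses = L, a = 1, analysis = "transportability",
                      estimator = "om", nuis = nuis)
  expect_equal(obs$estimate, 3.2, tolerance = 1e-12)
  expect_equal(tr$estimate, 2.2, tolerance = 1e-12)
  expect_equal(obs$n_target, 5)
})

test_that("ipw estimators match hand-computed weighted sums", {
  # observational: two (S=0, A=1) rows with losses {2, 4}, e = 0.5, n0 = 4
  d <- data.frame(Y = c(sqrt(2), 2, 0, 0, 1, 1),
                  A = c(1, 1, 0, 0, 1, 0),
                  S = c(0, 0, 0, 0, 1, 1),
                  X = rep(0, 6))
  ds <- multisource_data(d)
  L <- compute_losses(ds, g_zero)
  nuis <- fit_nuisances(ds, L, 1, analyses = "observational",
                        estimators = "ipw",
                        propensity_learner = learner("logistic", degree = 0))
  for (norm in c("hajek", "ht")) {
    est <- estimate_risk(ds, losses = L, a = 1, analysis = "observational",
                         estimator = "ipw", normalization = norm, nuis = nuis)
    expect_equal(est$estimate, 3.0, tolerance = 1e-10)
  }

  # transportability: n0 = 2; trial losses {1, 3} with e = 0.5, w = 1;
  # hajek gives 2.0 but ht gives 4.0 — the normalization choice matters.
  d2 <- data.frame(Y = c(0, 0, 1, sqrt(3)),
                   A = c(0, 0, 1, 1),
                   S = c(0, 0, 1, 1),
                   X = rep(0, 4))
  ds2 <- multisource_data(d2)
  L2 <- compute_losses(ds2, g_zero)
  nuis2 <- fit_nuisances(ds2, L2, 1, analyses = "transportability",
                         estimators = "ipw",
                         propensity_learner = learner("logistic", degree = 0),
                         trial_assignment_prob = 0.5)
  hajek <- estimate_risk(ds2, losses = L2, a = 1,
                         analysis = "transportability", estimator = "ipw",
                         normalization = "hajek", nuis = nuis2)
  ht <- estimate_risk(ds2, losses = L2, a = 1, analysis = "transportability",
                      estimator = "ipw", normalization = "ht", nuis = nuis2)
  expect_equal(hajek$estimate, 2.0, tolerance = 1e-10)
  expect_equal(ht$estimate, 4.0, tolerance = 1e-10)
})

test_that("dr collapses to om when the residual correction vanishes", {
  # single-source analyses: a saturated loss model zeroes the within-X-cell
  # residual sums, and the weights are constant within an X-cell, so the
  # correction cancels exactly
  for (seed in c(21, 22, 23)) {
    ds <- random_discrete_ds(seed)
    L <- compute_losses(ds, g_zero)
    nuis <- fit_nuisances(ds, L, 1, loss_learner = learner("saturated"))
    for (an in c("observational", "transportability")) {
      om <- estimate_risk(ds, losses = L, a = 1, analysis = an,
                          estimator = "om", nuis = nuis)$estimate
      dr <- estimate_risk(ds, losses = L, a = 1, analysis = an,
                          estimator = "dr", nuis = nuis)$estimate
      expect_equal(dr, om, tolerance = 1e-10)
    }
  }
  # joint analysis weights the two sources differently within an X-cell, so
  # exact equality needs the loss model to interpolate: make the loss a
  # deterministic function of X
  ds <- random_discrete_ds(24)
  ds$Y <- ds$X[, "X"] + 2
  L <- compute_losses(ds, g_zero)
  nuis <- fit_nuisances(ds, L, 1, loss_learner = learner("saturated"))
  for (an in c("observational", "transportability", "joint")) {
    om <- estimate_risk(ds, losses = L, a = 1, analysis = an,
                        estimator = "om", nuis = nuis)$estimate
    dr <- estimate_risk(ds, losses = L, a = 1, analysis = an,
                        estimator = "dr", nuis = nuis)$estimate
    expect_equal(dr, om, tolerance = 1e-12)
  }
})

test_that("saturated estimators equal the brute-force group-by plug-in", {
  for (seed in 31:35) {
    ds <- random_discrete_ds(seed)
    L <- compute_losses(ds, g_zero)
    nuis <- fit_nuisances(ds, L, 1, estimators = "om",
                          loss_learner = learner("saturated"))
    for (an in c("observational", "transportability", "joint")) {
      pkg <- estimate_risk(ds, losses = L, a = 1, analysis = an,
                           estimator = "om", nuis = nuis)$estimate
      expect_equal(pkg, brute_force_plugin(ds, L, 1, an), tolerance = 1e-10)
    }
  }
})

test_that("the estimate grid has full cardinality and collects cell failures", {
  ds <- make_toy_discrete()
  tab <- estimate_risk_table(ds, g_zero, a_levels = 1,
                             loss_learner = learner("saturated"),
                             trial_assignment_prob = 0.5)
  expect_equal(nrow(tab), 9)
  expect_true(all(is.na(tab$error)))
  tab2 <- estimate_risk_table(ds, g_zero, a_levels = c(0, 1),
                              loss_learner = learner("saturated"),
                              trial_assignment_prob = 0.5)
  expect_equal(nrow(tab2), 18)
  # break one cell: no (S=1, A=0) rows -> a=0 transportability fails, rest fine
  ds0 <- ds
  ds0$A[ds0$S == 1] <- 1L
  tab3 <- estimate_risk_table(ds0, g_zero, a_levels = c(0, 1),
                              loss_learner = learner("saturated"),
                              trial_assignment_prob = 0.5)
  bad <- tab3$a == 0 & tab3$analysis == "transportability"
  expect_true(all(is.na(tab3$estimate[bad])))
  expect_true(all(!is.na(tab3$estimate[tab3$a == 1 &
                                         tab3$analysis == "observational"])))
})

test_that("transportability never reads outcome or treatment of target rows", {
  sim <- quick_sim(seed = 44, n0 = 300, n1 = 300)
  ds <- sim$observed
  g <- true_outcome_model(sim$config, 1)
  run_tr <- function(d) {
    L <- compute_losses(d, g)
    nuis <- fit_nuisances(d, L, 1, analyses = "transportability",
                          trial_assignment_prob = 0.5)
    vapply(c("om", "ipw", "dr"), function(e) {
      estimate_risk(d, losses = L, a = 1, analysis = "transportability",
                    estimator = e, nuis = nuis)$estimate
    }, numeric(1))
  }
  base <- run_tr(ds)
  ds_sent <- ds
  s0 <- ds_sent$S == 0
  ds_sent$Y[s0] <- -999
  ds_sent$A[s0] <- 1L - ds_sent$A[s0]
  expect_identical(run_tr(ds_sent), base)
})

test_that("state errors fire when required nuisances are absent", {
  ds <- make_toy_discrete()
  L <- compute_losses(ds, g_zero)
  om_only <- fit_nuisances(ds, L, 1, analyses = "observational",
                           estimators = "om")
  expect_error(estimate_risk(ds, losses = L, a = 1, analysis = "joint",
                             estimator = "om", nuis = om_only),
               class = "cfrisk_state_error")
  expect_error(estimate_risk(ds, losses = L, a = 1, analysis = "observational",
                             estimator = "ipw", nuis = om_only),
               class = "cfrisk_state_error")
  expect_error(estimate_risk(ds, losses = L, a = 0, analysis = "observational",
                             estimator = "om", nuis = om_only),
               class = "cfrisk_state_error")
})
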