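test_that("intercept-bearing learners reproduce a constant response exactly", {
  ds <- make_toy_discrete()
  L <- rep(7, ds$n)
  for (lrn in list(learner("linear"), learner("linear", degree = 0),
                   learner("saturated"))) {
    h <- fit_loss_regression(ds, L, a = 1, source = 0, learner = lrn)
    expect_equal(predict(h, ds$X), rep(7, ds$n), tolerance = 1e-10)
  }
})

test_that("saturated loss regression recovers cell means", {
  ds <- make_toy_discrete()
  L <- compute_losses(ds, g_zero)
  h0 <- fit_loss_regression(ds, L, a = 1, source = 0,
                            learner = learner("saturated"))
  expect_equal(predict(h0, data.frame(X = c(0, 1))), c(2, 5), tolerance = 1e-12)
  h1 <- fit_loss_regression(ds, L, a = 1, source = 1,
                            learner = learner("saturated"))
  expect_equal(predict(h1, data.frame(X = c(0, 1))), c(1, 4), tolerance = 1e-12)
})

test_that("loss regression rejects empty cells and non-finite losses", {
  ds <- make_toy_discrete()
  L <- compute_losses(ds, g_zero)
  ds0 <- ds
  ds0$A[ds0$S == 1] <- 0L  # kill the (S=1, A=1) cell
  expect_error(fit_loss_regression(ds0, L, a = 1, source = 1),
               class = "cfrisk_estimability_error")
  L_bad <- L; L_bad[1] <- Inf
  expect_error(fit_loss_regression(ds, L_bad, a = 1, source = 0),
               class = "cfrisk_domain_error")
})

test_that("treatment model: intercept fit matches frequency, degenerate stratum errors", {
  sim <- quick_sim(seed = 4, n0 = 400, n1 = 400)
  ds <- sim$observed
  m <- fit_treatment_model(ds, 1, learner("logistic", degree = 0))
  expect_equal(predict(m, ds$X)[1], mean(ds$A[ds$S == 1]), tolerance = 1e-8)
  ds_one <- ds
  ds_one$A[ds_one$S == 1] <- 1L
  expect_error(fit_treatment_model(ds_one, 1),
               class = "cfrisk_estimability_error")
})

test_that("confounded treatment model recovers its generating coefficients", {
  sim <- quick_sim(seed = 5, n0 = 20000, n1 = 100, alpha_0 = -0.4,
                   alpha_X = 0.8)
  m <- fit_treatment_model(sim$observed, 0)
  co <- m$fit$fitted$coef
  expect_equal(unname(co["(Intercept)"]), -0.4, tolerance = 0.08)
  expect_equal(unname(co["X"]), 0.8, tolerance = 0.08)
})

test_that("participation model recovers the covariate-shift log-odds", {
  # X | S=0 ~ N(mu, 1), X | S=1 ~ N(0, 1), equal sizes: the Bayes posterior
  # log-odds of S=1 given x is linear with slope -mu and intercept mu^2/2.
  mu <- 0.8
  sim <- quick_sim(seed = 6, n0 = 20000, n1 = 20000, mu_X0 = mu)
  m <- fit_participation_model(sim$observed)
  co <- m$fit$fitted$coef
  expect_equal(unname(co["X"]), -mu, tolerance = 0.05)
  expect_equal(unname(co["(Intercept)"]), mu^2 / 2, tolerance = 0.05)
  # intercept-only on identical populations: p ~= n1/n, odds w ~= n0/n1
  sim2 <- quick_sim(seed = 7, n0 = 600, n1 = 200, mu_X0 = 0)
  m2 <- fit_participation_model(sim2$observed, learner("logistic", degree = 0))
  expect_equal(predict(m2, sim2$observed$X)[1], 0.25, tolerance = 1e-6)
  expect_equal(predict_odds(m2, sim2$observed$X)[1], 3, tolerance = 1e-5)
})

test_that("probability predictions respect the clipping bounds", {
  d <- data.frame(Y = rnorm(60), A = rep(0:1, 30), S = rep(0:1, each = 30),
                  X = c(rnorm(30, -4), rnorm(30, 4)))
  ds <- multisource_data(d)
  m <- fit_participation_model(ds, clip_bounds = c(0.001, 0.999))
  p <- predict(m, data.frame(X = c(-50, 0, 50)))
  expect_true(all(p >= 0.001 & p <= 0.999))
})

test_that("fitting is invariant to row permutation within a cell", {
  ds <- quick_sim(seed = 8, n0 = 200, n1 = 200)$observed
  L <- compute_losses(ds, g_zero)
  perm <- withr::with_seed(1, sample(ds$n))
  ds_p <- cfrisk:::subset_msdata(ds, perm)
  h <- fit_loss_regression(ds, L, 1, 0)
  h_p <- fit_loss_regression(ds_p, L[perm], 1, 0)
  grid <- data.frame(X = seq(-2, 2, by = 0.5))
  expect_equal(predict(h, grid), predict(h_p, grid), tolerance = 1e-10)
})

test_that("pooled loss regression approaches the per-source fits under equality", {
  sim <- quick_sim(seed = 10, n0 = 20000, n1 = 20000, mu_X0 = 0)
  ds <- sim$observed
  L <- compute_losses(ds, true_outcome_model(sim$config, 1))
  grid <- data.frame(X = c(-1, 0, 1))
  hp <- predict(fit_loss_regression(ds, L, 1, "pooled"), grid)
  h0 <- predict(fit_loss_regression(ds, L, 1, 0), grid)
  h1 <- predict(fit_loss_regression(ds, L, 1, 1), grid)
  expect_equal(hp, h0, tolerance = 0.1)
  expect_equal(hp, h1, tolerance = 0.1)
})

test_that("user-supplied learners plug in through the fit/predict contract", {
  ds <- make_toy_discrete()
  L <- compute_losses(ds, g_zero)
  mean_lrn <- user_learner(
    fit = function(X, y) mean(y),
    predict = function(state, X) rep(state, nrow(X))
  )
  h <- fit_loss_regression(ds, L, 1, 0, learner = mean_lrn)
  expect_equal(predict(h, ds$X), rep(mean(c(1, 3, 5)), ds$n))
})

test_that("cross-fitting changes in-cell predictions but not the interface", {
  ds <- quick_sim(seed = 12, n0 = 300, n1 = 300)$observed
  L <- compute_losses(ds, g_zero)
  n_plain <- fit_nuisances(ds, L, 1, analyses = "observational")
  n_cf <- fit_nuisances(ds, L, 1, analyses = "observational",
                        cross_fit = 5, seed = 3)
  n_cf2 <- fit_nuisances(ds, L, 1, analyses = "observational",
                         cross_fit = 5, seed = 3)
  cell <- ds$S == 0 & ds$A == 1
  expect_false(isTRUE(all.equal(n_plain$pred$h0[cell], n_cf$pred$h0[cell])))
  expect_identical(n_cf$pred$h0, n_cf2$pred$h0)  # seeded determinism
  # out-of-cell rows use the full-data fit either way
  expect_equal(n_plain$pred$h0[!cell], n_cf$pred$h0[!cell])
})
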