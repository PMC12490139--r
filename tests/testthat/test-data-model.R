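test_that("assembly counts sources and defaults X* to all covariates", {
  d <- data.frame(Y = rnorm(12), A = rep(0:1, 6),
                  S = rep(c(0, 1), c(5, 7)), X1 = rnorm(12), X2 = rnorm(12))
  ds <- multisource_data(d)
  expect_equal(ds$n0, 5)
  expect_equal(ds$n1, 7)
  expect_equal(ds$n, 12)
  expect_equal(ds$xstar_columns, c("X1", "X2"))
  expect_equal(glance(ds)$p_xstar, 2)
})

test_that("contract violations raise typed errors", {
  d <- data.frame(Y = rnorm(6), A = rep(0:1, 3), S = rep(0:1, each = 3),
                  X = rnorm(6))
  d_na <- d; d_na$Y[2] <- NA
  expect_error(multisource_data(d_na), class = "cfrisk_completeness_error")
  d_bad <- d; d_bad$A[1] <- 2
  expect_error(multisource_data(d_bad), class = "cfrisk_domain_error")
  expect_error(multisource_data(d, covariates = "Z"),
               class = "cfrisk_schema_error")
  expect_error(multisource_data(d, xstar = "Z"),
               class = "cfrisk_schema_error")
})

test_that("categorical encoding is one-hot, lexicographic, reference-dropped", {
  d <- data.frame(Y = rnorm(6), A = rep(0:1, 3), S = rep(0:1, each = 3),
                  grp = c("c", "a", "b", "a", "c", "b"), age = 1:6)
  ds <- multisource_data(d, categoricals = "grp")
  expect_equal(colnames(ds$X), c("grpb", "grpc", "age"))
  expect_equal(ds$X[, "grpb"], as.numeric(d$grp == "b"))
  expect_equal(ds$X[, "grpc"], as.numeric(d$grp == "c"))
  # naming a categorical in xstar pulls in all its indicator columns
  ds2 <- multisource_data(d, categoricals = "grp", xstar = "grp")
  expect_equal(ds2$xstar_columns, c("grpb", "grpc"))
})

test_that("CSV loading is deterministic and honors the schema config", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(out = rnorm(10), trt = rep(0:1, 5), src = rep(0:1, each = 5),
                  x1 = rnorm(10), site = rep(c("u", "v"), 5))
  readr::write_csv(d, path)
  schema <- list(outcome = "out", treatment = "trt", source = "src",
                 covariates = c("x1", "site"), xstar = "x1",
                 categoricals = "site")
  ds1 <- read_multisource(path, schema)
  ds2 <- read_multisource(path, schema)
  expect_identical(ds1$X, ds2$X)
  expect_equal(ds1$xstar_columns, "x1")
  expect_equal(ds1$n0 + ds1$n1, nrow(d))
  # config via YAML file
  cfgpath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(schema, cfgpath)
  ds3 <- read_multisource(path, cfgpath)
  expect_identical(ds3$X, ds1$X)
  expect_error(read_multisource(path, list(outcome = "out", treatment = "trt")),
               regexp = "source", class = "cfrisk_schema_error")
})

test_that("cell validation requires exactly the cells each analysis uses", {
  d <- data.frame(Y = rnorm(8), A = c(1, 1, 0, 0, 0, 0, 0, 0),
                  S = rep(0:1, each = 4), X = rnorm(8))
  ds <- multisource_data(d)  # no (S=1, A=1) rows
  expect_error(validate_cells(ds, 1, "transportability"),
               regexp = "S=1, A=1", class = "cfrisk_estimability_error")
  expect_true(validate_cells(ds, 1, "observational"))
  expect_true(validate_cells(ds, 0, "joint"))
  ds_full <- make_toy_discrete()
  expect_true(validate_cells(ds_full, 1, "joint"))
})

test_that("positivity diagnostics flag target rows outside trial support", {
  d <- withr::with_seed(18, data.frame(
    Y = rnorm(81),
    A = c(rep(c(0, 1), 20), rep(c(0, 1), 20), 0),
    S = c(rep(1, 40), rep(0, 41)),
    X = c(rnorm(40, 0), rnorm(40, 1.5), 5)  # one target row far beyond trial support
  ))
  ds <- multisource_data(d)
  L <- compute_losses(ds, g_zero)
  nuis <- fit_nuisances(ds, L, 1, analyses = "transportability",
                        estimators = "ipw")
  rep <- suppressWarnings(positivity_diagnostics(ds, nuis, threshold = 0.01))
  expect_true(nrow(d) %in% rep$flagged_rows)
  expect_true(all(ds$S[rep$flagged_rows] == 0))
  expect_true(all(rep$participation_prob_range_on_target >= 0 &
                    rep$participation_prob_range_on_target <= 1))
  # serializes to JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_overlap_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$threshold, 0.01)
})

test_that("no rows are flagged when the two source populations coincide", {
  sim <- quick_sim(seed = 9, n0 = 1000, n1 = 1000, mu_X0 = 0)
  ds <- sim$observed
  L <- compute_losses(ds, g_zero)
  nuis <- fit_nuisances(ds, L, 1, estimators = c("ipw"))
  rep <- positivity_diagnostics(ds, nuis, threshold = 0.01)
  expect_length(rep$flagged_rows, 0)
  # randomized trial with Bernoulli(0.5) assignment, intercept-only model:
  # propensity is the observed frequency, constant across rows
  nuis2 <- fit_nuisances(ds, L, 1, analyses = "transportability",
                         estimators = "ipw",
                         propensity_learner = learner("logistic", degree = 0))
  e1 <- nuis2$pred$e1[ds$S == 1]
  expect_equal(diff(range(e1)), 0, tolerance = 1e-12)
  expect_equal(e1[1], mean(ds$A[ds$S == 1]), tolerance = 1e-8)
})

test_that("diagnostics demand a fitted nuisance set", {
  ds <- make_toy_discrete()
  L <- compute_losses(ds, g_zero)
  om_only <- fit_nuisances(ds, L, 1, analyses = "observational",
                           estimators = "om")
  expect_error(positivity_diagnostics(ds, om_only), class = "cfrisk_state_error")
  expect_error(positivity_diagnostics(ds, list()), class = "cfrisk_state_error")
})
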