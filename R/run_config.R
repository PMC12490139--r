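#' Run a configured analysis end to end
#'
#' Config-driven entry point: one structured config (named list or YAML/JSON
#' file path) names a command and its parameters; outputs (CSV/JSON tables,
#' figures) are written under `output_dir` together with a `manifest.json`
#' recording the config, package version, seed, and every file written, so a
#' run is reproducible from its manifest alone. A thin command-line wrapper
#' around this function ships in `inst/cli/cfrisk.R`.
#'
#' Commands and their keys:
#'
#' * `simulate` — `sim` (a [sim_config()] parameter list), optional
#'   `include_oracle`; writes the simulated table as CSV.
#' * `evaluate` — `data` (CSV path) + `schema` (see [read_multisource()]),
#'   or `sim`; `a_levels`, `analyses`, `estimators`, `loss`,
#'   `normalization`; writes the estimate grid as CSV and JSON.
#' * `tailor` — data as above plus `a`, `analysis`; writes target-row
#'   predictions as CSV and model metadata as JSON.
#' * `benchmark` — data plus `a`, `estimator`, `B`, `level`; writes the
#'   benchmark result as JSON.
#' * `bias_grid`, `variance_study`, `demo` — simulation studies; write
#'   their result tables as CSV and a figure as SVG.
#'
#' All commands honor a top-level `seed` (default 1), from which every
#' source of randomness derives.
#'
#' @param config Named list or path to a YAML/JSON config file. Must contain
#'   `command`.
#' @param output_dir Directory for outputs (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
run_analysis <- function(config, output_dir = ".") {
  config <- load_config(config)
  command <- config$command
  if (is.null(command)) stop_schema("config is missing required key 'command'")
  command <- rlang::arg_match0(command, c("simulate", "evaluate", "tailor",
                                          "benchmark", "bias_grid",
                                          "variance_study", "demo"))
  seed <- as.integer(config$seed %||% 1L)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(output_dir, name)
    readr::write_csv(df, path)
    outputs <<- c(outputs, path)
  }
  emit_json <- function(obj, name) {
    path <- file.path(output_dir, name)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    outputs <<- c(outputs, path)
  }
  emit_plot <- function(p, name) {
    path <- file.path(output_dir, name)
    ggplot2::ggsave(path, p, width = 7, height = 5)
    outputs <<- c(outputs, path)
  }
  get_data <- function() {
    if (!is.null(config$data)) {
      if (is.null(config$schema)) stop_schema("config is missing required key 'schema'")
      read_multisource(config$data, config$schema)
    } else if (!is.null(config$sim)) {
      simulate_multisource(do.call(sim_config,
                                   modifyList(config$sim, list(seed = seed))))$observed
    } else {
      stop_schema("config needs either 'data' (+'schema') or 'sim'")
    }
  }
  get_model <- function(ds) {
    # A linear model spec {coefficients: {intercept:, <col>: ...}} or a
    # tailored-model fit request {fit_tailored: {a:, analysis:}}.
    if (!is.null(config$model$coefficients)) {
      co <- config$model$coefficients
      prediction_model(function(x) {
        out <- rep(co$intercept %||% 0, nrow(x))
        for (nm in setdiff(names(co), "intercept")) out <- out + co[[nm]] * x[[nm]]
        out
      }, description = "linear model from config")
    } else {
      stop_schema("config is missing required key 'model' (with 'coefficients')")
    }
  }

  if (command == "simulate") {
    if (is.null(config$sim)) stop_schema("config is missing required key 'sim'")
    sim <- simulate_multisource(do.call(sim_config,
                                        modifyList(config$sim, list(seed = seed))))
    tab <- tibble::tibble(Y = sim$observed$Y, A = sim$observed$A,
                          S = sim$observed$S)
    tab <- dplyr::bind_cols(tab, tibble::as_tibble(sim$observed$X))
    if (isTRUE(config$include_oracle)) tab <- dplyr::bind_cols(tab, sim$oracle)
    emit_csv(tab, "simulated.csv")
  } else if (command == "evaluate") {
    ds <- get_data()
    tab <- estimate_risk_table(
      ds, model = get_model(ds), loss = config$loss %||% "squared_error",
      a_levels = config$a_levels %||% c(0, 1),
      analyses = config$analyses %||% c("transportability", "observational", "joint"),
      estimators = config$estimators %||% c("om", "ipw", "dr"),
      normalization = config$normalization %||% "hajek"
    )
    emit_csv(tab, "estimates.csv")
    emit_json(as.data.frame(tab), "estimates.json")
  } else if (command == "tailor") {
    ds <- get_data()
    m <- fit_tailored(ds, a = config$a %||% 1,
                      analysis = config$analysis %||% "observational")
    emit_csv(tibble::tibble(row = which(ds$S == 0L), mu_hat = m$fitted_values),
             "tailored_predictions.csv")
    emit_json(list(a = m$a, analysis = m$analysis,
                   xstar_columns = m$xstar_columns, n_cell = m$n_cell,
                   coefficients = as.list(tidy(m)$estimate)),
              "tailored_model.json")
  } else if (command == "benchmark") {
    ds <- get_data()
    bm <- benchmark(ds, get_model(ds), loss = config$loss %||% "squared_error",
                    a = config$a %||% 1, estimator = config$estimator %||% "om",
                    B = config$B %||% 500, seed = seed,
                    level = config$level %||% 0.95)
    emit_json(as.list(tidy(bm)), "benchmark.json")
  } else if (command == "bias_grid") {
    grid <- run_bias_grid(canonical_cases(n0 = config$n0 %||% 2000,
                                          n1 = config$n1 %||% 2000),
                          n_sims = config$n_sims %||% 500, seed = seed)
    emit_csv(grid, "bias_grid.csv")
    emit_plot(autoplot(grid), "bias_grid.svg")
  } else if (command == "variance_study") {
    grid_list <- config$sample_size_grid %||% list(c(1000, 1000))
    vs <- run_variance_study(do.call(sim_config, config$sim %||% list()),
                             n_sims = config$n_sims %||% 500,
                             sample_size_grid = lapply(grid_list, unlist),
                             seed = seed)
    emit_csv(vs, "variance_study.csv")
    emit_plot(autoplot(vs), "variance_study.svg")
  } else if (command == "demo") {
    demo <- run_cass_style_demo(do.call(sim_config, config$sim %||% list()),
                                seed = seed, B = config$B %||% 500)
    emit_csv(demo, "demo_grid.csv")
    emit_plot(autoplot(demo), "demo_forest.svg")
  }

  manifest <- list(
    command = command, seed = seed,
    package_version = as.character(utils::packageVersion("cfrisk")),
    config = config, outputs = outputs,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
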