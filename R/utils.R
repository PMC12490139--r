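# Error helpers: every user-facing failure carries a cfrisk_* condition class
# so callers (and the test suite) can distinguish schema, completeness, domain,
# estimability, and state failures.

stop_schema <- function(msg) abort(msg, class = c("cfrisk_schema_error", "cfrisk_error"))
stop_completeness <- function(msg) abort(msg, class = c("cfrisk_completeness_error", "cfrisk_error"))
stop_domain <- function(msg) abort(msg, class = c("cfrisk_domain_error", "cfrisk_error"))
stop_estimability <- function(msg) abort(msg, class = c("cfrisk_estimability_error", "cfrisk_error"))
stop_state <- function(msg) abort(msg, class = c("cfrisk_state_error", "cfrisk_error"))

clip_prob <- function(p, bounds) pmin(pmax(p, bounds[1]), bounds[2])

expit <- function(x) plogis(x)

#' @noRd
match_analysis <- function(analysis) {
  rlang::arg_match0(analysis, c("observational", "transportability", "joint"))
}

match_estimator <- function(estimator) {
  rlang::arg_match0(estimator, c("om", "ipw", "dr"))
}

match_normalization <- function(normalization) {
  rlang::arg_match0(normalization, c("hajek", "ht"))
}

# Run expr under a local RNG state when seed is supplied; leave the global
# stream untouched either way unless seed is NULL (then the ambient stream is
# used, as base R consumers expect).
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
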