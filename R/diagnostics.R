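#' Positivity and overlap diagnostics
#'
#' The positivity assumptions — every covariate pattern in the target
#' population has a positive probability of each treatment, and of appearing
#' in the trial — can be examined (though never verified) from the observed
#' data. This reports the range of estimated treatment propensities within
#' each source, the range of the estimated participation probability
#' `Pr(S=1|X)` over the target (`S=0`) rows, and flags target rows whose
#' participation probability falls below `threshold`. Diagnostics warn;
#' they never abort an analysis.
#'
#' @param ds An `msdata` object.
#' @param nuis A `nuisance_set` from [fit_nuisances()] containing at least
#'   one propensity or participation component, or a list with fitted
#'   `e0`/`e1`/`p` models.
#' @param threshold Participation-probability cutoff below which target rows
#'   are flagged (default 0.01).
#' @return An `overlap_report`: a list with
#'   `treatment_propensity_range_by_source` (tibble),
#'   `participation_prob_range_on_target`, `flagged_rows` (indices into the
#'   dataset, all with `S=0`), and `threshold`. Has [tidy()] and JSON
#'   serialization via [write_overlap_json()].
#' @export
positivity_diagnostics <- function(ds, nuis, threshold = 0.01) {
  stopifnot(inherits(ds, "msdata"))
  if (!inherits(nuis, "nuisance_set")) {
    stop_state("nuis must be a fitted nuisance_set")
  }
  if (is.null(nuis$pred$e0) && is.null(nuis$pred$e1) && is.null(nuis$pred$p)) {
    stop_state(paste0("nuisance set contains no propensity or participation ",
                      "component; fit with estimators including 'ipw' or 'dr'"))
  }
  s0 <- ds$S == 0L
  rng <- function(v) if (is.null(v)) c(NA_real_, NA_real_) else range(v)
  e0r <- rng(nuis$pred$e0[s0])
  e1r <- rng(nuis$pred$e1[!s0])
  prop_tbl <- tibble::tibble(
    source = c(0L, 1L),
    min = c(e0r[1], e1r[1]),
    max = c(e0r[2], e1r[2])
  )
  if (!is.null(nuis$pred$p)) {
    p0 <- nuis$pred$p[s0]
    part_range <- range(p0)
    flagged <- which(s0)[p0 < threshold]
  } else {
    part_range <- c(NA_real_, NA_real_)
    flagged <- integer(0)
  }
  if (length(flagged) > 0) {
    warn(paste0(length(flagged), " target (S=0) row(s) have estimated ",
                "Pr(S=1|X) below ", threshold,
                "; transportability weighting may extrapolate"))
  }
  structure(
    list(treatment_propensity_range_by_source = prop_tbl,
         participation_prob_range_on_target = part_range,
         flagged_rows = flagged,
         threshold = threshold),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n")
  cat("  treatment propensity ranges:\n")
  print(x$treatment_propensity_range_by_source)
  cat("  Pr(S=1|X) on target rows: [",
      signif(x$participation_prob_range_on_target[1], 4), ", ",
      signif(x$participation_prob_range_on_target[2], 4), "]\n", sep = "")
  cat("  flagged target rows (< ", x$threshold, "): ",
      length(x$flagged_rows), "\n", sep = "")
  invisible(x)
}

#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$treatment_propensity_range_by_source,
                  quantity = "treatment_propensity", .before = 1),
    tibble::tibble(quantity = "participation_prob_on_target",
                   source = NA_integer_,
                   min = x$participation_prob_range_on_target[1],
                   max = x$participation_prob_range_on_target[2])
  )
}

#' Serialize an overlap report to JSON
#' @param x An `overlap_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_overlap_json <- function(x, path) {
  stopifnot(inherits(x, "overlap_report"))
  obj <- list(
    treatment_propensity_range_by_source =
      as.data.frame(x$treatment_propensity_range_by_source),
    participation_prob_range_on_target = x$participation_prob_range_on_target,
    flagged_rows = x$flagged_rows,
    threshold = x$threshold
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
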