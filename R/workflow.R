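#' Define a reliability criterion
#'
#' The user-defined acceptance rule: a maximum tolerated error at a stated
#' confidence level.
#'
#' @param max_error maximum error in percent, in (0, 100)
#' @param confidence confidence level in percent, in (0, 100)
#' @return object of class `reliability_criterion`
#' @export
reliability_criterion <- function(max_error = 10, confidence = 80) {
  stopifnot(max_error > 0, max_error < 100,
            confidence > 0, confidence < 100)
  structure(list(max_error = max_error, confidence = confidence),
            class = "reliability_criterion")
}

#' Assess a measurement against a reliability criterion
#'
#' The end-to-end decision algorithm: demultiplex the spectrum by DCLS,
#' compute RFE/SRI and the fitted target:control ratios, select the
#' calibrated reliability table whose mixture ratio is nearest the fitted
#' ratio, look up the minimum SRI required for the criterion's error bound,
#' and accept the measurement iff its realized SRI reaches that threshold.
#' Both the SRI and the fitted ratio enter the decision: a more imbalanced
#' mixture needs a higher SRI for the same error bound.
#'
#' Guard rails: tables must carry the hash of the same library (stale or
#' foreign tables are refused); a fitted ratio outside the calibrated ratio
#' range is rejected as out-of-calibration rather than extrapolated; a
#' spectrum with no particle signal yields verdict `no-signal`.
#'
#' @param spectrum intensity vector or `simulated_spectrum`
#' @param library the [spectral_library] the tables were calibrated against
#' @param tables list of `reliability_table` objects (one per ratio) from
#'   [build_reliability_table()]
#' @param criterion a [reliability_criterion()]
#' @param control_index control flavor for the ratio (default: last flavor)
#' @return object of class `assessment_outcome`: `demux`, `metrics`
#'   (rfe, sri), `ratios`, `required_min_sri`, `verdict` (`accept`,
#'   `reject` or `no-signal`), `advice`, `table_ratio`
#' @export
assess <- function(spectrum, library, tables, criterion,
                   control_index = length(library$flavors)) {
  stopifnot(inherits(criterion, "reliability_criterion"))
  if (inherits(tables, "reliability_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "reliability_table")))
  lib_hash <- library_hash(library)
  for (tb in tables) {
    if (!identical(tb$provenance$library_hash, lib_hash))
      stop("reliability table calibrated against a different library ",
           "(hash mismatch); recalibrate")
    if (tb$confidence != criterion$confidence)
      stop("table confidence ", tb$confidence,
           "% does not match the requested ", criterion$confidence, "%")
  }
  fit <- dcls_fit(spectrum, library)
  m <- list(rfe = rfe(fit), sri = sri(fit))
  targets <- setdiff(seq_along(fit$weights), control_index)
  ratios <- if (fit$weights[control_index] > 0)
    stats::setNames(fit$weights[targets] / fit$weights[control_index],
                    names(fit$weights)[targets]) else
    stats::setNames(rep(NA_real_, length(targets)),
                    names(fit$weights)[targets])

  outcome <- function(verdict, advice, required = NA_real_, tratio = NA_real_)
    structure(list(demux = fit, metrics = m, ratios = ratios,
                   required_min_sri = required, verdict = verdict,
                   advice = advice, criterion = criterion,
                   table_ratio = tratio),
              class = "assessment_outcome")

  if (is.na(m$sri))
    return(outcome("no-signal",
                   "no particle signal detected; increase particle concentration, integration time, or laser power"))
  if (any(is.na(ratios)))
    return(outcome("reject",
                   "fitted control weight is non-positive; the ratio is undefined -- repeat the measurement or average replicates"))

  tab_ratios <- vapply(tables, `[[`, numeric(1), "mixture_ratio")
  fitted_ratio <- ratios[[1]]
  rng <- range(tab_ratios)
  tol <- 0.25                                      # fractional headroom past the grid edge
  if (fitted_ratio < rng[1] * (1 - tol) || fitted_ratio > rng[2] * (1 + tol))
    return(outcome("reject",
                   "fitted mixture ratio is outside the calibrated ratio range; extend the calibration ratio grid",
                   tratio = fitted_ratio))
  tb <- tables[[which.min(abs(tab_ratios - fitted_ratio))]]
  key <- as.character(criterion$max_error)
  required <- if (key %in% names(tb$min_sri_for)) tb$min_sri_for[[key]]
              else min_sri_for_bound(tb$rows, criterion$max_error)
  if (is.na(required))
    return(outcome("reject",
                   "the requested error bound is not achievable within the calibrated SRI range; tighten acquisition or relax the criterion",
                   tratio = tb$mixture_ratio))
  if (m$sri >= required)
    outcome("accept", "measurement meets the reliability criterion",
            required, tb$mixture_ratio)
  else
    outcome("reject",
            "SRI below the required minimum; improve spectral quality through averaging or longer integration times",
            required, tb$mixture_ratio)
}

#' Remediation advice for a failed assessment
#'
#' Deterministic hint keyed to the failure mode. Refuses accepted outcomes.
#'
#' @param outcome an [assess()] result with verdict `reject` or `no-signal`
#' @return hint string
#' @export
advise <- function(outcome) {
  stopifnot(inherits(outcome, "assessment_outcome"))
  if (outcome$verdict == "accept")
    stop("advice is only defined for rejected or no-signal outcomes")
  outcome$advice
}

#' @export
print.assessment_outcome <- function(x, ...) {
  cat("Assessment: ", toupper(x$verdict), "\n", sep = "")
  cat("  SRI: ", signif(x$metrics$sri, 4),
      "  RFE: ", signif(x$metrics$rfe, 4), "\n", sep = "")
  if (!all(is.na(x$ratios)))
    cat("  fitted ratios: ",
        paste(names(x$ratios), signif(x$ratios, 4), sep = "=",
              collapse = ", "), "\n", sep = "")
  if (!is.na(x$required_min_sri))
    cat("  required min SRI (", x$criterion$max_error, "% error, ",
        x$criterion$confidence, "% confidence): ",
        signif(x$required_min_sri, 4), "\n", sep = "")
  if (x$verdict != "accept") cat("  advice: ", x$advice, "\n", sep = "")
  invisible(x)
}
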