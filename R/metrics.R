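#' Relative fitting error (RFE)
#'
#' Ratio of the norm of the full least-squares reconstruction to the norm of
#' the measured spectrum: ||sum_n w_n F_n + k B + sum_m a_m P_m|| / ||S||.
#' Equals 1 for a perfect fit and decreases toward 0 as the fit degrades.
#' Because the reconstruction is an orthogonal projection of S, the value
#' lies in [0, 1] up to floating-point rounding (clamped, with a warning if
#' the excursion exceeds 1e-9).
#'
#' RFE is biased toward 1 when the broadband background dominates: the
#' background and baseline columns fit smooth content with high fidelity
#' even when the particle weights are poor. See [sri()].
#'
#' @param fit a [dcls_fit()] result
#' @return scalar in \[0, 1\]
#' @export
rfe <- function(fit) {
  stopifnot(inherits(fit, "dcls_fit"))
  s_norm <- l2norm(fit$fitted_full + fit$residual)
  if (s_norm == 0)
    stop("RFE undefined: the measured spectrum has zero norm")
  clamp01(l2norm(fit$fitted_full) / s_norm)
}

#' Spectral reliability index (SRI)
#'
#' The RFE restricted to particle content, so that background and baseline
#' components do not inflate apparent fit quality:
#' ||sum_n w_n F_n|| / ||S - (k B + sum_m a_m P_m)||, i.e. the norm of the
#' particle-only reconstruction over the norm of the background/baseline-
#' subtracted signal. Equals 1 when the background-subtracted signal is
#' exactly the particle fit; near 0 for pure background plus noise.
#'
#' If the background-subtracted signal has (numerically) zero norm there is
#' no particle signal to judge; the function returns `NA` carrying attribute
#' `no_signal = TRUE` as a sentinel.
#'
#' @param fit a [dcls_fit()] result
#' @return scalar in \[0, 1\], or the no-signal sentinel
#' @export
sri <- function(fit) {
  stopifnot(inherits(fit, "dcls_fit"))
  # S - (kB + baseline) = particle fit + residual (residual orthogonal to
  # every design column, so the two parts are orthogonal and SRI <= 1)
  subtracted <- fit$fitted_particles + fit$residual
  denom <- l2norm(subtracted)
  s_norm <- l2norm(fit$fitted_full + fit$residual)
  if (denom <= 1e-12 * max(s_norm, 1))
    return(structure(NA_real_, no_signal = TRUE))
  clamp01(l2norm(fit$fitted_particles) / denom)
}

clamp01 <- function(x) {
  if (x < -1e-9 || x > 1 + 1e-9)
    warning("metric value ", format(x), " outside [0,1] beyond tolerance; clamped")
  min(max(x, 0), 1)
}

#' Signed percent error of one fitted weight
#'
#' 100 * (fitted - true) / true. Undefined at zero true concentration (use
#' the absolute fitted weight instead in that case).
#'
#' @param true_c true concentration (nonzero)
#' @param fitted_w fitted weight
#' @return signed percent
#' @export
percent_error <- function(true_c, fitted_w) {
  if (any(true_c == 0))
    stop("percent error undefined for a true concentration of zero")
  100 * (fitted_w - true_c) / true_c
}

#' Composite error of a multi-flavor mixture
#'
#' Root-mean-square of the per-flavor signed percent errors, giving a single
#' nonnegative error value for the whole mixture. Its nonnegativity is what
#' makes a gamma error model appropriate for mixtures.
#'
#' @param per_flavor_errors signed percent errors, one per flavor (>= 1)
#' @return nonnegative percent
#' @export
composite_error <- function(per_flavor_errors) {
  if (length(per_flavor_errors) == 0L)
    stop("composite error needs at least one per-flavor error")
  sqrt(mean(per_flavor_errors^2))
}

#' Ratio errors against a control flavor
#'
#' For ratiometric quantification a nontargeted control flavor serves as the
#' denominator. For each target t != control the signed percent error of the
#' fitted ratio is 100 * ((w_t/w_ctrl) - (c_t/c_ctrl)) / (c_t/c_ctrl).
#' A non-positive fitted control weight (possible under unconstrained least
#' squares at very low signal) makes every ratio unreliable; those are
#' returned as `NA` with a message.
#'
#' @param true_c true concentrations (per flavor)
#' @param fitted_w fitted weights (per flavor)
#' @param control_index index of the control flavor
#' @return named signed percent per non-control flavor (NA where excluded)
#' @export
ratio_error <- function(true_c, fitted_w, control_index) {
  stopifnot(length(true_c) == length(fitted_w),
            control_index >= 1, control_index <= length(true_c))
  if (true_c[control_index] == 0)
    stop("ratio errors undefined: true control concentration is zero")
  targets <- setdiff(seq_along(true_c), control_index)
  out <- stats::setNames(rep(NA_real_, length(targets)),
                         paste0("flavor", targets))
  if (fitted_w[control_index] <= 0) {
    message("fitted control weight <= 0; ", length(targets),
            " ratio error(s) flagged unreliable")
    return(out)
  }
  true_ratio <- true_c[targets] / true_c[control_index]
  fit_ratio <- fitted_w[targets] / fitted_w[control_index]
  out[] <- 100 * (fit_ratio - true_ratio) / true_ratio
  out
}
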