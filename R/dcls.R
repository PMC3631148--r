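#' Build the DCLS design matrix
#'
#' Columns are the flavor references F_1..F_n, the broadband background
#' reference B, and polynomial baseline terms P_0..P_3 of order 0-3
#' evaluated on the axis affinely mapped to [-1, 1] (for conditioning; raw
#' wavenumber monomials of order 3 would span ~10^9 in magnitude). The
#' background scale and the baseline coefficients are therefore estimated
#' jointly with the flavor weights in one linear least-squares solve.
#'
#' @param library a [spectral_library]
#' @param poly_order maximum baseline polynomial order (default 3)
#' @return object of class `dcls_design`: `matrix` (channels x
#'   (n_flavors + 1 + poly_order + 1)), index vectors `flavor_cols`,
#'   `background_col`, `poly_cols`, and the design `condition_number`
#' @export
build_design <- function(library, poly_order = 3L) {
  stopifnot(inherits(library, "spectral_library"), poly_order >= 0)
  Fm <- flavor_matrix(library)
  wn <- library$axis$wavenumbers
  t <- (wn - min(wn)) / diff(range(wn)) * 2 - 1
  P <- vapply(0:poly_order, function(m) t^m, numeric(length(t)))
  colnames(P) <- paste0("P", 0:poly_order)
  X <- cbind(Fm, B = library$background$intensities, P)
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 1e-12 * sv[1]) {
    # report which columns are (nearly) linear combinations of the others
    bad <- colnames(X)[apply(abs(svd(X)$v[, sv <= 1e-12 * sv[1], drop = FALSE]),
                             1, max) > 0.1]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(matrix = X,
                 flavor_cols = seq_len(ncol(Fm)),
                 background_col = ncol(Fm) + 1L,
                 poly_cols = ncol(Fm) + 1L + seq_len(poly_order + 1L),
                 condition_number = sv[1] / sv[length(sv)],
                 library = library),
            class = "dcls_design")
}

#' Demultiplex a spectrum by direct classical least squares
#'
#' Solves min ||S - (sum_n w_n F_n + k B + sum_m a_m P_m)||_2 by QR-based
#' ordinary least squares. The fit is unconstrained by default; with
#' `nonneg = TRUE` the flavor weights are constrained to be nonnegative
#' (active-set elimination) while background and baseline stay free.
#'
#' @param spectrum numeric intensity vector (length = channel count), or a
#'   `simulated_spectrum`
#' @param library a [spectral_library], or a prebuilt [build_design()]
#'   object (reusing a design across many fits avoids refactorizing)
#' @param nonneg constrain flavor weights to be >= 0
#' @param cond_warn warn when the design condition number exceeds this
#' @return object of class `dcls_fit`: `weights` (named, one per flavor),
#'   `background_weight`, `baseline_coeffs` (a_0..a_3), `fitted_full`,
#'   `fitted_particles`, `residual`, `design`
#' @export
dcls_fit <- function(spectrum, library, nonneg = FALSE, cond_warn = 1e8) {
  if (inherits(spectrum, "simulated_spectrum"))
    spectrum <- spectrum$intensities
  design <- if (inherits(library, "dcls_design")) library
            else build_design(library)
  X <- design$matrix
  if (length(spectrum) != nrow(X))
    stop("spectrum has ", length(spectrum), " channels; library has ", nrow(X))
  if (!all(is.finite(spectrum)))
    stop("spectrum contains non-finite values")
  if (design$condition_number > cond_warn)
    warning("ill-conditioned design (condition number ",
            signif(design$condition_number, 3), "); proceeding")
  coef <- qr.coef(qr(X), spectrum)
  if (nonneg) {
    # drop the most negative flavor column and refit until all retained
    # flavor weights are nonnegative; dropped flavors get weight 0
    active <- rep(TRUE, ncol(X))
    repeat {
      neg <- design$flavor_cols[active[design$flavor_cols] &
                                  coef[design$flavor_cols] < 0]
      if (length(neg) == 0L) break
      worst <- neg[which.min(coef[neg])]
      active[worst] <- FALSE
      coef[] <- 0
      coef[active] <- qr.coef(qr(X[, active, drop = FALSE]), spectrum)
    }
  }
  fitted_full <- drop(X %*% coef)
  fitted_particles <- drop(X[, design$flavor_cols, drop = FALSE] %*%
                             coef[design$flavor_cols])
  structure(list(
    weights = stats::setNames(coef[design$flavor_cols],
                              colnames(X)[design$flavor_cols]),
    background_weight = unname(coef[design$background_col]),
    baseline_coeffs = stats::setNames(coef[design$poly_cols],
                                      colnames(X)[design$poly_cols]),
    fitted_full = fitted_full,
    fitted_particles = fitted_particles,
    residual = spectrum - fitted_full,
    design = design),
    class = "dcls_fit")
}

#' @export
print.dcls_fit <- function(x, ...) {
  cat("DCLS fit\n  flavor weights:\n")
  print(round(x$weights, 6))
  cat("  background weight:", signif(x$background_weight, 6), "\n")
  cat("  baseline coeffs:", paste(signif(x$baseline_coeffs, 4),
                                  collapse = " "), "\n")
  cat("  ||residual||:", signif(l2norm(x$residual), 6), "\n")
  invisible(x)
}

# Fit many spectra (columns of S) against one design in a single QR solve.
# Returns the coefficient matrix (columns = replicates); used by the
# Monte-Carlo calibration where refitting per spectrum would dominate.
dcls_fit_batch <- function(S, design) {
  stopifnot(inherits(design, "dcls_design"), nrow(S) == nrow(design$matrix))
  qr.coef(qr(design$matrix), S)
}
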