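#' Run a Monte-Carlo calibration of error versus realized SRI
#'
#' Simulates `n_reps` spectral measurements, demultiplexes each by DCLS, and
#' records the realized SRI together with the measurement error: the signed
#' percent error for a single flavor, the composite (RMS percent) error for
#' a mixture, or the percent error in a target:control ratio.
#'
#' A target SRI cannot be imposed directly, so the calibration sweeps the
#' noise standard deviation over a grid (log-spaced by default) and lets each
#' replicate land where its realized SRI falls; downstream binning by the
#' observed statistic matches how an experimentalist consumes the result.
#' Replicates are split evenly over the grid.
#'
#' @param library a [spectral_library]
#' @param truth_template a [mixture_truth] fixing concentrations and
#'   background scale; its `noise_sigma` is ignored in favor of the sweep
#' @param noise_sweep vector of noise standard deviations
#' @param n_reps total number of simulated measurements (>= 1000 recommended
#'   for stable percentiles; warns below)
#' @param seed master seed
#' @param error_type `"auto"` (percent error for one flavor, composite for
#'   more), `"percent"`, `"composite"`, or `"ratio"`
#' @param control_index control flavor for `error_type = "ratio"`
#' @param target_index target flavor for `error_type = "ratio"` (default:
#'   first non-control flavor)
#' @return data.frame with columns `sri`, `error`, `noise_sigma`; ratio
#'   replicates with a non-positive fitted control weight are excluded and
#'   counted in attribute `n_excluded`
#' @export
run_calibration <- function(library, truth_template,
                            noise_sweep = default_noise_sweep(library, truth_template),
                            n_reps = 50000L, seed = 1L,
                            error_type = c("auto", "percent", "composite", "ratio"),
                            control_index = length(library$flavors),
                            target_index = NULL) {
  error_type <- match.arg(error_type)
  n_flavors <- length(library$flavors)
  if (error_type == "auto")
    error_type <- if (n_flavors == 1L) "percent" else "composite"
  if (error_type == "percent" && n_flavors != 1L)
    stop("percent error calibration requires a single-flavor library")
  if (n_reps < 1000)
    warning("fewer than 1000 replicates gives unstable percentile estimates")
  if (is.null(target_index))
    target_index <- setdiff(seq_len(n_flavors), control_index)[1]

  design <- build_design(library)
  per_level <- ceiling(n_reps / length(noise_sweep))
  res <- vector("list", length(noise_sweep))
  n_excluded <- 0L
  for (li in seq_along(noise_sweep)) {
    truth <- mixture_truth(truth_template$concentrations,
                           truth_template$background_scale,
                           noise_sweep[li])
    S <- batch_compose(library, truth, per_level, derive_seed(seed, li))
    m <- fit_metrics_batch(S, design, truth, error_type,
                           control_index, target_index)
    n_excluded <- n_excluded + m$n_excluded
    res[[li]] <- data.frame(sri = m$sri, error = m$error,
                            noise_sigma = noise_sweep[li])
  }
  out <- do.call(rbind, res)
  out <- out[seq_len(min(nrow(out), n_reps)), , drop = FALSE]
  out <- out[is.finite(out$sri) & is.finite(out$error), , drop = FALSE]
  if (nrow(out) == 0L)
    stop("calibration produced no usable fits; check library and noise sweep")
  attr(out, "n_excluded") <- n_excluded
  rownames(out) <- NULL
  out
}

# Fit every column of S against one design and return per-replicate SRI and
# error. All replicates share the QR factorization, which is what keeps a
# 50,000-spectrum calibration to seconds instead of hours.
fit_metrics_batch <- function(S, design, truth, error_type,
                              control_index, target_index) {
  X <- design$matrix
  coef <- qr.coef(qr(X), S)                       # p x n_reps
  fitted_full <- X %*% coef
  Wf <- coef[design$flavor_cols, , drop = FALSE]  # flavor weights
  particles <- X[, design$flavor_cols, drop = FALSE] %*% Wf
  resid <- S - fitted_full
  subtracted <- particles + resid                 # S - (kB + baseline)
  part_norm <- sqrt(colSums(particles^2))
  sub_norm <- sqrt(colSums(subtracted^2))
  sri <- ifelse(sub_norm > 1e-12, pmin(pmax(part_norm / sub_norm, 0), 1),
                NA_real_)
  n_excluded <- 0L
  if (error_type == "percent") {
    err <- 100 * (Wf[1, ] - truth$concentrations[1]) / truth$concentrations[1]
  } else if (error_type == "composite") {
    pe <- 100 * (Wf - truth$concentrations) / truth$concentrations
    err <- sqrt(colMeans(pe^2))
  } else {                                        # ratio
    ctrl <- Wf[control_index, ]
    true_ratio <- truth$concentrations[target_index] /
      truth$concentrations[control_index]
    err <- ifelse(ctrl > 0,
                  100 * (Wf[target_index, ] / ctrl - true_ratio) / true_ratio,
                  NA_real_)
    n_excluded <- sum(ctrl <= 0)
  }
  list(sri = sri, error = err, n_excluded = n_excluded)
}

#' Default noise sweep for a calibration
#'
#' Log-spaced noise standard deviations scaled to the noiseless spectrum's
#' RMS amplitude, spanning from 1/100 of it (near-perfect fits, SRI close
#' to 1) up to 2x (fits dominated by noise, low SRI), so that realized SRI
#' covers the full range the lookup tables need.
#'
#' @param library a [spectral_library]
#' @param truth a [mixture_truth]
#' The grid is dense (100 points by default) so that every SRI bin blends a
#' near-continuum of noise levels; with a coarse grid the error sample inside
#' a bin is a mixture of a few discrete noise conditions, which no single
#' gamma distribution represents well.
#'
#' @param n number of grid points
#' @return numeric vector of noise sigmas
#' @export
default_noise_sweep <- function(library, truth, n = 100L) {
  base_rms <- sqrt(mean(noiseless_spectrum(library, truth)^2))
  10^seq(log10(0.01 * base_rms), log10(2 * base_rms), length.out = n)
}

#' Bin calibration pairs by realized SRI
#'
#' Partitions \[0, 1\] into bins of width `bin_width` and assigns every
#' (SRI, error) pair to exactly one bin. Occupied bins holding fewer than
#' `min_count` samples are merged with their neighbor (message logged) so
#' every returned bin supports a stable distribution fit.
#'
#' @param pairs data.frame from [run_calibration()]
#' @param bin_width bin width in SRI units, in (0, 1); default 0.02
#' @param min_count minimum samples per returned bin
#' @return list of `sri_bin` objects: `sri_low`, `sri_high`, `center`,
#'   `errors`, `sris`, `n`
#' @export
bin_by_sri <- function(pairs, bin_width = 0.02, min_count = 200L) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0,
            bin_width > 0, bin_width < 1)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  idx <- findInterval(pairs$sri, breaks, rightmost.closed = TRUE)
  occupied <- sort(unique(idx))
  raw <- lapply(occupied, function(b) {
    sel <- idx == b
    list(lo = breaks[b], hi = breaks[b + 1L],
         errors = pairs$error[sel], sris = pairs$sri[sel])
  })
  # merge under-occupied bins into their (SRI-adjacent) successor; a small
  # trailing bin merges backwards into the last kept bin
  merged <- list()
  carry <- NULL
  for (b in raw) {
    if (!is.null(carry)) {
      b$lo <- carry$lo
      b$errors <- c(carry$errors, b$errors)
      b$sris <- c(carry$sris, b$sris)
      carry <- NULL
    }
    if (length(b$errors) < min_count) {
      message("SRI bin [", b$lo, ", ", b$hi, ") holds ", length(b$errors),
              " < ", min_count, " samples; merging with neighbor")
      carry <- b
    } else merged[[length(merged) + 1L]] <- b
  }
  if (!is.null(carry)) {
    if (length(merged) > 0L) {
      last <- merged[[length(merged)]]
      last$hi <- carry$hi
      last$errors <- c(last$errors, carry$errors)
      last$sris <- c(last$sris, carry$sris)
      merged[[length(merged)]] <- last
    } else merged[[1L]] <- carry     # everything was sparse: keep one bin
  }
  lapply(merged, function(b) {
    structure(list(sri_low = b$lo, sri_high = b$hi,
                   center = (b$lo + b$hi) / 2,
                   errors = b$errors, sris = b$sris,
                   n = length(b$errors)),
              class = "sri_bin")
  })
}

#' Fit a parametric model to an error sample
#'
#' Single-flavor signed percent errors are modeled as Gaussian; composite
#' errors of mixtures (nonnegative by construction) as gamma with location
#' fixed at zero. Fitting is maximum likelihood. For mixtures the Gaussian
#' log-likelihood is also recorded so the two families can be compared.
#' Degenerate (zero-variance) samples yield a point-mass descriptor.
#'
#' @param samples numeric error values (percent); >= 30 required, < 200
#'   draws a warning
#' @param flavor_count number of flavors the errors came from; selects the
#'   family (1 = gaussian, > 1 = gamma)
#' @return object of class `error_distribution`: `samples`, `family`,
#'   `params`, `n`, `loglik`, and for gamma fits `loglik_gaussian`
#' @export
fit_distribution <- function(samples, flavor_count) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), flavor_count >= 1)
  n <- length(samples)
  if (n < 30) stop("at least 30 samples are needed for a distribution fit")
  if (n < 200) warning("fewer than 200 samples; fitted percentiles are noisy")
  if (stats::sd(samples) == 0)
    return(structure(list(samples = samples, family = "point",
                          params = c(value = samples[1]), n = n,
                          loglik = Inf),
                     class = "error_distribution"))
  if (flavor_count == 1L) {
    mu <- mean(samples)
    sigma <- sqrt(mean((samples - mu)^2))          # ML estimate
    ll <- sum(stats::dnorm(samples, mu, sigma, log = TRUE))
    structure(list(samples = samples, family = "gaussian",
                   params = c(mean = mu, sd = sigma), n = n, loglik = ll),
              class = "error_distribution")
  } else {
    if (any(samples < 0))
      stop("gamma family requires nonnegative composite errors")
    fit <- fitdistrplus::fitdist(samples, "gamma", method = "mle",
                                 keepdata = FALSE)
    mu <- mean(samples)
    sigma <- sqrt(mean((samples - mu)^2))
    structure(list(samples = samples, family = "gamma",
                   params = fit$estimate, n = n,
                   loglik = fit$loglik,
                   loglik_gaussian = sum(stats::dnorm(samples, mu, sigma,
                                                      log = TRUE))),
              class = "error_distribution")
  }
}

#' Confidence-bounded error value from a fitted error distribution
#'
#' For a gamma model of composite errors this is the `confidence`-percentile
#' of the fitted CDF (e.g. e80 at confidence 80). For a Gaussian model of
#' signed single-flavor errors it is the bound b such that the central
#' probability mass P(|error| <= b) equals the confidence -- the half-width
#' of the shaded central region of the error histogram. An empirical mode
#' returns the corresponding sample percentile instead of the fitted one.
#'
#' @param dist an [fit_distribution()] result
#' @param confidence percentile level in (0, 100); default 80
#' @param method `"parametric"` (fitted CDF, default) or `"empirical"`
#' @return error bound in percent
#' @export
e_percentile <- function(dist, confidence = 80,
                         method = c("parametric", "empirical")) {
  stopifnot(inherits(dist, "error_distribution"),
            confidence > 0, confidence < 100)
  method <- match.arg(method)
  p <- confidence / 100
  if (dist$family == "point") return(unname(abs(dist$params["value"])))
  if (method == "empirical") {
    x <- if (dist$family == "gaussian") abs(dist$samples) else dist$samples
    return(unname(stats::quantile(x, p, names = FALSE)))
  }
  if (dist$family == "gaussian") {
    mu <- dist$params["mean"]; sigma <- dist$params["sd"]
    if (abs(mu) < 1e-12)
      return(unname(sigma * stats::qnorm(0.5 + p / 2)))
    f <- function(b) stats::pnorm(b, mu, sigma) - stats::pnorm(-b, mu, sigma) - p
    upper <- abs(mu) + 10 * sigma
    return(stats::uniroot(f, c(0, upper), tol = 1e-10)$root)
  }
  unname(stats::qgamma(p, shape = dist$params["shape"],
                       rate = dist$params["rate"]))
}

#' Error-versus-SRI curve at a confidence level
#'
#' One confidence-bounded error value (e.g. e80) per SRI bin. Sampling noise
#' can produce small non-monotonic wiggles, so the curve is optionally
#' regularized to be non-increasing in SRI by isotonic regression (the
#' physically expected shape: more reliable fits cannot carry larger error
#' bounds); when smoothing changes any value a message is logged.
#'
#' @param bins list of bins from [bin_by_sri()]
#' @param confidence percentile level in (0, 100)
#' @param flavor_count flavor count passed to [fit_distribution()]
#' @param isotonic enforce e non-increasing in SRI (default TRUE)
#' @param method percentile method, see [e_percentile()]
#' @return data.frame with `sri` (bin center), `e` (smoothed bound, %),
#'   `e_raw`, `n` (bin occupancy), sorted by `sri`
#' @export
error_vs_sri_curve <- function(bins, confidence = 80, flavor_count = 2L,
                               isotonic = TRUE,
                               method = c("parametric", "empirical")) {
  stopifnot(length(bins) >= 2)
  method <- match.arg(method)
  sri_c <- vapply(bins, `[[`, numeric(1), "center")
  ord <- order(sri_c)
  bins <- bins[ord]; sri_c <- sri_c[ord]
  e_raw <- vapply(bins, function(b) {
    e_percentile(fit_distribution(b$errors, flavor_count), confidence,
                 method = method)
  }, numeric(1))
  n <- vapply(bins, `[[`, numeric(1), "n")
  e <- e_raw
  if (isotonic && length(e) > 1) {
    iso <- stats::isoreg(sri_c, -e_raw)            # non-decreasing in -e
    e <- -iso$yf
    if (max(abs(e - e_raw)) > 1e-12)
      message("isotonic smoothing adjusted ", sum(abs(e - e_raw) > 1e-12),
              " of ", length(e), " curve points")
  }
  data.frame(sri = sri_c, e = e, e_raw = e_raw, n = n)
}

#' Minimum SRI guaranteeing an error bound
#'
#' The smallest SRI at which the calibrated confidence-bounded error drops
#' to or below `error_bound`: the crossing point of the (smoothed) curve is
#' found by linear interpolation between adjacent bin centers and then
#' padded by `margin` -- half a bin width by default. The padding gives the
#' threshold guarantee semantics: a measurement whose realized SRI reaches
#' the returned value satisfies the bound even if binning granularity
#' places it up to half a bin below the calibrated center, rather than
#' sitting exactly on the e-percentile = bound knife edge.
#'
#' If even the best calibrated bin exceeds the bound the criterion is not
#' achievable within the calibrated range; `NA` is returned with attribute
#' `reason = "not achievable"` -- the curve is never extrapolated.
#'
#' @param curve data.frame from [error_vs_sri_curve()]
#' @param error_bound maximum tolerated error in percent
#' @param margin padding added above the interpolated crossing; defaults to
#'   half the median spacing of the curve's bin centers. Not applied when
#'   the whole curve already satisfies the bound (the lowest calibrated bin
#'   is returned as-is), and never pushed past the highest calibrated bin.
#' @return minimum SRI, or `NA` when the bound is unreachable
#' @export
min_sri_for_bound <- function(curve, error_bound = 10, margin = NULL) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 1, error_bound > 0)
  curve <- curve[order(curve$sri), , drop = FALSE]
  if (is.null(margin))
    margin <- if (nrow(curve) > 1) stats::median(diff(curve$sri)) / 2 else 0
  ok <- curve$e <= error_bound
  if (!any(ok))
    return(structure(NA_real_, reason = "not achievable"))
  first <- which(ok)[1]
  if (first == 1L) return(curve$sri[1])            # whole curve satisfies
  # interpolate the crossing between the last failing and first passing bin
  x0 <- curve$sri[first - 1L]; y0 <- curve$e[first - 1L]
  x1 <- curve$sri[first];      y1 <- curve$e[first]
  crossing <- if (y0 == y1) x1
              else x0 + (y0 - error_bound) / (y0 - y1) * (x1 - x0)
  min(crossing + margin, curve$sri[nrow(curve)])
}

#' Simulate fresh measurements pinned at a target realized SRI
#'
#' Validation counterpart of [run_calibration()]: generates spectra whose
#' realized SRI falls within `tol` of `sri_target` by first locating, with a
#' pilot sweep, the noise levels that produce such SRIs, then simulating at
#' those levels and keeping only replicates landing inside the window.
#' Used to verify that a calibrated minimum-SRI threshold actually delivers
#' its error bound on data it has never seen.
#'
#' @param library a [spectral_library]
#' @param truth_template a [mixture_truth]; its noise level is ignored
#' @param sri_target target realized SRI in (0, 1)
#' @param n number of pinned replicates to collect
#' @param seed master seed (distinct from the calibration seed for a true
#'   hold-out)
#' @param tol half-width of the accepted SRI window (default 0.01, half the
#'   default calibration bin width)
#' @param error_type,control_index,target_index as in [run_calibration()]
#' @param max_batches safety cap on simulation rounds
#' @return data.frame with `sri` and `error` for the pinned replicates
#' @export
simulate_at_sri <- function(library, truth_template, sri_target, n = 5000L,
                            seed = 1L, tol = 0.01,
                            error_type = c("auto", "percent", "composite", "ratio"),
                            control_index = length(library$flavors),
                            target_index = NULL, max_batches = 200L) {
  stopifnot(sri_target > 0, sri_target < 1, n >= 1)
  error_type <- match.arg(error_type)
  n_flavors <- length(library$flavors)
  if (error_type == "auto")
    error_type <- if (n_flavors == 1L) "percent" else "composite"
  if (is.null(target_index))
    target_index <- setdiff(seq_len(n_flavors), control_index)[1]
  design <- build_design(library)

  # pilot: median realized SRI per noise level on a dense grid
  sweep <- default_noise_sweep(library, truth_template, n = 60L)
  med <- vapply(seq_along(sweep), function(li) {
    truth <- mixture_truth(truth_template$concentrations,
                           truth_template$background_scale, sweep[li])
    S <- batch_compose(library, truth, 30L, derive_seed(seed, 100000L + li))
    stats::median(fit_metrics_batch(S, design, truth, error_type,
                                    control_index, target_index)$sri,
                  na.rm = TRUE)
  }, numeric(1))
  # simulate at the levels bracketing the target until n pinned replicates
  cand <- order(abs(med - sri_target))[1:5]
  got_sri <- numeric(0); got_err <- numeric(0)
  batch <- 0L
  while (length(got_sri) < n && batch < max_batches) {
    batch <- batch + 1L
    li <- cand[(batch - 1L) %% length(cand) + 1L]
    truth <- mixture_truth(truth_template$concentrations,
                           truth_template$background_scale, sweep[li])
    S <- batch_compose(library, truth, 2000L, derive_seed(seed, batch))
    m <- fit_metrics_batch(S, design, truth, error_type,
                           control_index, target_index)
    keep <- !is.na(m$sri) & abs(m$sri - sri_target) <= tol &
      is.finite(m$error)
    got_sri <- c(got_sri, m$sri[keep])
    got_err <- c(got_err, m$error[keep])
  }
  if (length(got_sri) < n)
    warning("collected only ", length(got_sri), " of ", n,
            " pinned replicates within the SRI window")
  data.frame(sri = got_sri[seq_len(min(n, length(got_sri)))],
             error = got_err[seq_len(min(n, length(got_err)))])
}

#' Build reliability lookup tables across mixture ratios
#'
#' For each requested target:control mixture ratio, runs a full Monte-Carlo
#' calibration, derives the error-vs-SRI curve at the requested confidence,
#' and records the minimum SRI for each error bound. The resulting tables
#' are the precomputed lookup an assessment workflow consults in real time.
#' Each table carries full provenance: seed, replicate count, noise sweep,
#' and the hash of the library it was calibrated against.
#'
#' @param library a two-or-more-flavor [spectral_library]; the first flavor
#'   is the target whose concentration is scaled by the ratio, the control
#'   keeps concentration 1
#' @param ratios numeric target:control ratios (e.g. `c(0.2, 1, 5)` for
#'   1:5, 1:1 and 5:1)
#' @param confidence percentile level (default 80)
#' @param error_bounds error bounds in percent for the min-SRI map
#' @param n_reps replicates per ratio
#' @param seed master seed
#' @param background_scale background scale k of the simulated truths
#' @param bin_width,min_count passed to [bin_by_sri()]
#' @param error_type passed to [run_calibration()] (composite by default)
#' @return list of `reliability_table` objects
#' @export
build_reliability_table <- function(library, ratios, confidence = 80,
                                    error_bounds = 10, n_reps = 20000L,
                                    seed = 1L, background_scale = 1,
                                    bin_width = 0.02, min_count = 200L,
                                    error_type = "composite") {
  stopifnot(length(ratios) >= 1, all(ratios > 0),
            length(library$flavors) >= 2)
  lib_hash <- library_hash(library)
  lapply(seq_along(ratios), function(ri) {
    r <- ratios[ri]
    conc <- c(r, rep(1, length(library$flavors) - 1L))
    truth <- mixture_truth(conc, background_scale, 0)
    sweep <- default_noise_sweep(library, truth)
    pairs <- run_calibration(library, truth, noise_sweep = sweep,
                             n_reps = n_reps, seed = derive_seed(seed, ri),
                             error_type = error_type,
                             control_index = length(library$flavors))
    bins <- bin_by_sri(pairs, bin_width, min_count)
    curve <- error_vs_sri_curve(bins, confidence,
                                flavor_count = length(library$flavors))
    min_sri <- vapply(error_bounds, function(b) min_sri_for_bound(curve, b),
                      numeric(1))
    structure(list(
      schema_version = "1.0",
      mixture_ratio = r,
      confidence = confidence,
      rows = curve,
      min_sri_for = stats::setNames(min_sri, as.character(error_bounds)),
      provenance = list(seed = seed, sub_seed = derive_seed(seed, ri),
                        n_reps = n_reps, noise_sweep = sweep,
                        bin_width = bin_width, min_count = min_count,
                        background_scale = background_scale,
                        error_type = error_type,
                        library_hash = lib_hash)),
      class = "reliability_table")
  })
}

#' @export
print.reliability_table <- function(x, ...) {
  cat("Reliability table (mixture ratio ", x$mixture_ratio, ":1, ",
      x$confidence, "% confidence)\n", sep = "")
  cat("  ", nrow(x$rows), " SRI bins, ", sum(x$rows$n), " samples\n", sep = "")
  for (b in names(x$min_sri_for))
    cat("  min SRI for error <= ", b, "%: ",
        signif(x$min_sri_for[[b]], 4), "\n", sep = "")
  invisible(x)
}
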