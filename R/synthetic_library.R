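#' Construct a spectral axis
#'
#' The common Raman-shift grid on which every spectrum in a library lives.
#' The default spans the fingerprint region 800-1800 cm^-1 with 1024
#' channels, a typical spectroscopic-CCD column count.
#'
#' @param from,to axis limits in cm^-1
#' @param channels number of spectral channels (>= 16)
#' @return an object of class `spectral_axis` with fields `wavenumbers`
#'   (strictly increasing numeric vector) and `channel_count`
#' @export
spectral_axis <- function(from = 800, to = 1800, channels = 1024L) {
  stopifnot(is.numeric(from), is.numeric(to), to > from)
  channels <- as.integer(channels)
  if (channels < 16L)
    stop("a spectral axis needs at least 16 channels")
  structure(
    list(wavenumbers = seq(from, to, length.out = channels),
         channel_count = channels),
    class = "spectral_axis")
}

channel_spacing <- function(axis) {
  diff(range(axis$wavenumbers)) / (axis$channel_count - 1L)
}

#' Generate a synthetic SERS flavor reference spectrum
#'
#' A flavor fingerprint is modeled as a sum of sharp Lorentzian lines --
#' the canonical Raman lineshape -- with seeded-random centers, widths and
#' amplitudes, normalized to unit peak maximum. Deterministic for a fixed
#' seed.
#'
#' @param seed integer seed
#' @param axis a [spectral_axis]
#' @param n_peaks number of Lorentzian lines (>= 1)
#' @param width_range half-width-at-half-maximum interval in cm^-1; must be
#'   resolvable on the axis (lower bound > channel spacing)
#' @param label flavor identifier
#' @return object of class `reference_spectrum` with `label` and
#'   `intensities` (nonnegative, unit maximum)
#' @export
generate_flavor <- function(seed, axis, n_peaks = 8L,
                            width_range = c(4, 12),
                            label = sprintf("F%03d", seed %% 1000L)) {
  stopifnot(inherits(axis, "spectral_axis"), n_peaks >= 1,
            length(width_range) == 2L, all(width_range > 0),
            width_range[1] <= width_range[2])
  if (width_range[1] < channel_spacing(axis))
    stop("axis too coarse to resolve peaks of width ", width_range[1],
         " cm^-1 (channel spacing ", signif(channel_spacing(axis), 4), ")")
  wn <- axis$wavenumbers
  span <- diff(range(wn))
  if (width_range[2] > span / 10)
    stop("requested peak widths are not narrow relative to the axis span")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  # keep centers off the extreme edges so peaks are fully on-axis
  centers <- stats::runif(n_peaks, min(wn) + 0.05 * span, max(wn) - 0.05 * span)
  gammas  <- stats::runif(n_peaks, width_range[1], width_range[2])
  amps    <- stats::runif(n_peaks, 0.2, 1)
  y <- numeric(length(wn))
  for (p in seq_len(n_peaks))
    y <- y + amps[p] * gammas[p]^2 / ((wn - centers[p])^2 + gammas[p]^2)
  y <- y / max(y)
  structure(list(label = label, intensities = y),
            class = "reference_spectrum")
}

#' Generate a smooth broadband background spectrum
#'
#' A positive, spectrally smooth curve: a low-order polynomial trend plus one
#' broad Gaussian hump, normalized to unit maximum. The minimum feature width
#' (`smoothness`) encodes the assumption that backgrounds -- stray laser
#' light and the long-wavelength autofluorescence tail -- are broadband
#' relative to the sharp SERS peaks.
#'
#' @param seed integer seed
#' @param axis a [spectral_axis]
#' @param smoothness minimum feature width in cm^-1; must exceed twice the
#'   channel spacing, and should exceed flavor peak widths several-fold
#' @return object of class `background_spectrum`
#' @export
generate_background <- function(seed, axis, smoothness = 300) {
  stopifnot(inherits(axis, "spectral_axis"), smoothness > 0)
  if (smoothness < 2 * channel_spacing(axis))
    stop("smoothness ", smoothness, " cm^-1 is below twice the channel spacing")
  wn <- axis$wavenumbers
  span <- diff(range(wn))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  t <- (wn - min(wn)) / span * 2 - 1                  # [-1, 1]
  coefs <- stats::runif(3, -0.3, 0.3)
  hump_c <- stats::runif(1, min(wn) + 0.2 * span, max(wn) - 0.2 * span)
  hump_w <- max(smoothness, stats::runif(1, smoothness, 2 * smoothness))
  y <- 1 + coefs[1] * t + coefs[2] * t^2 + coefs[3] * t^3 +
    stats::runif(1, 0.5, 1.5) * exp(-(wn - hump_c)^2 / (2 * (hump_w / 2.355)^2))
  y <- y - min(y) + 0.1 * diff(range(y))              # strictly positive
  y <- y / max(y)
  structure(list(intensities = y), class = "background_spectrum")
}

#' Build a synthetic spectral library
#'
#' Generates `n_flavors` distinct flavor references plus one broadband
#' background on a shared axis. Per-flavor sub-seeds are derived
#' deterministically from the master seed, so a library is extensible: the
#' first k flavors of an (n>k)-flavor library equal the k-flavor library from
#' the same seed. A degenerate (rank-deficient or near-collinear) draw is
#' regenerated from a perturbed sub-seed with a message.
#'
#' @param seed master seed
#' @param axis a [spectral_axis]
#' @param n_flavors number of flavors (>= 1)
#' @param n_peaks,width_range passed to [generate_flavor()]
#' @param smoothness passed to [generate_background()]
#' @return object of class `spectral_library`: fields `axis`, `flavors`
#'   (list of `reference_spectrum`), `background`, and `condition_number`
#'   of the flavor design matrix
#' @export
build_library <- function(seed, axis = spectral_axis(), n_flavors = 2L,
                          n_peaks = 8L, width_range = c(4, 12),
                          smoothness = 300) {
  stopifnot(n_flavors >= 1)
  flavors <- vector("list", n_flavors)
  for (i in seq_len(n_flavors)) {
    sub <- derive_seed(seed, i)
    f <- generate_flavor(sub, axis, n_peaks, width_range,
                         label = sprintf("S%03d", 400L + i))
    attempt <- 0L
    while (attempt < 5L && i > 1L &&
           max_cosine(f$intensities, flavors[seq_len(i - 1L)]) > 0.95) {
      attempt <- attempt + 1L
      message("flavor ", i, " too collinear with an earlier flavor; ",
              "regenerating with perturbed sub-seed")
      f <- generate_flavor(derive_seed(sub, 7919L * attempt), axis, n_peaks,
                           width_range, label = sprintf("S%03d", 400L + i))
    }
    flavors[[i]] <- f
  }
  bg <- generate_background(derive_seed(seed, 0L), axis, smoothness)
  lib <- structure(
    list(axis = axis, flavors = flavors, background = bg,
         condition_number = NA_real_),
    class = "spectral_library")
  Fm <- flavor_matrix(lib)
  sv <- svd(Fm, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 1e-10 * sv[1])
    stop("generated library is rank deficient; choose a different seed")
  lib$condition_number <- sv[1] / sv[length(sv)]
  lib
}

max_cosine <- function(x, flavor_list) {
  if (length(flavor_list) == 0L) return(0)
  max(vapply(flavor_list, function(f) {
    sum(x * f$intensities) / (l2norm(x) * l2norm(f$intensities))
  }, numeric(1)))
}

#' Flavor design matrix of a library
#'
#' @param library a [spectral_library]
#' @return channels x n_flavors matrix with flavor labels as column names
#' @export
flavor_matrix <- function(library) {
  m <- vapply(library$flavors, function(f) f$intensities,
              numeric(library$axis$channel_count))
  m <- matrix(m, nrow = library$axis$channel_count)
  colnames(m) <- vapply(library$flavors, function(f) f$label, character(1))
  m
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("Synthetic SERS spectral library\n")
  cat("  axis: ", min(x$axis$wavenumbers), "-", max(x$axis$wavenumbers),
      " cm^-1, ", x$axis$channel_count, " channels\n", sep = "")
  cat("  flavors:", paste(vapply(x$flavors, `[[`, character(1), "label"),
                          collapse = ", "), "\n")
  cat("  flavor design condition number:",
      signif(x$condition_number, 4), "\n")
  invisible(x)
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
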