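#' Define the ground truth of a simulated mixture
#'
#' @param concentrations nonnegative amplitude per flavor (dimensionless,
#'   relative to the unit-maximum references)
#' @param background_scale nonnegative scale factor applied to the broadband
#'   background reference
#' @param noise_sigma standard deviation of the additive zero-mean Gaussian
#'   noise, in the same arbitrary units as the intensities
#' @return object of class `mixture_truth`
#' @export
mixture_truth <- function(concentrations, background_scale = 1,
                          noise_sigma = 0) {
  stopifnot(is.numeric(concentrations), all(is.finite(concentrations)),
            all(concentrations >= 0),
            length(background_scale) == 1L, background_scale >= 0,
            length(noise_sigma) == 1L, noise_sigma >= 0)
  structure(list(concentrations = as.numeric(concentrations),
                 background_scale = as.numeric(background_scale),
                 noise_sigma = as.numeric(noise_sigma)),
            class = "mixture_truth")
}

# noiseless part of the forward model: sum_n c_n F_n + k B
noiseless_spectrum <- function(library, truth) {
  drop(flavor_matrix(library) %*% truth$concentrations) +
    truth$background_scale * library$background$intensities
}

#' Simulate one measured spectrum
#'
#' Forward model: X = sum_n c_n F_n + k B + delta, with delta i.i.d.
#' Gaussian(0, noise_sigma^2) per channel. Negative intensities produced by
#' noise are retained (clipping would bias the least-squares fit).
#'
#' @param library a [spectral_library]
#' @param truth a [mixture_truth] whose concentration vector matches the
#'   library's flavor count
#' @param seed integer seed; the spectrum is deterministic given the seed
#' @return object of class `simulated_spectrum` with `intensities`, `truth`,
#'   `seed`
#' @export
compose_spectrum <- function(library, truth, seed) {
  stopifnot(inherits(library, "spectral_library"),
            inherits(truth, "mixture_truth"))
  if (length(truth$concentrations) != length(library$flavors))
    stop("truth has ", length(truth$concentrations),
         " concentrations but the library has ", length(library$flavors),
         " flavors")
  x <- noiseless_spectrum(library, truth)
  if (truth$noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    x <- x + stats::rnorm(length(x), 0, truth$noise_sigma)
  }
  structure(list(intensities = x, truth = truth, seed = as.integer(seed)),
            class = "simulated_spectrum")
}

#' Simulate a batch of independent spectra
#'
#' Replicate spectra share the ground truth; each replicate draws its noise
#' from a sub-seed derived from the master seed, so the batch is reproducible
#' and replicate `i` is independent of batch size.
#'
#' Returned as a channels x n_reps matrix rather than a list, which keeps
#' large Monte-Carlo calibrations (tens of thousands of replicates) cheap.
#'
#' @param library a [spectral_library]
#' @param truth a [mixture_truth]
#' @param n_reps number of replicates (>= 1)
#' @param seed master seed
#' @return matrix (channels x n_reps) with attribute `truth`
#' @export
batch_compose <- function(library, truth, n_reps, seed) {
  stopifnot(n_reps >= 1)
  n_reps <- as.integer(n_reps)
  base <- noiseless_spectrum(library, truth)
  nc <- library$axis$channel_count
  out <- matrix(base, nrow = nc, ncol = n_reps)
  if (truth$noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    # one derived stream per batch; replicate i occupies column i, identical
    # to compose_spectrum(derive_seed(seed, i)) draw-for-draw
    for (i in seq_len(n_reps)) {
      set.seed(derive_seed(seed, i))
      out[, i] <- out[, i] + stats::rnorm(nc, 0, truth$noise_sigma)
    }
  }
  attr(out, "truth") <- truth
  out
}
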