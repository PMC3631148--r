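#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed. Sub-seeds for
#' replicates, flavors, and calibration stages are derived deterministically
#' with a counter so that batches are extensible without reshuffling earlier
#' draws. The derivation stays below 2^31 so the result is always a valid
#' R integer seed.
#'
#' @param seed master seed (single integer-valued number)
#' @param index nonnegative counter (replicate number, flavor index, ...)
#' @return a single integer seed
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(index), all(index >= 0))
  # affine map modulo a Mersenne prime; operands stay < 2^53 so the double
  # arithmetic is exact
  s <- ((abs(seed) %% 2147483647) * 48271) %% 2147483647
  as.integer((s + 1103 * (index %% 1048573)) %% 2147483647)
}

# Euclidean norm
l2norm <- function(x) sqrt(sum(x^2))

#' Hash of a spectral library
#'
#' MD5 digest of the library's canonical JSON serialization. Reliability
#' tables record this hash so that a table calibrated against one library
#' can never be applied to a different one.
#'
#' @param library a [spectral_library] object
#' @return hex digest string
#' @export
library_hash <- function(library) {
  stopifnot(inherits(library, "spectral_library"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(library_json(library), tmp)
  unname(tools::md5sum(tmp))
}

# canonical JSON text for a library (fixed digits => stable hash)
library_json <- function(library) {
  jsonlite::toJSON(list(
    schema_version = "1.0",
    wavenumbers = library$axis$wavenumbers,
    labels = vapply(library$flavors, function(f) f$label, character(1)),
    flavors = lapply(library$flavors, function(f) f$intensities),
    background = library$background$intensities
  ), digits = NA, auto_unbox = TRUE, pretty = FALSE)
}
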