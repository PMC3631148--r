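# Shared fixtures: small, fast synthetic libraries built in code.

# compact axis for unit tests (cheap QR factorizations)
small_axis <- function(channels = 256L) spectral_axis(800, 1800, channels)

small_library <- function(seed = 42, n_flavors = 2L, channels = 256L) {
  build_library(seed, small_axis(channels), n_flavors = n_flavors)
}

# default-scale library used by end-to-end and acceptance-style tests
full_library <- function(seed = 42, n_flavors = 2L) {
  build_library(seed, n_flavors = n_flavors)
}

# independent least-squares oracle: explicit normal equations, no QR
normal_equations_fit <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}
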