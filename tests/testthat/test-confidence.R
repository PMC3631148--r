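# shared small calibration reused across tests in this file
calib_env <- new.env()
get_calib <- function() {
  if (is.null(calib_env$pairs)) {
    lib <- small_library()
    truth <- mixture_truth(c(1, 1), 1, 0)
    calib_env$lib <- lib
    calib_env$pairs <- run_calibration(lib, truth, n_reps = 12000L, seed = 5)
    calib_env$bins <- suppressMessages(bin_by_sri(calib_env$pairs, 0.02, 200))
  }
  calib_env
}

test_that("calibration is reproducible and covers the SRI range", {
  ce <- get_calib()
  expect_true(all(c("sri", "error", "noise_sigma") %in% names(ce$pairs)))
  expect_true(all(ce$pairs$sri >= 0 & ce$pairs$sri <= 1))
  expect_true(all(ce$pairs$error >= 0))
  expect_lt(min(ce$pairs$sri), 0.4)
  expect_gt(max(ce$pairs$sri), 0.95)
  again <- run_calibration(calib_env$lib, mixture_truth(c(1, 1), 1, 0),
                           n_reps = 12000L, seed = 5)
  expect_identical(ce$pairs, again)
})

test_that("zero-noise sweep point yields near-zero error and SRI near 1", {
  lib <- small_library()
  truth <- mixture_truth(c(1, 1), 1, 0)
  pairs <- run_calibration(lib, truth, noise_sweep = 1e-9, n_reps = 1000,
                           seed = 2)
  expect_lt(max(pairs$error), 1e-4)
  expect_gt(min(pairs$sri), 1 - 1e-6)
})

test_that("binning partitions the sample and matches a brute-force histogram", {
  ce <- get_calib()
  expect_equal(sum(vapply(ce$bins, `[[`, numeric(1), "n")), nrow(ce$pairs))
  for (b in ce$bins) {
    expect_true(all(b$sris >= b$sri_low - 1e-12))
    expect_true(all(b$sris <= b$sri_high + 1e-12))
    expect_gte(b$n, 200)
  }
  # brute-force recount on the unmerged grid agrees with bin totals
  h <- table(cut(ce$pairs$sri, seq(0, 1, 0.02), include.lowest = TRUE))
  expect_equal(sum(h), nrow(ce$pairs))
  one_sri <- data.frame(sri = rep(0.515, 300), error = runif(300),
                        noise_sigma = 1)
  expect_length(bin_by_sri(one_sri, 0.02, 200), 1L)
  expect_error(bin_by_sri(data.frame()), "nrow")
})

test_that("distribution fits recover parameters and pick the right family", {
  set.seed(99)
  g <- fit_distribution(rnorm(4000, 0, 5), flavor_count = 1)
  expect_equal(g$family, "gaussian")
  expect_equal(unname(g$params["sd"]), 5, tolerance = 0.1)

  ga <- fit_distribution(rgamma(4000, shape = 3, rate = 0.5),
                         flavor_count = 2)
  expect_equal(ga$family, "gamma")
  expect_equal(unname(ga$params["shape"]), 3, tolerance = 0.2)
  # proper CDF
  q <- vapply(c(10, 50, 90), function(p) e_percentile(ga, p), numeric(1))
  expect_true(all(diff(q) > 0))

  expect_equal(fit_distribution(rep(7, 250), 2)$family, "point")
  expect_error(fit_distribution(1:10, 1), "30 samples")
  expect_error(fit_distribution(rnorm(500), 2), "nonnegative")
})

test_that("e_percentile matches closed forms and empirical coverage", {
  # point mass
  pm <- fit_distribution(rep(7, 250), 2)
  expect_equal(e_percentile(pm, 80), 7)
  # zero-mean Gaussian sigma = 5: central 80% band is 5 * 1.2816
  g <- structure(list(samples = numeric(0), family = "gaussian",
                      params = c(mean = 0, sd = 5), n = 0, loglik = 0),
                 class = "error_distribution")
  expect_equal(e_percentile(g, 80), 5 * qnorm(0.9), tolerance = 1e-6)
  # biased Gaussian: uniroot solution satisfies the defining equation
  gb <- g; gb$params <- c(mean = 2, sd = 5)
  b <- e_percentile(gb, 80)
  expect_equal(pnorm(b, 2, 5) - pnorm(-b, 2, 5), 0.8, tolerance = 1e-6)
  # gamma e80 covers ~80% of fresh draws from the same distribution
  set.seed(7)
  ga <- fit_distribution(rgamma(5000, 2.5, rate = 0.4), 2)
  e80 <- e_percentile(ga, 80)
  expect_equal(mean(rgamma(20000, 2.5, rate = 0.4) <= e80), 0.8,
               tolerance = 0.02)
  # empirical mode
  expect_equal(e_percentile(ga, 80, method = "empirical"),
               quantile(ga$samples, 0.8, names = FALSE))
})

test_that("error-vs-SRI curve is non-increasing and anchored at the ends", {
  ce <- get_calib()
  curve <- suppressMessages(error_vs_sri_curve(ce$bins, 80, 2))
  expect_true(all(diff(curve$e) <= 1e-12))
  expect_gt(curve$e[1], utils::tail(curve$e, 1))
  expect_lt(utils::tail(curve$e, 1), 5)   # near-noiseless bin: small bound
})

test_that("min_sri_for_bound interpolates, saturates, and refuses to extrapolate", {
  curve <- data.frame(sri = c(0.3, 0.5, 0.7, 0.9), e = c(40, 20, 10, 5),
                      e_raw = c(40, 20, 10, 5), n = rep(1000, 4))
  # raw crossings (margin 0): exact hit and linear interpolation
  expect_equal(min_sri_for_bound(curve, 10, margin = 0), 0.7)
  expect_equal(min_sri_for_bound(curve, 15, margin = 0), 0.6)
  # default margin pads by half the bin spacing (guarantee semantics)
  expect_equal(min_sri_for_bound(curve, 10), 0.8)
  expect_equal(min_sri_for_bound(curve, 15), 0.7)
  expect_equal(min_sri_for_bound(curve, 50), 0.3)  # whole curve satisfies
  expect_equal(min_sri_for_bound(curve, 5), 0.9)   # capped at highest bin
  out <- min_sri_for_bound(curve, 2)
  expect_true(is.na(out))
  expect_equal(attr(out, "reason"), "not achievable")
})

test_that("reliability tables reproduce bit-for-bit and encode the ratio penalty", {
  lib <- small_library()
  tabs <- suppressMessages(build_reliability_table(
    lib, ratios = c(1, 5), n_reps = 8000L, seed = 3))
  tabs2 <- suppressMessages(build_reliability_table(
    lib, ratios = c(1, 5), n_reps = 8000L, seed = 3))
  expect_identical(tabs, tabs2)
  m1 <- tabs[[1]]$min_sri_for[["10"]]
  m5 <- tabs[[2]]$min_sri_for[["10"]]
  # an imbalanced mixture needs a higher SRI for the same error bound
  expect_gt(m5, m1)
  expect_equal(tabs[[1]]$provenance$library_hash, library_hash(lib))
})

test_that("gamma outfits the Gaussian on composite errors in most bins", {
  ce <- get_calib()
  wins <- vapply(ce$bins, function(b) {
    d <- fit_distribution(b$errors, 2)
    d$loglik > d$loglik_gaussian
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
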