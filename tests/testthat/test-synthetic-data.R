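test_that("simulators are bit-identical under identical seeds", {
  p <- kymo_sim_params(duration_s = 5, seed = 3)
  expect_identical(simulate_kymograph(p), simulate_kymograph(p))
  mp <- mixture_sim_params(10.8, 60, 0.4, 50, seed = 9)
  expect_identical(simulate_blink_counts(mp), simulate_blink_counts(mp))
  expect_identical(simulate_dual_color_population(500, 0.3, seed = 4),
                   simulate_dual_color_population(500, 0.3, seed = 4))
  expect_identical(simulate_spectra(0.3, "cd", seed = 8),
                   simulate_spectra(0.3, "cd", seed = 8))
})

test_that("simulators do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(simulate_kymograph(kymo_sim_params(duration_s = 2, seed = 99)))
  expect_identical(runif(1), a)
})

test_that("zero signal and zero noise give a flat background image", {
  sim <- simulate_kymograph(kymo_sim_params(
    duration_s = 3, photons_per_frame = 0, background_sd = 0,
    background_mean = 12, seed = 1))
  expect_true(all(sim$kymograph$intensity == 12))
})

test_that("no blinking means no ground-truth blinks", {
  sim <- simulate_kymograph(kymo_sim_params(blink_rate_per_s = 0,
                                            n_emitters = 1, seed = 6))
  expect_identical(sim$ground_truth$true_blink_count, 0L)
  expect_true(all(sim$ground_truth$emitter_on))
})

test_that("kymograph parameter validation rejects bad inputs", {
  expect_error(kymo_sim_params(duration_s = 1, frame_rate_hz = 0.3), "integer")
  expect_error(kymo_sim_params(n_emitters = 3), "1 \\(monomer\\) or 2")
  expect_error(kymo_sim_params(n_pixels = 3), ">= 5")
  expect_error(kymo_sim_params(psf_sigma_px = 0), "positive")
  expect_error(kymo_sim_params(mean_dark_frames = 0.5), ">= 1")
})

test_that("two emitters blink independently: joint dark fraction is the product", {
  # per-frame blink probability 0.0625 with mean dark dwell 4 frames gives a
  # stationary dark fraction of 0.2 per emitter, hence ~0.04 jointly
  rate <- -10 * log(1 - 0.0625)
  joint <- m1 <- m2 <- 0
  nf <- 0
  for (s in 1:50) {
    sim <- simulate_kymograph(kymo_sim_params(
      n_emitters = 2, blink_rate_per_s = rate, mean_dark_frames = 4,
      photons_per_frame = 0, background_sd = 0, seed = 500 + s))
    on <- sim$ground_truth$emitter_on
    joint <- joint + sum(!on[1, ] & !on[2, ])
    m1 <- m1 + sum(!on[1, ])
    m2 <- m2 + sum(!on[2, ])
    nf <- nf + ncol(on)
  }
  expect_gt(nf, 1e4)
  expect_equal(joint / nf, (m1 / nf) * (m2 / nf), tolerance = 0.01 / 0.04)
})

test_that("image-simulator blink counts match an independent chain oracle", {
  p_blink <- 1 - exp(-0.18 / 10)
  p_recover <- 1 / 3
  sim_counts <- vapply(1:150, function(s) {
    simulate_kymograph(kymo_sim_params(
      photons_per_frame = 0, background_sd = 0,
      seed = 2000 + s))$ground_truth$true_blink_count
  }, integer(1))
  set.seed(424)
  oracle_counts <- replicate(600, chain_blink_count(600, p_blink, p_recover))
  se <- sqrt(stats::var(sim_counts) / length(sim_counts) +
               stats::var(oracle_counts) / length(oracle_counts))
  expect_lt(abs(mean(sim_counts) - mean(oracle_counts)), 3 * se)
})

test_that("blink-count samples obey the law of large numbers at both extremes", {
  m1 <- mean(simulate_blink_counts(mixture_sim_params(10.8, 60, alpha = 1,
                                                      n_kymographs = 1e5,
                                                      seed = 31)))
  expect_lt(abs(m1 - 10.8), 3 * sqrt(10.8 / 1e5))
  m0 <- mean(simulate_blink_counts(mixture_sim_params(10.8, 60, alpha = 0,
                                                      n_kymographs = 1e5,
                                                      seed = 32)))
  expect_lt(abs(m0 - 1.944), 3 * sqrt(1.944 / 1e5))
  z <- simulate_blink_counts(mixture_sim_params(0, 60, alpha = 0.5,
                                                n_kymographs = 100, seed = 33))
  expect_true(all(z == 0))
})

test_that("degenerate mixtures pass a chi-squared goodness of fit to Poisson", {
  for (alpha in c(0, 1)) {
    counts <- simulate_blink_counts(mixture_sim_params(
      10.8, 60, alpha = alpha, n_kymographs = 1e4, seed = 40 + alpha))
    lam <- if (alpha == 1) 10.8 else dimer_expected(10.8, 60)
    kmax <- max(counts)
    obs <- tabulate(counts + 1L, nbins = kmax + 2L)
    probs <- c(dpois(0:kmax, lam), stats::ppois(kmax, lam, lower.tail = FALSE))
    # pool bins with expected count < 5
    exp_n <- probs * length(counts)
    keep <- exp_n >= 5
    obs_p <- c(obs[keep], sum(obs[!keep]))
    probs_p <- c(probs[keep], sum(probs[!keep]))
    stat <- sum((obs_p - probs_p * length(counts))^2 /
                  (probs_p * length(counts)))
    pval <- stats::pchisq(stat, df = length(obs_p) - 1, lower.tail = FALSE)
    expect_gt(pval, 0.01)
  }
})

test_that("dual-color outcome frequencies converge to the analytic distribution", {
  for (f in c(0.3, 1)) {
    counts <- simulate_dual_color_population(1e5, f, c(0.5, 0.5), seed = 55)
    emp <- c(single_a = counts$n_color_a, single_b = counts$n_color_b,
             dual = counts$n_dual) / counts$n_total
    theo <- expected_color_distribution(f, c(0.5, 0.5))$observed
    expect_lt(sum(abs(emp - theo[names(emp)])) / 2, 0.01)  # total variation
  }
})

test_that("spectra with zero coupling and zero noise sum exactly", {
  for (kind in c("fret_excitation", "cd")) {
    sp <- simulate_spectra(0, kind, seed = 3, noise_sd = 0)
    d <- sim_difference(sp)
    expect_true(all(d$signal == 0))
  }
})

test_that("the coupling deviation is linear in the coupling coefficient", {
  s1 <- sim_difference(simulate_spectra(0.25, "fret_excitation", seed = 7,
                                        noise_sd = 0))
  s2 <- sim_difference(simulate_spectra(0.5, "fret_excitation", seed = 7,
                                        noise_sd = 0))
  expect_equal(s2$signal, 2 * s1$signal, tolerance = 1e-12)
})

test_that("positive coupling yields a positive donor-band enhancement", {
  sp <- simulate_spectra(0.5, "fret_excitation", seed = 12)
  score <- band_enhancement(sim_difference(sp), default_bands()$fret_donor)
  expect_gt(score$z_score, 0)
})
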