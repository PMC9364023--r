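test_that("a noiseless Gaussian profile is recovered to machine precision", {
  x <- 1:41
  prof <- 100 * exp(-(x - 20.0)^2 / (2 * 1.5^2)) + 10
  fr <- fit_frame(prof)
  expect_equal(fr$center_px, 20.0, tolerance = 1e-8)
  expect_equal(fr$amplitude, 100, tolerance = 1e-8)
  expect_equal(fr$sigma_px, 1.5, tolerance = 1e-8)
  expect_equal(fr$offset, 10, tolerance = 1e-8)
  expect_gt(fr$r2, 0.999999)
})

test_that("flat profiles get R^2 = 0 and short profiles are rejected", {
  fr <- fit_frame(rep(7, 20))
  expect_identical(fr$r2, 0)
  expect_identical(fr$amplitude, 0)
  expect_error(fit_frame(c(1, 2, 3)), "length >= 5")
})

test_that("pure-noise profiles fit poorly (R^2 below the OFF threshold)", {
  set.seed(301)
  r2 <- replicate(300, fit_frame(rnorm(32, mean = 10, sd = 3))$r2)
  expect_gte(mean(r2 < 0.7), 0.95)
})

test_that("noise-free simulated frames localize to the ground-truth position", {
  sim <- simulate_kymograph(kymo_sim_params(
    duration_s = 2, blink_rate_per_s = 0, background_sd = 0,
    shot_noise = FALSE, seed = 5))
  track <- fit_kymograph(sim$kymograph)
  expect_equal(track$center_px, sim$ground_truth$true_positions_px,
               tolerance = 1e-6)
})

test_that("localization error at default SNR is well below half a pixel", {
  sim <- simulate_kymograph(kymo_sim_params(duration_s = 60,
                                            blink_rate_per_s = 0, seed = 17))
  track <- fit_kymograph(sim$kymograph)
  err <- track$center_px - sim$ground_truth$true_positions_px
  expect_lt(stats::sd(err), 0.5)
})

test_that("frame classification applies thresholds with hysteresis", {
  expect_equal(classify_frames(rep(0.95, 5)), rep(TRUE, 5))
  expect_equal(classify_frames(c(0.95, 0.5, 0.5, 0.95)),
               c(TRUE, FALSE, FALSE, TRUE))
  # intermediate frame carries the preceding resolved state
  expect_equal(classify_frames(c(0.95, 0.8, 0.5, 0.95)),
               c(TRUE, TRUE, FALSE, TRUE))
  # leading intermediates take the first resolved state
  expect_equal(classify_frames(c(0.8, 0.5, 0.95)), c(FALSE, FALSE, TRUE))
  # no resolved frame at all: everything OFF
  expect_equal(classify_frames(rep(0.8, 4)), rep(FALSE, 4))
  expect_error(classify_frames(0.5, r2_off = 0.9, r2_on = 0.7), "thresholds")
})

test_that("lowering the OFF threshold never increases the number of OFF frames", {
  set.seed(77)
  for (i in 1:50) {
    r2 <- runif(40)
    off_strict <- sum(!classify_frames(r2, r2_off = 0.5, r2_on = 0.9))
    off_loose <- sum(!classify_frames(r2, r2_off = 0.7, r2_on = 0.9))
    expect_lte(off_strict, off_loose)
  }
})

test_that("blinks are interior OFF runs only", {
  expect_equal(count_blinks(rep(TRUE, 10))$n_blinks, 0)
  s <- count_blinks(c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(s$n_blinks, 2)
  expect_equal(s$events$n_frames, c(1, 1))
  # a leading OFF run is censored, not a blink
  expect_equal(count_blinks(c(FALSE, FALSE, TRUE, FALSE, TRUE))$n_blinks, 1)
  expect_equal(count_blinks(c(TRUE, FALSE, TRUE, FALSE, FALSE))$n_blinks, 1)
})

test_that("blink counting is invariant to padding with ON frames", {
  set.seed(99)
  for (i in 1:50) {
    v <- runif(30) > 0.3
    base <- count_blinks(v)$n_blinks
    padded <- count_blinks(c(TRUE, TRUE, v, TRUE))$n_blinks
    expect_gte(padded, base)  # padding can only uncensor boundary runs
    # padding an already ON-flanked vector changes nothing
    v2 <- c(TRUE, v, TRUE)
    expect_equal(count_blinks(c(TRUE, v2, TRUE))$n_blinks,
                 count_blinks(v2)$n_blinks)
  }
})

test_that("MSD of a stationary noiseless spot is zero; short tracks are flagged", {
  sim <- simulate_kymograph(kymo_sim_params(
    duration_s = 5, diffusion_coeff_px2_per_frame = 0, blink_rate_per_s = 0,
    background_sd = 0, shot_noise = FALSE, seed = 2))
  track <- fit_kymograph(sim$kymograph)
  m <- track_msd(track, rep(TRUE, nrow(track)))
  expect_true(all(abs(m$msd_nm2) < 1e-10))
  short <- track_msd(track[1:8, ], rep(c(TRUE, FALSE), 4))
  expect_equal(nrow(short), 0)
  expect_true(isTRUE(attr(short, "insufficient")))
})

test_that("MSD slope recovers the simulated diffusion coefficient", {
  D <- 0.05  # px^2/frame
  slopes <- vapply(1:40, function(s) {
    sim <- simulate_kymograph(kymo_sim_params(
      duration_s = 30, n_pixels = 64, diffusion_coeff_px2_per_frame = D,
      blink_rate_per_s = 0, background_sd = 0, shot_noise = FALSE, seed = s))
    track <- fit_kymograph(sim$kymograph)
    m <- track_msd(track, rep(TRUE, nrow(track)))
    m <- m[m$lag_frames <= 10, ]
    unname(stats::coef(stats::lm(msd_nm2 ~ 0 + lag_frames, data = m))[1])
  }, numeric(1))
  expected <- 2 * D * 63.2^2  # MSD = 2 D t, in nm^2 per frame
  expect_equal(mean(slopes), expected, tolerance = 0.2)
})

test_that("analyze_kymograph reproduces ground-truth blink counts", {
  sim <- simulate_kymograph(kymo_sim_params(seed = 41))
  ana <- analyze_kymograph(sim$kymograph)
  expect_equal(ana$blinks$n_blinks, sim$ground_truth$true_blink_count)
})
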