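fret_grid <- seq(450, 650, 10)

test_that("spectrum construction validates its grid", {
  expect_error(spectrum(c(450, 450, 460), 1:3, "cd"), "strictly increasing")
  expect_error(spectrum(c(450, 460), c(1, NA), "cd"), "finite")
  s <- spectrum(fret_grid, rep(1, 21), "fret_excitation", "flat")
  expect_s3_class(s, "spectrum")
})

test_that("summation is pointwise, permutation-invariant, and cancels negations", {
  set.seed(5)
  a <- spectrum(fret_grid, rnorm(21), "fret_excitation", "a")
  b <- spectrum(fret_grid, rnorm(21), "fret_excitation", "b")
  c_ <- spectrum(fret_grid, rnorm(21), "fret_excitation", "c")
  expect_equal(sum_spectra(list(a, b, c_))$signal,
               sum_spectra(list(c_, a, b))$signal)
  neg <- spectrum(fret_grid, -a$signal, "fret_excitation", "-a")
  expect_true(all(sum_spectra(list(a, neg))$signal == 0))
  sp <- simulate_spectra(0, "fret_excitation", seed = 2, noise_sd = 0)
  expect_equal(sum_spectra(sp[1:2])$signal, sp$mixture$signal)
})

test_that("grid or kind mismatches are rejected, never silently interpolated", {
  a <- spectrum(fret_grid, rep(1, 21), "fret_excitation")
  b <- spectrum(fret_grid + 5, rep(1, 21), "fret_excitation")
  expect_error(sum_spectra(list(a, b)), "regrid_spectrum")
  expect_error(difference_spectrum(a, b), "regrid_spectrum")
  cdspec <- spectrum(fret_grid, rep(1, 21), "cd")
  expect_error(a + cdspec, "kinds differ")
})

test_that("difference spectra are antisymmetric and exactly linear", {
  set.seed(9)
  a <- spectrum(fret_grid, rnorm(21), "fret_excitation", "a")
  b <- spectrum(fret_grid, rnorm(21), "fret_excitation", "b")
  delta <- rnorm(21)
  mix <- spectrum(fret_grid, a$signal + b$signal + delta, "fret_excitation")
  d <- difference_spectrum(sum_spectra(list(a, b)), mix)
  expect_equal(d$signal, delta, tolerance = 1e-12)
  expect_equal(difference_spectrum(a, b)$signal,
               -difference_spectrum(b, a)$signal)
  self <- difference_spectrum(a, a)
  expect_true(all(self$signal == 0))
})

test_that("a zero difference spectrum scores zero", {
  z <- spectrum(fret_grid, rep(0, 21), "fret_excitation")
  score <- band_enhancement(z, c(480, 520))
  expect_identical(score$integrated_difference, 0)
  expect_identical(score$z_score, 0)
})

test_that("simulated FRET coupling produces a strong in-band score", {
  sp <- simulate_spectra(0.5, "fret_excitation", seed = 21)
  score <- band_enhancement(sim_difference(sp), default_bands()$fret_donor)
  expect_gt(score$z_score, 3)
  expect_true(score$peak_wavelength_nm >= 480 && score$peak_wavelength_nm <= 520)
})

test_that("the band score is scale-equivariant in the integral, invariant in z", {
  sp <- simulate_spectra(0.5, "fret_excitation", seed = 22)
  d <- sim_difference(sp)
  d10 <- spectrum(d$wavelength_nm, 10 * d$signal, d$kind)
  s1 <- band_enhancement(d, c(480, 520))
  s10 <- band_enhancement(d10, c(480, 520))
  expect_equal(s10$integrated_difference, 10 * s1$integrated_difference)
  expect_equal(s10$z_score, s1$z_score, tolerance = 1e-12)
})

test_that("bands outside the grid are rejected", {
  d <- spectrum(fret_grid, rep(0, 21), "fret_excitation")
  expect_error(band_enhancement(d, c(400, 520)), "outside")
  expect_error(band_enhancement(d, c(520, 480)), "increasing")
})

test_that("null coupling rarely clears the detection threshold", {
  z <- vapply(1:300, function(s) {
    sp <- simulate_spectra(0, "fret_excitation", seed = s)
    band_enhancement(sim_difference(sp), default_bands()$fret_donor)$z_score
  }, numeric(1))
  expect_gte(mean(abs(z) < 2), 0.95)
})

test_that("non-consensus DNA suppresses the 281 nm CD band score", {
  z <- vapply(1:200, function(s) {
    sp <- simulate_spectra(0.5, "cd", seed = 700 + s, consensus = FALSE)
    band_enhancement(sim_difference(sp), default_bands()$cd_dna)$z_score
  }, numeric(1))
  expect_gte(mean(abs(z) < 2), 0.95)
  # the same coupling with the consensus site present is clearly detected
  sp <- simulate_spectra(0.5, "cd", seed = 701, consensus = TRUE)
  expect_gt(band_enhancement(sim_difference(sp), default_bands()$cd_dna)$z_score, 3)
})

test_that("regridding interpolates linearly and logs its use", {
  s <- spectrum(c(450, 460, 470), c(0, 10, 20), "fret_excitation", "lin")
  expect_message(r <- regrid_spectrum(s, c(455, 465)), "regridding")
  expect_equal(r$signal, c(5, 15))
  expect_error(suppressMessages(regrid_spectrum(s, c(440, 460))), "within")
})

test_that("replicate averaging reports the pointwise mean and SE", {
  set.seed(31)
  reps <- lapply(1:3, function(i) {
    spectrum(fret_grid, rnorm(21, mean = 10), "fret_excitation",
             sprintf("rep%d", i))
  })
  avg <- average_spectra(reps)
  m <- sapply(reps, `[[`, "signal")
  expect_equal(avg$signal, rowMeans(m))
  expect_equal(avg$se, apply(m, 1, sd) / sqrt(3))
})
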