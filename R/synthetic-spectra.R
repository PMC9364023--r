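# Gaussian band helper on a wavelength grid
gauss_band <- function(wl, center, sigma) exp(-(wl - center)^2 / (2 * sigma^2))

#' Simulate component and mixture spectra
#'
#' Generates the three spectra the difference-spectrum analysis consumes: two
#' components measured alone and their mixture.  With `coupling = 0` the
#' mixture is exactly the sum of the components (plus noise); `coupling > 0`
#' adds a band-localized deviation whose magnitude is linear in `coupling`:
#'
#' * `"fret_excitation"`: excitation scans 450–650 nm in 10 nm steps at fixed
#'   700 nm emission.  Component A is a donor (mNeonGreen-like, excitation
#'   band near 506 nm) whose direct contribution at 700 nm is small;
#'   component B is the acceptor (mCherry-like, band near 587 nm).  Coupling
#'   adds energy-transfer signal in the donor band — the acceptor emits when
#'   the donor is excited.
#' * `"cd"`: circular dichroism scans 190–320 nm in 1 nm steps, in
#'   millidegrees.  Component A is a helical protein (negative 208/222 nm
#'   bands), component B a DNA duplex with a positive band at 281 nm.
#'   Coupling increases the 281 nm band amplitude, emulating a
#'   binding-induced DNA structural change; with `consensus = FALSE` (a
#'   duplex lacking the recognition site) the coupling term is suppressed
#'   and the mixture is the plain sum.
#'
#' @param coupling Interaction strength in `[0, 1]`.
#' @param kind `"fret_excitation"` or `"cd"`.
#' @param seed Integer seed for the noise draws.
#' @param noise_sd Per-wavelength Gaussian noise SD applied independently to
#'   each of the three spectra.  Defaults: 1 count (FRET), 0.05 mdeg (CD).
#'   Set 0 for noiseless output.
#' @param consensus For `kind = "cd"`: does the DNA carry the consensus
#'   binding site?  Ignored for FRET.
#' @return Named list of three [spectrum()] objects: `component_a`,
#'   `component_b`, `mixture`.
#' @examples
#' sp <- simulate_spectra(0.5, "fret_excitation", seed = 1)
#' d <- difference_spectrum(sum_spectra(sp[1:2]), sp$mixture)
#' band_enhancement(d, default_bands()$fret_donor)
#' @export
simulate_spectra <- function(coupling, kind = c("fret_excitation", "cd"),
                             seed = 1L, noise_sd = NULL, consensus = TRUE) {
  kind <- match.arg(kind)
  check_probability(coupling, "coupling")
  if (is.null(noise_sd)) noise_sd <- if (kind == "cd") 0.05 else 1
  check_scalar_pos(noise_sd, "noise_sd", strict = FALSE)

  if (kind == "fret_excitation") {
    wl <- seq(450, 650, by = 10)
    a0 <- 5 * gauss_band(wl, 506, 18)                   # donor bleed-through
    b0 <- 100 * gauss_band(wl, 587, 22)                 # direct acceptor
    dev <- coupling * 60 * gauss_band(wl, 506, 18)      # transfer term
    labels <- c("donor_fusion", "acceptor_fusion", "mixture")
  } else {
    wl <- seq(190, 320, by = 1)
    a0 <- -8 * gauss_band(wl, 208, 6) - 6 * gauss_band(wl, 222, 6)
    b0 <- 4 * gauss_band(wl, 281, 9) - 5 * gauss_band(wl, 245, 8) +
      2.5 * gauss_band(wl, 219, 6)
    dev <- if (isTRUE(consensus)) coupling * 2 * gauss_band(wl, 281, 6) else 0 * wl
    labels <- c("protein", "dna", "mixture")
  }

  with_seed(seed, {
    noise <- function() if (noise_sd > 0) stats::rnorm(length(wl), 0, noise_sd) else 0
    list(
      component_a = spectrum(wl, a0 + noise(), kind, labels[1]),
      component_b = spectrum(wl, b0 + noise(), kind, labels[2]),
      mixture = spectrum(wl, a0 + b0 + dev + noise(), kind, labels[3])
    )
  })
}
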