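#' Kymograph simulation parameters
#'
#' Acquisition and emitter parameters for [simulate_kymograph()].  Defaults
#' emulate the study conditions: 60 s records at 10 frames/s with 63.2 nm
#' pixels, a single diffusing quantum-dot-labeled protein on a DNA tightrope,
#' and signal/noise levels at which single-frame Gaussian fits give R^2 > 0.9
#' for a visible emitter and R^2 < 0.7 for background.
#'
#' @param duration_s Record length, seconds.
#' @param frame_rate_hz Frames per second.  `duration_s * frame_rate_hz` must
#'   be a positive integer.
#' @param pixel_nm Nanometers per pixel along the tightrope.
#' @param n_pixels Number of pixels along the tightrope axis.
#' @param psf_sigma_px Gaussian point-spread-function width, pixels.
#' @param photons_per_frame Mean peak signal amplitude per ON emitter
#'   (counts; Poisson shot noise applies when `shot_noise = TRUE`).
#' @param background_mean,background_sd Additive camera background: constant
#'   offset plus Gaussian read noise.
#' @param diffusion_coeff_px2_per_frame 1D diffusion coefficient D of the
#'   spot, px^2/frame; displacement per frame has variance `2 * D`.
#' @param n_emitters 1 (monomer) or 2 (dimer).  A dimer's emitters share one
#'   diffusing center — a dimer is one diffraction-limited spot.
#' @param blink_rate_per_s Per-emitter rate of entering the dark state while
#'   emitting (Poisson process in time).
#' @param mean_dark_frames Mean dwell of a dark interval, frames (geometric;
#'   must be >= 1).
#' @param shot_noise Apply Poisson shot noise to the signal?  Disable
#'   together with `background_sd = 0` for noiseless ground-truth frames.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A validated `kymo_sim_params` list.
#' @export
kymo_sim_params <- function(duration_s = 60, frame_rate_hz = 10,
                            pixel_nm = 63.2, n_pixels = 32,
                            psf_sigma_px = 1.5, photons_per_frame = 200,
                            background_mean = 10, background_sd = 3,
                            diffusion_coeff_px2_per_frame = 0.21,
                            n_emitters = 1, blink_rate_per_s = 0.18,
                            mean_dark_frames = 3, shot_noise = TRUE,
                            seed = 1L) {
  check_scalar_pos(duration_s, "duration_s")
  check_scalar_pos(frame_rate_hz, "frame_rate_hz")
  n_frames <- duration_s * frame_rate_hz
  if (abs(n_frames - round(n_frames)) > 1e-9 || n_frames < 1) {
    stop("duration_s * frame_rate_hz must be a positive integer number of frames",
         call. = FALSE)
  }
  check_scalar_pos(pixel_nm, "pixel_nm")
  if (!is.numeric(n_pixels) || length(n_pixels) != 1L || n_pixels < 5 ||
      n_pixels != floor(n_pixels)) {
    stop("`n_pixels` must be an integer >= 5", call. = FALSE)
  }
  check_scalar_pos(psf_sigma_px, "psf_sigma_px")
  check_scalar_pos(photons_per_frame, "photons_per_frame", strict = FALSE)
  check_scalar_pos(background_mean, "background_mean", strict = FALSE)
  check_scalar_pos(background_sd, "background_sd", strict = FALSE)
  check_scalar_pos(diffusion_coeff_px2_per_frame, "diffusion_coeff_px2_per_frame",
                   strict = FALSE)
  if (!n_emitters %in% c(1, 2)) {
    stop("`n_emitters` must be 1 (monomer) or 2 (dimer)", call. = FALSE)
  }
  check_scalar_pos(blink_rate_per_s, "blink_rate_per_s", strict = FALSE)
  if (!is.numeric(mean_dark_frames) || length(mean_dark_frames) != 1L ||
      mean_dark_frames < 1) {
    stop("`mean_dark_frames` must be >= 1", call. = FALSE)
  }
  structure(
    list(duration_s = duration_s, frame_rate_hz = frame_rate_hz,
         pixel_nm = pixel_nm, n_pixels = as.integer(n_pixels),
         psf_sigma_px = psf_sigma_px, photons_per_frame = photons_per_frame,
         background_mean = background_mean, background_sd = background_sd,
         diffusion_coeff_px2_per_frame = diffusion_coeff_px2_per_frame,
         n_emitters = as.integer(n_emitters),
         blink_rate_per_s = blink_rate_per_s,
         mean_dark_frames = mean_dark_frames,
         shot_noise = isTRUE(shot_noise), seed = as.integer(seed),
         n_frames = as.integer(round(n_frames))),
    class = "kymo_sim_params"
  )
}

# reflect a free 1D coordinate into [1, n] (reflective boundaries)
reflect_position <- function(x, n) {
  if (n == 1) return(rep(1, length(x)))
  period <- 2 * (n - 1)
  r <- (x - 1) %% period
  1 + ifelse(r <= n - 1, r, period - r)
}

# two-state emitter chain: TRUE = emitting.  Starts ON.
simulate_onoff <- function(n_frames, p_blink, p_recover) {
  on <- logical(n_frames)
  state <- TRUE
  u <- stats::runif(n_frames)
  for (t in seq_len(n_frames)) {
    on[t] <- state
    state <- if (state) u[t] >= p_blink else u[t] < p_recover
  }
  on
}

# interior maximal runs where `dark` is TRUE (runs touching either end are
# censored and not counted) -- shared by simulator ground truth and analysis
interior_dark_runs <- function(dark) {
  r <- rle(dark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & starts > 1L & ends < length(dark)
  data.frame(start_frame = starts[keep], n_frames = r$lengths[keep])
}

#' Simulate a kymograph with ground truth
#'
#' Generates a position-by-time intensity matrix for 1 or 2 stochastically
#' blinking point emitters diffusing along a DNA tightrope, plus the ground
#' truth needed to score downstream analysis.  The spot follows a reflected
#' 1D random walk; each emitter independently enters dark states as a
#' Poisson process in time with geometric dark dwells; per-frame signal is a
#' Gaussian profile summed over ON emitters with Poisson shot noise, on top
#' of a constant background with Gaussian read noise.
#'
#' The ground-truth blink count is the number of maximal runs of frames in
#' which *all* emitters are simultaneously dark, excluding runs touching the
#' first or last frame (their true extent is censored) — the same boundary
#' rule [count_blinks()] applies.
#'
#' @param params A [kymo_sim_params()] object.
#' @return List with `kymograph` (class `kymograph`: `intensity` matrix
#'   `n_pixels x n_frames`, `pixel_nm`, `frame_interval_s`, `id`) and
#'   `ground_truth` (class `kymo_ground_truth`: `true_positions_px`,
#'   `emitter_on` matrix `n_emitters x n_frames`, `true_blink_count`,
#'   `blink_events`).
#' @examples
#' sim <- simulate_kymograph(kymo_sim_params(duration_s = 10, seed = 7))
#' dim(sim$kymograph$intensity)
#' sim$ground_truth$true_blink_count
#' @export
simulate_kymograph <- function(params) {
  if (!inherits(params, "kymo_sim_params")) {
    stop("`params` must come from kymo_sim_params()", call. = FALSE)
  }
  p <- params
  with_seed(p$seed, {
    n_frames <- p$n_frames
    # shared diffusing center (dimer emitters are co-moving: one spot)
    steps <- stats::rnorm(n_frames - 1L, 0,
                          sqrt(2 * p$diffusion_coeff_px2_per_frame))
    free <- cumsum(c((p$n_pixels + 1) / 2, steps))
    pos <- reflect_position(free, p$n_pixels)

    p_blink <- 1 - exp(-p$blink_rate_per_s / p$frame_rate_hz)
    p_recover <- 1 / p$mean_dark_frames
    on <- matrix(TRUE, nrow = p$n_emitters, ncol = n_frames)
    for (e in seq_len(p$n_emitters)) {
      on[e, ] <- simulate_onoff(n_frames, p_blink, p_recover)
    }

    px <- seq_len(p$n_pixels)
    img <- matrix(0, nrow = p$n_pixels, ncol = n_frames)
    for (t in seq_len(n_frames)) {
      lam <- numeric(p$n_pixels)
      n_on <- sum(on[, t])
      if (n_on > 0 && p$photons_per_frame > 0) {
        lam <- n_on * p$photons_per_frame *
          exp(-(px - pos[t])^2 / (2 * p$psf_sigma_px^2))
      }
      signal <- if (p$shot_noise) stats::rpois(p$n_pixels, lam) else lam
      read <- if (p$background_sd > 0) {
        stats::rnorm(p$n_pixels, 0, p$background_sd)
      } else 0
      img[, t] <- p$background_mean + signal + read
    }

    all_dark <- colSums(on) == 0
    events <- interior_dark_runs(all_dark)

    list(
      kymograph = structure(
        list(intensity = img, pixel_nm = p$pixel_nm,
             frame_interval_s = 1 / p$frame_rate_hz,
             id = sprintf("sim-seed%d", p$seed)),
        class = "kymograph"),
      ground_truth = structure(
        list(true_positions_px = pos, emitter_on = on,
             true_blink_count = nrow(events), blink_events = events),
        class = "kymo_ground_truth")
    )
  })
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph '%s': %d px x %d frames (%.1f nm/px, %.3g s/frame)\n",
              x$id, nrow(x$intensity), ncol(x$intensity), x$pixel_nm,
              x$frame_interval_s))
  invisible(x)
}
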