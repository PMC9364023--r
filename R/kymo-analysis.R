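#' Fit one kymograph frame with a 1D Gaussian
#'
#' Least-squares fit of `amplitude * exp(-(x - center)^2 / (2 * sigma^2)) +
#' offset` to a single intensity profile (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]).  Initialization: center at the argmax pixel,
#' offset at the profile median, amplitude at `max - median`, sigma at 1.5
#' px; a single restart from the intensity centroid is tried if the first
#' attempt fails.  Pixel coordinates are 1-based; the fitted center is
#' continuous (subpixel) in pixel units.
#'
#' R-squared is computed against the profile's variance about its mean.  A
#' zero-variance (all-equal) profile gets `r2 = 0` (no spot present); a fit
#' that fails from both starts returns `r2 = -Inf`, never an error.
#'
#' @param profile Numeric intensity vector, length >= 5.
#' @return One-row data.frame: `center_px`, `sigma_px`, `amplitude`,
#'   `offset`, `r2`.
#' @examples
#' x <- 1:31
#' fit_frame(100 * exp(-(x - 17.3)^2 / (2 * 1.5^2)) + 10)
#' @export
fit_frame <- function(profile) {
  if (!is.numeric(profile) || length(profile) < 5 || any(!is.finite(profile))) {
    stop("`profile` must be a finite numeric vector of length >= 5",
         call. = FALSE)
  }
  n <- length(profile)
  x <- seq_len(n)
  sst <- sum((profile - mean(profile))^2)
  if (sst == 0) {
    return(data.frame(center_px = NA_real_, sigma_px = NA_real_,
                      amplitude = 0, offset = profile[1], r2 = 0))
  }
  resid_fun <- function(p) {
    p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4] - profile
  }
  run <- function(start) {
    tryCatch({
      # maxiter exhaustion on pure-noise frames is routine, not an error
      fit <- suppressWarnings(minpack.lm::nls.lm(
        par = start, fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-14,
                                             ptol = 1e-14)
      ))
      p <- fit$par
      if (any(!is.finite(p)) || p[3] == 0) return(NULL)
      list(par = p, rss = sum(fit$fvec^2))
    }, error = function(e) NULL)
  }
  med <- stats::median(profile)
  amp0 <- max(profile) - med
  if (amp0 <= 0) amp0 <- max(stats::sd(profile), 1e-6)
  fit <- run(c(amp0, which.max(profile), 1.5, med))
  if (is.null(fit)) {
    wts <- pmax(profile - min(profile), 0)
    c0 <- if (sum(wts) > 0) sum(x * wts) / sum(wts) else (n + 1) / 2
    fit <- run(c(amp0, c0, 1.5, med))
  }
  if (is.null(fit)) {
    return(data.frame(center_px = NA_real_, sigma_px = NA_real_,
                      amplitude = NA_real_, offset = NA_real_, r2 = -Inf))
  }
  data.frame(center_px = fit$par[2], sigma_px = abs(fit$par[3]),
             amplitude = fit$par[1], offset = fit$par[4],
             r2 = 1 - fit$rss / sst)
}

#' Fit every frame of a kymograph
#'
#' @param kymo A `kymograph` (see [simulate_kymograph()] or
#'   [read_kymograph()]).
#' @return A `track_fit` data.frame (one row per frame: `frame`, `center_px`,
#'   `sigma_px`, `amplitude`, `offset`, `r2`) carrying `pixel_nm` and
#'   `frame_interval_s` attributes.
#' @export
fit_kymograph <- function(kymo) {
  if (!inherits(kymo, "kymograph")) {
    stop("`kymo` must be a kymograph", call. = FALSE)
  }
  n_frames <- ncol(kymo$intensity)
  out <- matrix(NA_real_, nrow = n_frames, ncol = 5)
  for (t in seq_len(n_frames)) {
    out[t, ] <- as.numeric(fit_frame(kymo$intensity[, t]))
  }
  df <- data.frame(frame = seq_len(n_frames), center_px = out[, 1],
                   sigma_px = out[, 2], amplitude = out[, 3],
                   offset = out[, 4], r2 = out[, 5])
  attr(df, "pixel_nm") <- kymo$pixel_nm
  attr(df, "frame_interval_s") <- kymo$frame_interval_s
  attr(df, "id") <- kymo$id
  class(df) <- c("track_fit", "data.frame")
  df
}

#' Classify frames as emitter ON or OFF by goodness of fit
#'
#' Frames with `r2 < r2_off` are OFF (the fitter latched onto background);
#' frames with `r2 >= r2_on` are ON.  Frames in the intermediate band
#' inherit the state of the nearest preceding resolved frame (hysteresis);
#' leading intermediate frames take the first resolved state, and a track
#' with no resolved frame at all is entirely OFF.
#'
#' @param track A `track_fit` (or anything with an `r2` column / numeric
#'   vector of R-squared values).
#' @param r2_off OFF threshold (default 0.7).
#' @param r2_on ON threshold (default 0.9); must satisfy
#'   `0 < r2_off <= r2_on < 1`.
#' @return Logical vector, `TRUE` = ON.
#' @export
classify_frames <- function(track, r2_off = 0.7, r2_on = 0.9) {
  if (!(r2_off > 0 && r2_off <= r2_on && r2_on < 1)) {
    stop("thresholds must satisfy 0 < r2_off <= r2_on < 1", call. = FALSE)
  }
  r2 <- if (is.numeric(track)) track else track$r2
  if (is.null(r2) || length(r2) == 0) stop("no r2 values", call. = FALSE)
  state <- rep(NA, length(r2))
  state[r2 >= r2_on] <- TRUE
  state[r2 < r2_off] <- FALSE
  if (all(is.na(state))) return(rep(FALSE, length(r2)))
  # carry the previous resolved state forward; backfill the leading gap
  first_resolved <- which(!is.na(state))[1]
  if (first_resolved > 1) state[seq_len(first_resolved - 1)] <- state[first_resolved]
  for (t in seq_along(state)[-1]) {
    if (is.na(state[t])) state[t] <- state[t - 1]
  }
  state
}

#' Count blink events in an ON/OFF state vector
#'
#' A blink is a maximal run of OFF frames strictly inside the observation;
#' OFF runs touching the first or last frame are excluded because their true
#' extent is censored.  No merging of blinks separated by single ON frames.
#'
#' @param on_state Logical vector, `TRUE` = ON.
#' @param frame_interval_s Optional frame interval; stored so that downstream
#'   histograms know the record duration.
#' @return A `blink_series`: `events` (data.frame `start_frame`, `n_frames`),
#'   `n_blinks`, `on_state`, `n_frames_total`, and `duration_s` when the
#'   interval is known.
#' @examples
#' count_blinks(c(TRUE, FALSE, TRUE, FALSE, TRUE))$n_blinks  # 2
#' @export
count_blinks <- function(on_state, frame_interval_s = NULL) {
  if (!is.logical(on_state) || length(on_state) == 0 || any(is.na(on_state))) {
    stop("`on_state` must be a non-empty logical vector", call. = FALSE)
  }
  events <- interior_dark_runs(!on_state)
  structure(
    list(events = events, n_blinks = nrow(events), on_state = on_state,
         n_frames_total = length(on_state),
         duration_s = if (is.null(frame_interval_s)) NULL
                      else length(on_state) * frame_interval_s),
    class = "blink_series"
  )
}

#' @export
print.blink_series <- function(x, ...) {
  cat(sprintf("Blink series: %d blinks in %d frames%s\n", x$n_blinks,
              x$n_frames_total,
              if (is.null(x$duration_s)) ""
              else sprintf(" (%.4g s)", x$duration_s)))
  invisible(x)
}

#' Analyze one kymograph end to end
#'
#' Convenience wrapper: per-frame Gaussian fits, ON/OFF classification, blink
#' counting.
#'
#' @inheritParams classify_frames
#' @param kymo A `kymograph`.
#' @return List with `track` (`track_fit`), `on_state`, and `blinks`
#'   (`blink_series`).
#' @export
analyze_kymograph <- function(kymo, r2_off = 0.7, r2_on = 0.9) {
  track <- fit_kymograph(kymo)
  on_state <- classify_frames(track, r2_off, r2_on)
  blinks <- count_blinks(on_state, frame_interval_s = kymo$frame_interval_s)
  list(track = track, on_state = on_state, blinks = blinks)
}

#' Mean-squared displacement of a tracked spot
#'
#' MSD over the fitted subpixel positions of ON frames, at lags 1 to
#' `n_frames / 4`, in nm^2.  Position pairs spanning OFF frames are simply
#' omitted (both endpoints must be ON).
#'
#' @param track A `track_fit`.
#' @param on_state Logical ON/OFF vector (default: [classify_frames()] on the
#'   track).
#' @return Data.frame `lag_frames`, `lag_s` (when the frame interval is
#'   known), `msd_nm2`, `n_pairs`.  With fewer than 10 ON frames an empty
#'   data.frame is returned, flagged with `attr(, "insufficient") = TRUE`.
#' @export
track_msd <- function(track, on_state = NULL) {
  if (!inherits(track, "track_fit")) {
    stop("`track` must be a track_fit", call. = FALSE)
  }
  if (is.null(on_state)) on_state <- classify_frames(track)
  pixel_nm <- attr(track, "pixel_nm") %||% 1
  dt <- attr(track, "frame_interval_s")
  pos <- ifelse(on_state, track$center_px, NA_real_)
  empty <- data.frame(lag_frames = integer(0), lag_s = numeric(0),
                      msd_nm2 = numeric(0), n_pairs = integer(0))
  if (sum(on_state) < 10) {
    attr(empty, "insufficient") <- TRUE
    return(empty)
  }
  n <- length(pos)
  lags <- seq_len(max(1L, floor(n / 4)))
  msd <- n_pairs <- numeric(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    d2 <- (pos[(1 + k):n] - pos[1:(n - k)])^2
    n_pairs[i] <- sum(!is.na(d2))
    msd[i] <- mean(d2, na.rm = TRUE) * pixel_nm^2
  }
  data.frame(lag_frames = lags,
             lag_s = if (is.null(dt)) NA_real_ else lags * dt,
             msd_nm2 = msd, n_pairs = as.integer(n_pairs))
}
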