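# File IO: TIFF kymographs with JSON sidecars, CSV tables, JSON reports.

#' Write a kymograph as TIFF plus JSON sidecar
#'
#' The intensity matrix (position rows x time columns) is stored as a
#' single-page 32-bit grayscale TIFF, linearly rescaled to `[0, 1]`; the
#' sidecar records the rescaling (`intensity_min`, `intensity_max`), the
#' pixel/frame calibration, and — when supplied — the simulation ground
#' truth, so the round trip is lossless up to float precision.
#'
#' @param kymo A `kymograph`.
#' @param path Path of the `.tif` file; the sidecar takes the same path with
#'   `.json`.
#' @param ground_truth Optional `kymo_ground_truth` to embed in the sidecar.
#' @return Invisibly, the sidecar path.
#' @export
write_kymograph <- function(kymo, path, ground_truth = NULL) {
  if (!inherits(kymo, "kymograph")) stop("`kymo` must be a kymograph", call. = FALSE)
  rng <- range(kymo$intensity)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((kymo$intensity - rng[1]) / scale, path,
                  bits.per.sample = 32L)
  sidecar <- list(
    id = kymo$id, pixel_nm = kymo$pixel_nm,
    frame_interval_s = kymo$frame_interval_s,
    n_pixels = nrow(kymo$intensity), n_frames = ncol(kymo$intensity),
    intensity_min = rng[1], intensity_max = rng[2]
  )
  if (!is.null(ground_truth)) {
    sidecar$ground_truth <- list(
      true_positions_px = ground_truth$true_positions_px,
      emitter_on = unname(split(ground_truth$emitter_on,
                                row(ground_truth$emitter_on))),
      true_blink_count = ground_truth$true_blink_count
    )
  }
  json_path <- sub("\\.tiff?$", ".json", path)
  if (json_path == path) json_path <- paste0(path, ".json")
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}

#' Read a kymograph written by [write_kymograph()]
#'
#' @param path Path of the `.tif` file (sidecar looked up next to it).
#' @return List with `kymograph` and, when present in the sidecar,
#'   `ground_truth`.
#' @export
read_kymograph <- function(path) {
  json_path <- sub("\\.tiff?$", ".json", path)
  if (json_path == path) json_path <- paste0(path, ".json")
  if (!file.exists(json_path)) {
    stop("calibration sidecar not found: ", json_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  img <- img * (meta$intensity_max - meta$intensity_min) + meta$intensity_min
  out <- list(kymograph = structure(
    list(intensity = img, pixel_nm = meta$pixel_nm,
         frame_interval_s = meta$frame_interval_s, id = meta$id),
    class = "kymograph"))
  if (!is.null(meta$ground_truth)) {
    gt <- meta$ground_truth
    on <- do.call(rbind, lapply(gt$emitter_on, as.logical))
    out$ground_truth <- structure(
      list(true_positions_px = gt$true_positions_px, emitter_on = on,
           true_blink_count = gt$true_blink_count,
           blink_events = interior_dark_runs(colSums(on) == 0)),
      class = "kymo_ground_truth")
  }
  out
}

#' Write / read per-kymograph blink counts as CSV
#'
#' Columns `kymograph_id`, `blink_count`.
#'
#' @param counts Integer vector of blink counts.
#' @param path CSV path.
#' @param ids Optional kymograph identifiers (default `kymo_001`, ...).
#' @return Invisibly, `path` (write); integer count vector named by id (read).
#' @export
write_blink_counts <- function(counts, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("kymo_%03d", seq_along(counts))
  utils::write.csv(data.frame(kymograph_id = ids, blink_count = counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blink_counts
#' @export
read_blink_counts <- function(path) {
  df <- utils::read.csv(path)
  stats::setNames(as.integer(df$blink_count), df$kymograph_id)
}

#' Write / read dual-color category counts as CSV
#'
#' Columns `category` (`dual`, `color_a`, `color_b`), `count`.
#'
#' @param counts A [dual_color_counts()] object.
#' @param path CSV path.
#' @return Invisibly, `path` (write); a `dual_color_counts` (read).
#' @export
write_dual_color_counts <- function(counts, path) {
  utils::write.csv(
    data.frame(category = c("dual", "color_a", "color_b"),
               count = c(counts$n_dual, counts$n_color_a, counts$n_color_b)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dual_color_counts
#' @export
read_dual_color_counts <- function(path) {
  df <- utils::read.csv(path)
  get1 <- function(cat) {
    v <- df$count[df$category == cat]
    if (length(v) != 1) stop("missing category: ", cat, call. = FALSE)
    v
  }
  dual_color_counts(get1("dual"), get1("color_a"), get1("color_b"))
}

#' Write / read a spectrum as CSV
#'
#' Columns `wavelength_nm`, `signal`, and `se` when present.
#'
#' @param s A [spectrum()].
#' @param path CSV path.
#' @param kind,label Metadata to attach on read (CSV stores only the trace).
#' @return Invisibly, `path` (write); a `spectrum` (read).
#' @export
write_spectrum <- function(s, path) {
  df <- data.frame(wavelength_nm = s$wavelength_nm, signal = s$signal)
  if (!is.null(s$se)) df$se <- s$se
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, kind = c("fret_excitation", "cd"),
                          label = basename(path)) {
  df <- utils::read.csv(path)
  spectrum(df$wavelength_nm, df$signal, match.arg(kind), label,
           se = df$se)
}

#' Write a model-fit report as JSON
#'
#' Serializes a [fit_dual_poisson()] result (sans the bulky fitted table,
#' which goes to its own CSV) for archiving alongside run outputs.
#'
#' @param fit A `dual_poisson_fit`.
#' @param path JSON path.
#' @param fitted_csv Optional path for the observed-vs-fitted CSV.
#' @return Invisibly, `path`.
#' @export
write_fit_report <- function(fit, path, fitted_csv = NULL) {
  report <- list(
    bl_mon = fit$bl_mon, bl_dim = fit$bl_dim, duration_s = fit$duration_s,
    alpha = as.list(fit$alpha), dimer_percent = as.list(fit$dimer_percent),
    se_dimer_percent = as.list(fit$se_dimer_percent),
    r_squared = fit$r_squared, sse = fit$sse, converged = fit$converged,
    n_boot = fit$n_boot, seed = fit$seed
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(fitted_csv)) {
    utils::write.csv(fit$fitted, fitted_csv, row.names = FALSE)
  }
  invisible(path)
}
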