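#' Configuration for an end-to-end replication run
#'
#' Bundles every stage's parameters with one global seed.  The defaults
#' reproduce the study-scale experiment: two conditions of 50 kymographs x
#' 60 s each for the blink-model stage (monomer expectation 10.8
#' blinks/kymograph; dimer percentages 87.1 and 45.8 for the two
#' conditions), a small set of fully analyzed synthetic kymograph images, a
#' two-color labeling stage, and FRET/CD spectra stages.
#'
#' @param seed Global integer seed; every stage derives its own sub-seed
#'   from it.
#' @param out_dir Output directory for all artifacts.
#' @param duration_s,frame_rate_hz Kymograph duration and frame rate.
#' @param n_kymographs Kymographs per condition for the blink-count stage.
#' @param bl_mon True monomer blink expectation for the simulated conditions.
#' @param dimer_percent Named numeric: true dimer percentage per condition.
#' @param n_boot Bootstrap replicates for the mixture-fit standard errors.
#' @param n_image_kymographs Synthetic kymograph images to simulate and
#'   analyze end to end (frame fits are the slow stage, so this is kept
#'   small by default).
#' @param dual_color List: `n_molecules`, `dimer_fraction`, `color_probs`,
#'   `label_efficiency`.
#' @param spectra List: `coupling_fret`, `coupling_cd`, `consensus`.
#' @param verbose Print stage progress?
#' @return A `replication_config` list.
#' @export
replication_config <- function(seed = 1L,
                               out_dir = tempfile("oligoblink_run_"),
                               duration_s = 60, frame_rate_hz = 10,
                               n_kymographs = 50, bl_mon = 10.8,
                               dimer_percent = c(condition_a = 87.1,
                                                 condition_b = 45.8),
                               n_boot = 200,
                               n_image_kymographs = 4,
                               dual_color = list(n_molecules = 500,
                                                 dimer_fraction = 0.3,
                                                 color_probs = c(0.5, 0.5),
                                                 label_efficiency = 1),
                               spectra = list(coupling_fret = 0.5,
                                              coupling_cd = 0.5,
                                              consensus = TRUE),
                               verbose = FALSE) {
  if (length(dimer_percent) != 2 || is.null(names(dimer_percent)) ||
      any(names(dimer_percent) == "")) {
    stop("`dimer_percent` must be a named vector with one entry per condition ",
         "(two conditions)", call. = FALSE)
  }
  if (any(dimer_percent < 0) || any(dimer_percent > 100)) {
    stop("`dimer_percent` entries must lie in [0, 100]", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), out_dir = out_dir,
         duration_s = duration_s, frame_rate_hz = frame_rate_hz,
         n_kymographs = n_kymographs, bl_mon = bl_mon,
         dimer_percent = dimer_percent, n_boot = n_boot,
         n_image_kymographs = n_image_kymographs,
         dual_color = dual_color, spectra = spectra, verbose = verbose),
    class = "replication_config"
  )
}

run_stage <- function(name, verbose, expr) {
  if (verbose) message("stage: ", name)
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full replication pipeline
#'
#' Simulate blink counts for each condition and fit the linked dual-Poisson
#' mixture; simulate, write, re-read and analyze kymograph images against
#' their ground truth; simulate a two-color population and estimate its
#' dimer fraction; simulate FRET and CD spectra (including a
#' non-consensus-DNA CD control) and score the analysis bands.  All
#' intermediate artifacts (TIFF, CSV, JSON) are written under
#' `config$out_dir` together with `summary.json` and a file manifest; two
#' runs with the same seed produce byte-identical summaries.
#'
#' @param config A [replication_config()].
#' @return Invisibly, a `replication_report` list (the summary), with `ok`
#'   reflecting all convergence flags.
#' @export
run_replication <- function(config) {
  if (!inherits(config, "replication_config")) {
    stop("`config` must come from replication_config()", call. = FALSE)
  }
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  v <- cfg$verbose
  seed <- cfg$seed
  files <- character(0)
  keep <- function(path) { files <<- c(files, basename(path)); path }

  # -- blink-count stage: simulate per condition, fit jointly ---------------
  blink <- run_stage("blink_model", v, {
    conds <- names(cfg$dimer_percent)
    hists <- list()
    for (i in seq_along(conds)) {
      par <- mixture_sim_params(
        bl_mon = cfg$bl_mon, duration_s = cfg$duration_s,
        alpha = 1 - cfg$dimer_percent[[i]] / 100,
        n_kymographs = cfg$n_kymographs, seed = seed + 10L + i)
      counts <- simulate_blink_counts(par)
      write_blink_counts(counts, keep(file.path(
        cfg$out_dir, sprintf("blink_counts_%s.csv", conds[i]))))
      hists[[conds[i]]] <- blink_histogram(counts, cfg$duration_s)
    }
    fit <- fit_dual_poisson(hists[[1]], hists[[2]], n_boot = cfg$n_boot,
                            seed = seed + 20L)
    write_fit_report(
      fit, keep(file.path(cfg$out_dir, "blink_fit.json")),
      fitted_csv = keep(file.path(cfg$out_dir, "blink_fit_curves.csv")))
    names(fit$alpha) <- names(fit$dimer_percent) <-
      names(fit$se_dimer_percent) <- conds
    fit
  })

  # -- image stage: simulate, write, re-read, analyze -----------------------
  image_stage <- run_stage("kymo_analysis", v, {
    n <- cfg$n_image_kymographs
    res <- data.frame(kymograph_id = character(n), true_blinks = integer(n),
                      counted_blinks = integer(n))
    for (i in seq_len(n)) {
      sim <- simulate_kymograph(kymo_sim_params(
        duration_s = cfg$duration_s, frame_rate_hz = cfg$frame_rate_hz,
        seed = seed + 100L + i))
      tif <- keep(file.path(cfg$out_dir, sprintf("kymo_%02d.tif", i)))
      keep(write_kymograph(sim$kymograph, tif, sim$ground_truth))
      back <- read_kymograph(tif)
      ana <- analyze_kymograph(back$kymograph)
      fits <- cbind(ana$track, on_state = ana$on_state)
      utils::write.csv(fits, keep(file.path(
        cfg$out_dir, sprintf("kymo_%02d_fits.csv", i))), row.names = FALSE)
      res$kymograph_id[i] <- sim$kymograph$id
      res$true_blinks[i] <- sim$ground_truth$true_blink_count
      res$counted_blinks[i] <- ana$blinks$n_blinks
    }
    utils::write.csv(res, keep(file.path(cfg$out_dir, "kymo_blink_summary.csv")),
                     row.names = FALSE)
    list(n = n, agreement = mean(res$true_blinks == res$counted_blinks),
         mean_counted = mean(res$counted_blinks))
  })

  # -- dual-color stage ------------------------------------------------------
  dual <- run_stage("dual_color_stoich", v, {
    dc <- cfg$dual_color
    counts <- simulate_dual_color_population(
      dc$n_molecules, dc$dimer_fraction, dc$color_probs,
      seed = seed + 200L, label_efficiency = dc$label_efficiency)
    write_dual_color_counts(counts, keep(file.path(cfg$out_dir,
                                                   "dual_color_counts.csv")))
    est <- estimate_dimer_fraction(counts, dc$color_probs, dc$label_efficiency)
    jsonlite::write_json(
      list(dual_fraction = est$dual_fraction,
           dimer_fraction = est$dimer_fraction, se_dual = est$se_dual,
           se_dimer = est$se_dimer, capped = est$capped, n_total = est$n_total),
      keep(file.path(cfg$out_dir, "dual_color_estimate.json")),
      auto_unbox = TRUE, digits = NA)
    est
  })

  # -- spectra stage ---------------------------------------------------------
  spect <- run_stage("spectra_analysis", v, {
    bands <- default_bands()
    score_set <- function(sp, band) {
      d <- difference_spectrum(sum_spectra(sp[1:2]), sp$mixture)
      band_enhancement(d, band)
    }
    fret <- simulate_spectra(cfg$spectra$coupling_fret, "fret_excitation",
                             seed = seed + 300L)
    cd <- simulate_spectra(cfg$spectra$coupling_cd, "cd", seed = seed + 301L,
                           consensus = cfg$spectra$consensus)
    cd_ctrl <- simulate_spectra(cfg$spectra$coupling_cd, "cd",
                                seed = seed + 302L, consensus = FALSE)
    for (nm in names(fret)) {
      write_spectrum(fret[[nm]], keep(file.path(
        cfg$out_dir, sprintf("fret_%s.csv", nm))))
      write_spectrum(cd[[nm]], keep(file.path(
        cfg$out_dir, sprintf("cd_%s.csv", nm))))
    }
    list(fret = score_set(fret, bands$fret_donor),
         cd = score_set(cd, bands$cd_dna),
         cd_control = score_set(cd_ctrl, bands$cd_dna))
  })

  summary <- list(
    package = "oligoblink",
    seed = seed,
    config = list(duration_s = cfg$duration_s,
                  frame_rate_hz = cfg$frame_rate_hz,
                  n_kymographs = cfg$n_kymographs, bl_mon = cfg$bl_mon,
                  true_dimer_percent = as.list(cfg$dimer_percent),
                  n_boot = cfg$n_boot,
                  n_image_kymographs = cfg$n_image_kymographs,
                  dual_color = cfg$dual_color, spectra = cfg$spectra),
    blink_fit = list(
      bl_mon = blink$bl_mon, bl_dim = blink$bl_dim,
      dimer_percent = as.list(blink$dimer_percent),
      se_dimer_percent = as.list(blink$se_dimer_percent),
      r_squared = blink$r_squared, converged = blink$converged),
    kymo_images = image_stage,
    dual_color = list(dual_fraction = dual$dual_fraction,
                      dimer_fraction = dual$dimer_fraction,
                      se_dimer = dual$se_dimer, capped = dual$capped),
    spectra = list(
      fret_donor_band_z = spect$fret$z_score,
      fret_donor_band_integral = spect$fret$integrated_difference,
      cd_dna_band_z = spect$cd$z_score,
      cd_control_band_z = spect$cd_control$z_score),
    ok = isTRUE(blink$converged)
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(files = sort(c(files, "summary.json"))),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  class(summary) <- "replication_report"
  invisible(summary)
}

#' @export
print.replication_report <- function(x, ...) {
  cat("Replication run (seed", x$seed, ")\n")
  cat(sprintf("  blink fit: bl_mon %.3g, bl_dim %.3g, R^2 %.3f, dimer %% = %s\n",
              x$blink_fit$bl_mon, x$blink_fit$bl_dim, x$blink_fit$r_squared,
              paste(sprintf("%s %.1f", names(x$blink_fit$dimer_percent),
                            unlist(x$blink_fit$dimer_percent)),
                    collapse = ", ")))
  cat(sprintf("  images: %d analyzed, blink-count agreement %.0f%%\n",
              x$kymo_images$n, 100 * x$kymo_images$agreement))
  cat(sprintf("  dual color: dimer fraction %.3f (SE %.3f)\n",
              x$dual_color$dimer_fraction, x$dual_color$se_dimer))
  cat(sprintf("  spectra z: FRET donor %.2f, CD 281 nm %.2f, CD control %.2f\n",
              x$spectra$fret_donor_band_z, x$spectra$cd_dna_band_z,
              x$spectra$cd_control_band_z))
  cat("  ok:", x$ok, "\n")
  invisible(x)
}
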