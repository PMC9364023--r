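#' Poisson probability mass function
#'
#' Probability of observing `n` blink events in a fixed observation window
#' when the expected number of events is `expected`.  Evaluated in log space
#' (via [stats::dpois()]) so large counts and rates stay stable.
#'
#' @param n Non-negative integer count(s) of blink events.
#' @param expected Non-negative expected count (`expected = 0` puts all mass
#'   at `n = 0`).
#' @return Probability (vectorised over `n`).
#' @examples
#' poisson_pmf(0, 1.94)     # chance a dimer-rate emitter never blinks
#' @export
poisson_pmf <- function(n, expected) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0) || any(n != floor(n))) {
    stop("`n` must be non-negative integer(s)", call. = FALSE)
  }
  if (!is.numeric(expected) || any(!is.finite(expected)) || any(expected < 0)) {
    stop("`expected` must be non-negative", call. = FALSE)
  }
  stats::dpois(n, expected)
}

#' Expected dimer blink count from the monomer expectation
#'
#' A complex carrying two independently blinking quantum dots only goes fully
#' dark when both emitters are dark at once, so the dimer's dark-state *rate*
#' is the square of the monomer's.  Converting the per-kymograph monomer
#' expectation `bl_mon` to a rate (dividing by the duration), squaring, and
#' converting back gives the expected number of complete blinks for a dimer:
#' `(bl_mon / duration_s)^2 * duration_s`.
#'
#' @param bl_mon Expected monomer blinks per kymograph (>= 0).
#' @param duration_s Kymograph duration in seconds (> 0).
#' @return Expected dimer blinks per kymograph.
#' @examples
#' dimer_expected(10.8, 60)  # 1.944 blinks/kymograph
#' @export
dimer_expected <- function(bl_mon, duration_s) {
  if (!is.numeric(bl_mon) || any(!is.finite(bl_mon)) || any(bl_mon < 0)) {
    stop("`bl_mon` must be non-negative", call. = FALSE)
  }
  check_scalar_pos(duration_s, "duration_s")
  (bl_mon / duration_s)^2 * duration_s
}

#' Monomer/dimer blink-count mixture pmf
#'
#' Two-component Poisson mixture in which the monomer component has
#' expectation `bl_mon` and the dimer component has the *linked* expectation
#' [dimer_expected()] — never an independent parameter.  `alpha` is the
#' monomer amplitude.
#'
#' @param n Non-negative integer count(s).
#' @param bl_mon Expected monomer blinks per kymograph.
#' @param alpha Monomer mixture amplitude in `[0, 1]`.
#' @param duration_s Kymograph duration in seconds.
#' @return Probability (vectorised over `n`).
#' @export
mixture_pmf <- function(n, bl_mon, alpha, duration_s) {
  check_probability(alpha, "alpha")
  alpha * poisson_pmf(n, bl_mon) +
    (1 - alpha) * poisson_pmf(n, dimer_expected(bl_mon, duration_s))
}

#' Blink-count histogram
#'
#' Builds the percentage-occurrence histogram of blinks per kymograph that
#' the mixture model is fitted to.  Construct either from raw per-kymograph
#' integer counts (`x` numeric) or from a list of [count_blinks()] results
#' (`x` list; all series must share one duration).
#'
#' @param x Integer vector of per-kymograph blink counts, or a list of
#'   `blink_series` objects.
#' @param duration_s Observation duration in seconds, shared by all
#'   kymographs.  For a list of series carrying their own durations it may be
#'   omitted.
#' @return A `blink_histogram`: list with `percent_at_n` (named percentage
#'   per integer count, bins `0..max`), `duration_s`, `n_kymographs`, and the
#'   raw `counts` when available.
#' @examples
#' blink_histogram(c(1, 1, 2), duration_s = 60)
#' @export
blink_histogram <- function(x, duration_s = NULL) {
  UseMethod("blink_histogram")
}

#' @export
blink_histogram.numeric <- function(x, duration_s = NULL) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    stop("blink counts must be non-negative integers (and non-empty)",
         call. = FALSE)
  }
  check_scalar_pos(duration_s, "duration_s")
  counts <- as.integer(x)
  bins <- 0:max(counts)
  pct <- 100 * tabulate(counts + 1L, nbins = max(counts) + 1L) / length(counts)
  names(pct) <- as.character(bins)
  structure(
    list(percent_at_n = pct, duration_s = duration_s,
         n_kymographs = length(counts), counts = counts),
    class = "blink_histogram"
  )
}

#' @export
blink_histogram.list <- function(x, duration_s = NULL) {
  if (!all(vapply(x, inherits, logical(1), "blink_series"))) {
    stop("list input must contain `blink_series` objects", call. = FALSE)
  }
  durs <- vapply(x, function(s) s$duration_s %||% NA_real_, numeric(1))
  if (is.null(duration_s)) {
    if (any(is.na(durs))) {
      stop("series carry no duration; supply `duration_s`", call. = FALSE)
    }
    duration_s <- durs[1]
  }
  known <- durs[!is.na(durs)]
  if (length(known) && any(abs(known - duration_s) > 1e-9)) {
    stop("kymographs of mixed durations cannot share one histogram ",
         "(the dimer expectation depends on a single duration)", call. = FALSE)
  }
  blink_histogram(vapply(x, function(s) s$n_blinks, numeric(1)), duration_s)
}

#' Construct a blink histogram from pre-binned percentages
#'
#' @param percent_at_n Named numeric vector: names are integer blink counts,
#'   values are percentages of kymographs.  Must sum to 100 within 1e-6.
#' @param duration_s Kymograph duration in seconds.
#' @param n_kymographs Number of kymographs behind the percentages (needed
#'   for bootstrap resampling).
#' @return A `blink_histogram`.
#' @export
as_blink_histogram <- function(percent_at_n, duration_s, n_kymographs = NA_integer_) {
  check_scalar_pos(duration_s, "duration_s")
  nn <- suppressWarnings(as.numeric(names(percent_at_n)))
  if (any(is.na(nn)) || any(nn < 0) || any(nn != floor(nn))) {
    stop("names of `percent_at_n` must be non-negative integers", call. = FALSE)
  }
  if (any(percent_at_n < 0) || abs(sum(percent_at_n) - 100) > 1e-6) {
    stop("percentages must be non-negative and sum to 100 (within 1e-6)",
         call. = FALSE)
  }
  bins <- 0:max(nn)
  pct <- numeric(length(bins))
  pct[nn + 1L] <- percent_at_n
  names(pct) <- as.character(bins)
  structure(
    list(percent_at_n = pct, duration_s = duration_s,
         n_kymographs = as.integer(n_kymographs), counts = NULL),
    class = "blink_histogram"
  )
}

#' @export
print.blink_histogram <- function(x, ...) {
  cat(sprintf("Blink histogram: %s kymographs, %.4g s each, counts 0..%d\n",
              ifelse(is.na(x$n_kymographs), "?", x$n_kymographs),
              x$duration_s, length(x$percent_at_n) - 1L))
  print(round(x$percent_at_n[x$percent_at_n > 0], 2))
  invisible(x)
}

# percentage histogram padded onto bins 0..n_max
padded_percent <- function(hist, n_max) {
  pct <- numeric(n_max + 1L)
  have <- seq_along(hist$percent_at_n) - 1L
  pct[have + 1L] <- hist$percent_at_n
  pct
}

# sum-of-squares objective (and analytic gradient) for the joint fit, on the
# percentage scale, bins 0..n_max for each dataset present
dp_sse <- function(par, bins, obs_list, dur, alpha_fixed) {
  bl <- par[1]
  alphas <- if (is.null(alpha_fixed)) par[-1] else rep(alpha_fixed, length(obs_list))
  bld <- dimer_expected(bl, dur)
  pm <- stats::dpois(bins, bl)
  pd <- stats::dpois(bins, bld)
  sse <- 0
  for (i in seq_along(obs_list)) {
    fit <- 100 * (alphas[i] * pm + (1 - alphas[i]) * pd)
    sse <- sse + sum((obs_list[[i]] - fit)^2)
  }
  sse
}

dp_sse_grad <- function(par, bins, obs_list, dur, alpha_fixed) {
  bl <- max(par[1], 1e-12)
  alphas <- if (is.null(alpha_fixed)) par[-1] else rep(alpha_fixed, length(obs_list))
  bld <- dimer_expected(bl, dur)
  pm <- stats::dpois(bins, bl)
  pd <- stats::dpois(bins, bld)
  dpm_dbl <- pm * (bins / bl - 1)
  dbld_dbl <- 2 * bl / dur
  dpd_dbl <- if (bld > 0) pd * (bins / bld - 1) * dbld_dbl else {
    # at bld == 0 only the n = 0,1 terms have nonzero derivative in the limit
    d <- numeric(length(bins)); d[bins == 0] <- -dbld_dbl; d[bins == 1] <- dbld_dbl
    d
  }
  g_bl <- 0
  g_alpha <- numeric(length(obs_list))
  for (i in seq_along(obs_list)) {
    fit <- 100 * (alphas[i] * pm + (1 - alphas[i]) * pd)
    res <- fit - obs_list[[i]]
    g_bl <- g_bl + sum(2 * res * 100 * (alphas[i] * dpm_dbl + (1 - alphas[i]) * dpd_dbl))
    g_alpha[i] <- sum(2 * res * 100 * (pm - pd))
  }
  if (is.null(alpha_fixed)) c(g_bl, g_alpha) else g_bl
}

dp_optim_once <- function(start, bins, obs_list, dur, alpha_fixed, bl_upper) {
  np <- length(obs_list)
  lower <- c(1e-8, rep(0, if (is.null(alpha_fixed)) np else 0))
  upper <- c(bl_upper, rep(1, if (is.null(alpha_fixed)) np else 0))
  stats::optim(
    par = start, fn = dp_sse, gr = dp_sse_grad,
    bins = bins, obs_list = obs_list, dur = dur, alpha_fixed = alpha_fixed,
    method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(factr = 1e1, maxit = 2000)
  )
}

dp_fit_core <- function(obs_list, bins, dur, alpha_fixed = NULL,
                        starts_bl = seq(0.5, 30, length.out = 10),
                        starts_alpha = c(seq(0.1, 0.9, by = 0.1), 0.5)) {
  bl_upper <- max(100, 5 * max(bins))
  np <- length(obs_list)
  best <- NULL
  log <- data.frame(start_bl = numeric(0), start_alpha = numeric(0),
                    objective = numeric(0), convergence = integer(0))
  for (k in seq_along(starts_bl)) {
    a0 <- starts_alpha[((k - 1) %% length(starts_alpha)) + 1L]
    start <- c(starts_bl[k], if (is.null(alpha_fixed)) rep(a0, np))
    res <- tryCatch(
      dp_optim_once(start, bins, obs_list, dur, alpha_fixed, bl_upper),
      error = function(e) NULL
    )
    if (is.null(res)) next
    log <- rbind(log, data.frame(start_bl = starts_bl[k], start_alpha = a0,
                                 objective = res$value,
                                 convergence = res$convergence))
    better <- is.null(best) || res$value < best$value - 1e-12 ||
      (abs(res$value - best$value) <= 1e-12 && res$par[1] < best$par[1])
    if (better) best <- res
  }
  if (is.null(best)) {
    return(list(converged = FALSE, log = log))
  }
  converged <- best$convergence == 0
  # polish from the incumbent (a line-search failure here just means the
  # incumbent was already at the optimum; it does not revoke convergence)
  res <- tryCatch(
    dp_optim_once(best$par, bins, obs_list, dur, alpha_fixed, bl_upper),
    error = function(e) NULL
  )
  if (!is.null(res) && res$value <= best$value) {
    best <- res
    converged <- converged || res$convergence == 0
  }
  list(converged = converged, par = best$par, value = best$value, log = log)
}

#' Fit the linked dual-Poisson blink mixture to one or two histograms
#'
#' Fits the monomer/dimer Poisson mixture ([mixture_pmf()]) to
#' percentage-occurrence blink histograms by least squares.  The monomer
#' expectation `bl_mon` is shared across datasets (the same quantum dots are
#' assumed for both conditions); the dimer expectation is recomputed from
#' `bl_mon` at every optimizer step via [dimer_expected()] and is never a
#' free parameter.  Each dataset gets its own monomer amplitude `alpha`,
#' hard-bounded to `[0, 1]`.  The support of the fit is the integer bins
#' `0..max(observed)`, zero-padded.
#'
#' Optimization is bounded local least squares (L-BFGS-B with analytic
#' gradients) from 10 starts spread over `bl_mon` in `[0.5, 30]` and a grid
#' of amplitudes; the best objective wins, ties broken towards the smaller
#' `bl_mon`.  Uncertainties on the dimer percentages come from a seeded
#' bootstrap that resamples kymographs with replacement and refits.
#'
#' @param hist_a,hist_b `blink_histogram` objects sharing one duration
#'   (`hist_b` may be `NULL` for a single-dataset fit).
#' @param n_boot Bootstrap replicates for standard errors (default 1000; set
#'   to 0 to skip).
#' @param seed Integer seed for the bootstrap.
#' @param fix_alpha Optionally fix the monomer amplitude(s) to a constant
#'   (e.g. `1` for a pure single-Poisson fit); then only `bl_mon` is free.
#' @return A `dual_poisson_fit` with elements `bl_mon`, `bl_dim`,
#'   `duration_s`, `alpha` (per dataset), `dimer_percent` (= `100 * (1 -
#'   alpha)`), `se_dimer_percent` (bootstrap), `r_squared` (combined, about
#'   the grand mean of all observed percentages), `sse`, `fitted` (long table
#'   of observed vs fitted percentages), `converged`, and optimizer
#'   diagnostics.
#' @examples
#' h <- blink_histogram(stats::rpois(50, 10.8), duration_s = 60)
#' fit <- fit_dual_poisson(h, n_boot = 50, seed = 1)
#' fit$bl_mon
#' @export
fit_dual_poisson <- function(hist_a, hist_b = NULL, n_boot = 1000, seed = 1L,
                             fix_alpha = NULL) {
  if (!inherits(hist_a, "blink_histogram")) {
    stop("`hist_a` must be a blink_histogram", call. = FALSE)
  }
  hists <- list(a = hist_a)
  if (!is.null(hist_b)) {
    if (!inherits(hist_b, "blink_histogram")) {
      stop("`hist_b` must be a blink_histogram", call. = FALSE)
    }
    if (abs(hist_a$duration_s - hist_b$duration_s) > 1e-9) {
      stop("both histograms must share one duration (the linked dimer ",
           "expectation requires a single `dur`)", call. = FALSE)
    }
    hists$b <- hist_b
  }
  if (any(vapply(hists, function(h) length(h$percent_at_n) == 0, logical(1)))) {
    stop("empty histogram", call. = FALSE)
  }
  if (!is.null(fix_alpha)) check_probability(fix_alpha, "fix_alpha")
  dur <- hist_a$duration_s
  n_max <- max(vapply(hists, function(h) length(h$percent_at_n) - 1L, integer(1)))
  bins <- 0:n_max
  obs_list <- lapply(hists, padded_percent, n_max = n_max)

  core <- dp_fit_core(obs_list, bins, dur, alpha_fixed = fix_alpha)
  if (is.null(core$par)) {
    stop("dual-Poisson fit failed to converge from every start; ",
         "diagnostics: ", nrow(core$log), " attempted starts", call. = FALSE)
  }
  bl <- core$par[1]
  alphas <- if (is.null(fix_alpha)) core$par[-1] else rep(fix_alpha, length(hists))
  names(alphas) <- names(hists)
  bld <- dimer_expected(bl, dur)

  fitted_pct <- lapply(alphas, function(a) 100 * mixture_pmf(bins, bl, a, dur))
  sse <- core$value
  all_obs <- unlist(obs_list, use.names = FALSE)
  sst <- sum((all_obs - mean(all_obs))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_

  fitted <- do.call(rbind, lapply(names(hists), function(nm) {
    data.frame(dataset = nm, n_blinks = bins,
               observed_percent = obs_list[[nm]],
               fitted_percent = fitted_pct[[nm]])
  }))
  rownames(fitted) <- NULL

  # bootstrap over kymographs
  se <- rep(NA_real_, length(hists))
  names(se) <- names(hists)
  boot_draws <- NULL
  if (n_boot > 0) {
    ok <- vapply(hists, function(h) !is.null(h$counts) || !is.na(h$n_kymographs),
                 logical(1))
    if (all(ok)) {
      boot_draws <- with_seed(seed, {
        draws <- matrix(NA_real_, n_boot, length(hists),
                        dimnames = list(NULL, names(hists)))
        for (b in seq_len(n_boot)) {
          rehists <- lapply(hists, function(h) {
            if (!is.null(h$counts)) {
              sample(h$counts, length(h$counts), replace = TRUE)
            } else {
              vals <- as.integer(names(h$percent_at_n))
              sample(vals, h$n_kymographs, replace = TRUE,
                     prob = h$percent_at_n / 100)
            }
          })
          bmax <- max(vapply(rehists, max, numeric(1)))
          bbins <- 0:bmax
          bobs <- lapply(rehists, function(cts) {
            100 * tabulate(cts + 1L, nbins = bmax + 1L) / length(cts)
          })
          bres <- dp_fit_core(bobs, bbins, dur, alpha_fixed = fix_alpha,
                              starts_bl = bl, starts_alpha = mean(alphas))
          if (!is.null(bres$par)) {
            ba <- if (is.null(fix_alpha)) bres$par[-1] else rep(fix_alpha, length(hists))
            draws[b, ] <- 100 * (1 - ba)
          }
        }
        draws
      })
      se <- apply(boot_draws, 2, stats::sd, na.rm = TRUE)
    }
  }

  structure(
    list(bl_mon = bl, bl_dim = bld, duration_s = dur,
         alpha = alphas, dimer_percent = 100 * (1 - alphas),
         se_dimer_percent = se, r_squared = r2, sse = sse,
         fitted = fitted, converged = core$converged,
         n_boot = n_boot, seed = as.integer(seed),
         diagnostics = core$log),
    class = "dual_poisson_fit"
  )
}

#' @export
print.dual_poisson_fit <- function(x, ...) {
  cat("Linked dual-Poisson blink mixture fit\n")
  cat(sprintf("  bl_mon = %.4g blinks/kymograph, bl_dim = %.4g (linked), dur = %.4g s\n",
              x$bl_mon, x$bl_dim, x$duration_s))
  for (nm in names(x$alpha)) {
    cat(sprintf("  dataset %s: dimer %.1f%% (SE %.2g), alpha = %.4f\n",
                nm, x$dimer_percent[[nm]], x$se_dimer_percent[[nm]],
                x$alpha[[nm]]))
  }
  cat(sprintf("  combined R^2 = %.4f, SSE = %.4g, converged: %s\n",
              x$r_squared, x$sse, x$converged))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
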