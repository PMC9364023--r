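#' Mixture simulation parameters for blink counts
#'
#' Parameters of the generative version of the linked dual-Poisson mixture:
#' each kymograph is a monomer with probability `alpha` (blink counts then
#' Poisson with mean `bl_mon`) or a dimer with probability `1 - alpha`
#' (Poisson with the linked mean [dimer_expected()]`(bl_mon, duration_s)`).
#' Defaults follow the study scale: 50 kymographs of 60 s.
#'
#' @param bl_mon Expected monomer blinks per kymograph.
#' @param duration_s Kymograph duration in seconds.
#' @param alpha Monomer amplitude in `[0, 1]`.
#' @param n_kymographs Sample size.
#' @param seed Integer seed.
#' @return A validated `mixture_sim_params` list.
#' @export
mixture_sim_params <- function(bl_mon = 10.8, duration_s = 60, alpha = 0.5,
                               n_kymographs = 50, seed = 1L) {
  check_scalar_pos(bl_mon, "bl_mon", strict = FALSE)
  check_scalar_pos(duration_s, "duration_s")
  check_probability(alpha, "alpha")
  if (!is.numeric(n_kymographs) || n_kymographs < 1 ||
      n_kymographs != floor(n_kymographs)) {
    stop("`n_kymographs` must be a positive integer", call. = FALSE)
  }
  structure(
    list(bl_mon = bl_mon, duration_s = duration_s, alpha = alpha,
         n_kymographs = as.integer(n_kymographs), seed = as.integer(seed)),
    class = "mixture_sim_params"
  )
}

#' Sample per-kymograph blink counts from the dual-Poisson mixture
#'
#' @param params A [mixture_sim_params()] object.
#' @return Integer vector of length `n_kymographs`.
#' @examples
#' counts <- simulate_blink_counts(mixture_sim_params(alpha = 0.542, seed = 3))
#' mean(counts)
#' @export
simulate_blink_counts <- function(params) {
  if (!inherits(params, "mixture_sim_params")) {
    stop("`params` must come from mixture_sim_params()", call. = FALSE)
  }
  bl_dim <- dimer_expected(params$bl_mon, params$duration_s)
  with_seed(params$seed, {
    is_mon <- stats::runif(params$n_kymographs) < params$alpha
    lam <- ifelse(is_mon, params$bl_mon, bl_dim)
    stats::rpois(params$n_kymographs, lam)
  })
}

#' Dual-color observation counts
#'
#' Observed single-spot category counts from a two-color labeling experiment:
#' entities showing only color A, only color B, or both colors at once.
#'
#' @param n_dual Dual-colored entities.
#' @param n_color_a,n_color_b Single-colored entities of each color.
#' @return A `dual_color_counts` list with `n_total = n_dual + n_color_a +
#'   n_color_b`.
#' @export
dual_color_counts <- function(n_dual, n_color_a, n_color_b) {
  for (nm in c("n_dual", "n_color_a", "n_color_b")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        v != floor(v)) {
      stop(sprintf("`%s` must be a non-negative integer", nm), call. = FALSE)
    }
  }
  structure(
    list(n_dual = as.integer(n_dual), n_color_a = as.integer(n_color_a),
         n_color_b = as.integer(n_color_b),
         n_total = as.integer(n_dual + n_color_a + n_color_b)),
    class = "dual_color_counts"
  )
}

#' @export
print.dual_color_counts <- function(x, ...) {
  cat(sprintf("Dual-color counts: dual %d, color A %d, color B %d (total %d)\n",
              x$n_dual, x$n_color_a, x$n_color_b, x$n_total))
  invisible(x)
}

#' Simulate two-color labeling of a partially dimerized population
#'
#' Each molecule is a dimer with probability `dimer_fraction`.  Every subunit
#' independently carries a label with probability `label_efficiency` and, if
#' labeled, takes color A or B with probabilities `color_probs` (equimolar
#' premixed quantum dots give `(0.5, 0.5)`).  Entities with no labeled
#' subunit are invisible and excluded from the observed counts.
#'
#' @param n_molecules Population size.
#' @param dimer_fraction Probability a molecule is a dimer, in `[0, 1]`.
#' @param color_probs Two color probabilities summing to 1.
#' @param seed Integer seed.
#' @param label_efficiency Per-subunit probability of carrying any label.
#' @return A [dual_color_counts()] object; the number of invisible
#'   (unlabeled) entities is in `attr(, "n_invisible")`.
#' @examples
#' simulate_dual_color_population(1000, dimer_fraction = 0.3, seed = 2)
#' @export
simulate_dual_color_population <- function(n_molecules, dimer_fraction,
                                           color_probs = c(0.5, 0.5),
                                           seed = 1L, label_efficiency = 1) {
  if (!is.numeric(n_molecules) || n_molecules < 1 ||
      n_molecules != floor(n_molecules)) {
    stop("`n_molecules` must be a positive integer", call. = FALSE)
  }
  check_probability(dimer_fraction, "dimer_fraction")
  check_color_probs(color_probs)
  check_probability(label_efficiency, "label_efficiency")
  qa <- color_probs[1] * label_efficiency
  qb <- color_probs[2] * label_efficiency
  q0 <- 1 - label_efficiency
  with_seed(seed, {
    n_dim <- stats::rbinom(1L, n_molecules, dimer_fraction)
    n_mon <- n_molecules - n_dim
    # monomer: one subunit
    mono <- stats::rmultinom(1L, n_mon, c(qa, qb, q0))
    # dimer: two independent subunits -> categories dual / A-only / B-only /
    # invisible
    di <- stats::rmultinom(1L, n_dim,
                           c(2 * qa * qb,
                             qa^2 + 2 * qa * q0,
                             qb^2 + 2 * qb * q0,
                             q0^2))
    out <- dual_color_counts(n_dual = di[1],
                             n_color_a = mono[1] + di[2],
                             n_color_b = mono[2] + di[3])
    attr(out, "n_invisible") <- as.integer(mono[3] + di[4])
    out
  })
}
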