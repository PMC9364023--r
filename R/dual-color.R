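#' Expected category distribution under two-color labeling
#'
#' For a population with a given dimer fraction in which every subunit
#' independently carries a label with probability `label_efficiency` and, if
#' labeled, takes color A or B with probabilities `color_probs`: a dimer
#' shows both colors only when its two subunits draw different colors, and
#' there are two ways round that can happen, so with equal colors and full
#' efficiency `P(dual | dimer) = 2 * 0.5 * 0.5 = 0.5` — dual-colored counts
#' underestimate dimers by half.  Entities with no labeled subunit are
#' invisible and renormalized out of the observed categories.
#'
#' @param dimer_fraction Proportion of molecules that are dimers, `[0, 1]`.
#' @param color_probs Two color probabilities summing to 1.
#' @param label_efficiency Per-subunit probability of carrying any label,
#'   `(0, 1]`.
#' @return List with `observed` (named probabilities `single_a`, `single_b`,
#'   `dual` over *visible* entities, summing to 1), `p_invisible`, and
#'   `p_dual_given_dimer` (probability a *visible* dimer shows both colors —
#'   the correction factor's denominator).
#' @examples
#' expected_color_distribution(1, c(0.5, 0.5))$observed       # 0.25/0.25/0.5
#' expected_color_distribution(0.5, c(0.7, 0.3))$observed["dual"]  # 0.21
#' @export
expected_color_distribution <- function(dimer_fraction,
                                        color_probs = c(0.5, 0.5),
                                        label_efficiency = 1) {
  check_probability(dimer_fraction, "dimer_fraction")
  check_color_probs(color_probs)
  check_probability(label_efficiency, "label_efficiency", allow_zero = FALSE)
  f <- dimer_fraction
  qa <- color_probs[1] * label_efficiency
  qb <- color_probs[2] * label_efficiency
  q0 <- 1 - label_efficiency
  # dimer subunit-pair outcomes
  dual_d <- 2 * qa * qb
  sa_d <- qa^2 + 2 * qa * q0
  sb_d <- qb^2 + 2 * qb * q0
  inv_d <- q0^2
  p_dual <- f * dual_d
  p_sa <- (1 - f) * qa + f * sa_d
  p_sb <- (1 - f) * qb + f * sb_d
  p_inv <- (1 - f) * q0 + f * inv_d
  visible <- 1 - p_inv
  if (visible <= 0) stop("no entity is visible at these parameters", call. = FALSE)
  list(
    observed = c(single_a = p_sa, single_b = p_sb, dual = p_dual) / visible,
    p_invisible = p_inv,
    p_dual_given_dimer = dual_d / (1 - inv_d)
  )
}

#' Estimate the dimer fraction from dual-color counts
#'
#' The observed dual-colored fraction is divided by the probability that a
#' (visible) dimer shows both colors, `p_dual_given_dimer` — exactly 2x the
#' dual fraction in the default equal-color, full-efficiency case.  Standard
#' errors are binomial on the dual fraction, scaled by the same correction
#' factor.  An estimate above 1 (counts incompatible with the labeling
#' assumptions) is capped at 1 and flagged.
#'
#' @param counts A [dual_color_counts()] object with `n_total > 0`.
#' @param color_probs Two color probabilities summing to 1.
#' @param label_efficiency Per-subunit labeling probability.
#' @return A `stoich_estimate`: `dual_fraction`, `dimer_fraction`, `se_dual`,
#'   `se_dimer`, `capped` flag, `n_total`, and the `assumptions` used.
#' @examples
#' estimate_dimer_fraction(dual_color_counts(15, 45, 40))  # 30% dimer
#' @export
estimate_dimer_fraction <- function(counts, color_probs = c(0.5, 0.5),
                                    label_efficiency = 1) {
  if (!inherits(counts, "dual_color_counts")) {
    stop("`counts` must be a dual_color_counts object", call. = FALSE)
  }
  if (counts$n_total <= 0) stop("`n_total` must be positive", call. = FALSE)
  check_color_probs(color_probs)
  check_probability(label_efficiency, "label_efficiency", allow_zero = FALSE)
  p_dgd <- expected_color_distribution(1, color_probs,
                                       label_efficiency)$p_dual_given_dimer
  dual_fraction <- counts$n_dual / counts$n_total
  raw <- dual_fraction / p_dgd
  capped <- raw > 1
  se_dual <- sqrt(dual_fraction * (1 - dual_fraction) / counts$n_total)
  structure(
    list(dual_fraction = dual_fraction,
         dimer_fraction = min(raw, 1),
         se_dual = se_dual,
         se_dimer = se_dual / p_dgd,
         capped = capped,
         n_total = counts$n_total,
         assumptions = list(color_probs = color_probs,
                            label_efficiency = label_efficiency,
                            p_dual_given_dimer = p_dgd)),
    class = "stoich_estimate"
  )
}

#' @export
print.stoich_estimate <- function(x, ...) {
  cat(sprintf(
    "Dual-color stoichiometry: %.1f%% dual-colored (SE %.2g) -> %.1f%% dimer (SE %.2g)%s\n",
    100 * x$dual_fraction, 100 * x$se_dual, 100 * x$dimer_fraction,
    100 * x$se_dimer,
    if (x$capped) " [capped at 100%: counts exceed labeling assumptions]" else ""))
  invisible(x)
}
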