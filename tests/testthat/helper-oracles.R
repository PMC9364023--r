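# Independent oracles and fixture builders used across the suite.

# Exact percentage histogram of the monomer/dimer mixture pmf, truncated at
# nmax and renormalized to 100.
exact_mixture_hist <- function(bl_mon, alpha, duration_s, nmax = 40,
                               n_kymographs = 50L) {
  p <- mixture_pmf(0:nmax, bl_mon, alpha, duration_s)
  as_blink_histogram(stats::setNames(100 * p / sum(p), 0:nmax), duration_s,
                     n_kymographs)
}

# Brute-force one-parameter Poisson least-squares fit on the percentage
# scale: grid search over the expected value at `step` resolution.
grid_poisson_ls <- function(percent, bins, grid) {
  sse <- vapply(grid, function(bl) {
    sum((percent - 100 * stats::dpois(bins, bl))^2)
  }, numeric(1))
  grid[which.min(sse)]
}

# Independent two-state (ON/dark) chain simulator used as an oracle for the
# image simulator's marginal blink statistics.  Counts interior dark runs
# only, like the package.
chain_blink_count <- function(n_frames, p_blink, p_recover) {
  state <- TRUE
  dark <- logical(n_frames)
  for (t in seq_len(n_frames)) {
    dark[t] <- !state
    state <- if (state) stats::runif(1) >= p_blink else stats::runif(1) < p_recover
  }
  r <- rle(dark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sum(r$values & starts > 1L & ends < n_frames)
}

# Brute-force enumeration of two-color labeling outcomes for one molecule.
# Subunit states: color A (prob pa*e), color B (pb*e), unlabeled (1-e).
enumerate_color_distribution <- function(dimer_fraction, color_probs,
                                         label_efficiency) {
  qa <- color_probs[1] * label_efficiency
  qb <- color_probs[2] * label_efficiency
  q0 <- 1 - label_efficiency
  states <- c(A = qa, B = qb, U = q0)
  cat_of <- function(labels) {
    labels <- labels[labels != "U"]
    if (length(labels) == 0) "invisible"
    else if (all(labels == "A")) "single_a"
    else if (all(labels == "B")) "single_b"
    else "dual"
  }
  probs <- c(single_a = 0, single_b = 0, dual = 0, invisible = 0)
  for (s in names(states)) {  # monomer: one subunit
    probs[cat_of(s)] <- probs[cat_of(s)] + (1 - dimer_fraction) * states[[s]]
  }
  for (s1 in names(states)) for (s2 in names(states)) {  # dimer: two subunits
    probs[cat_of(c(s1, s2))] <- probs[cat_of(c(s1, s2))] +
      dimer_fraction * states[[s1]] * states[[s2]]
  }
  probs
}

# Difference spectrum of a simulated spectrum set.
sim_difference <- function(sp) {
  difference_spectrum(sum_spectra(sp[c("component_a", "component_b")]),
                      sp$mixture)
}
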