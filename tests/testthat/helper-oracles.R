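# Independent oracles used across the suite: closed-form / linear-algebra
# solutions for birth-death chains, a brute-force permutation enumerator, and
# small fixture builders. These never call the code paths they validate.

# Mean first-passage time from each state in (target, N] to first reach
# `target`, solving the generator linear system directly. vf[m] is the rate
# (m-1) -> m, vr[m] the rate m -> (m-1) (1-based, as in rate_table), with a
# reflecting ceiling at N.
oracle_mfpt <- function(vf, vr, start, target) {
  N <- length(vf)
  states <- (target + 1L):N
  n <- length(states)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m <- states[i]
    up <- if (m < N) vf[m + 1L] else 0
    dn <- vr[m]
    A[i, i] <- -(up + dn)
    if (m < N) A[i, i + 1L] <- up
    if (i > 1L) A[i, i - 1L] <- dn
  }
  tt <- solve(A, rep(-1, n))
  tt[match(start, states)]
}

# Probability of hitting 0 before reaching `stop_state`, by first-step
# analysis on the embedded jump chain (absorbing at both ends).
oracle_hit_zero_first <- function(vf, vr, m0, stop_state) {
  states <- 1:(stop_state - 1L)
  n <- length(states)
  A <- diag(n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    m <- states[i]
    p_up <- vf[m + 1L] / (vf[m + 1L] + vr[m])
    p_dn <- 1 - p_up
    if (m - 1L >= 1L) A[i, i - 1L] <- -p_dn else b[i] <- b[i] + p_dn
    if (m + 1L <= stop_state - 1L) A[i, i + 1L] <- -p_up
  }
  h <- solve(A, b)
  if (m0 == 0L) 1 else if (m0 >= stop_state) 0 else h[m0]
}

# Boltzmann stationary law of the reflecting chain, computed from the rates
# alone (pi(m)/pi(m-1) = vf[m]/vr[m]).
oracle_stationary <- function(vf, vr) {
  w <- exp(c(0, cumsum(log(vf) - log(vr))))
  w / sum(w)
}

# all permutations of 1..n, brute force
oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# hand-made rate table (bypasses sequence thermodynamics) for chain-level
# tests
make_rates <- function(v_f, v_r, k0 = 1) {
  structure(list(n_positions = length(v_f), v_f = v_f, v_r = v_r, k0 = k0,
                 ddG = rep(NA_real_, length(v_f)), RT = 0.6163),
            class = "rate_table")
}

# hand-made trajectory (bypasses the simulator) for observable tests
make_traj <- function(times, states, max_t, N, m0 = states[1L],
                      boundary = "reflecting") {
  structure(list(times = times, states = as.integer(states),
                 m0 = as.integer(m0), max_t = max_t, N = as.integer(N),
                 absorbed = FALSE, t_abs = NA_real_, boundary = boundary),
            class = "rloop_trajectory")
}

# degenerate energy model in which hybrid and duplex doublet tables agree,
# so every exchange energy is zero
flat_model <- function() {
  dd <- default_energy_model()
  rna_keys <- names(dd$rna_dna)
  dna_vals <- vapply(rna_keys, function(k) {
    rloopkmc:::dna_stack(dd, chartr("U", "T", k))
  }, numeric(1L))
  energy_model(dna_dna = dd$dna_dna,
               rna_dna = stats::setNames(dna_vals, rna_keys),
               mismatch_offsets = dd$mismatch_offsets)
}

# random perfectly matched pair under a fixed seed
random_pair <- function(seed, n = 20L) {
  make_pair(generator_spec(seed = seed, guide_length = n), 1L)
}
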