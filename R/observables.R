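# Trajectory-ensemble observables: time-fraction occupancy profiles,
# threshold occupancies, first-passage lifetimes, fall-off probabilities and
# re-trapping counts. Time after absorption at m = 0 counts as time spent at
# m = 0, so all time fractions are normalized over [0, max_t]; a trajectory
# censored at max_t holds its last state to the horizon.

# time spent in each state 0..N for one trajectory
.state_times <- function(traj) {
  occ <- numeric(traj$N + 1L)
  tt <- c(traj$times, traj$max_t)
  dt <- diff(tt)
  for (k in seq_along(dt)) {
    occ[traj$states[k] + 1L] <- occ[traj$states[k] + 1L] + dt[k]
  }
  occ
}

.as_ensemble <- function(trajs) {
  if (inherits(trajs, "rloop_trajectory")) trajs <- list(trajs)
  if (length(trajs) == 0L) stop("empty trajectory ensemble")
  mt <- vapply(trajs, `[[`, numeric(1L), "max_t")
  if (length(unique(mt)) != 1L) stop("trajectories must share max_t")
  trajs
}

#' Time-fraction occupancy profile of an ensemble
#'
#' Fraction of the simulated window `[0, max_t]` that the R-loop spends at
#' each length `m`, averaged over replicate trajectories. Entries sum to 1;
#' time after absorption accrues to `m = 0`.
#'
#' @param trajs an `rloop_ensemble`, list of trajectories, or a single
#'   `rloop_trajectory`.
#' @return named numeric vector over states `0..N`.
#' @export
occupancy_profile <- function(trajs) {
  trajs <- .as_ensemble(trajs)
  occ <- Reduce(`+`, lapply(trajs, .state_times)) / length(trajs)
  stats::setNames(occ / trajs[[1L]]$max_t, 0:trajs[[1L]]$N)
}

#' Threshold occupancy: mean fraction of time m >= m_star
#'
#' The per-replicate time fraction with `m(t) >= m_star`, its mean over
#' replicates and the standard error of that mean (computed across
#' replicates, which are i.i.d.). Equals the tail sum of
#' [occupancy_profile()].
#'
#' @inheritParams occupancy_profile
#' @param m_star threshold position, `0..N`.
#' @return object of class `stability_estimate`: list with `mean`, `sem`,
#'   `reps`, `m_star`, `per_rep`.
#' @export
threshold_occupancy <- function(trajs, m_star) {
  trajs <- .as_ensemble(trajs)
  N <- trajs[[1L]]$N
  stopifnot(m_star >= 0, m_star <= N)
  fr <- vapply(trajs, function(tr) {
    sum(.state_times(tr)[(m_star + 1L):(N + 1L)]) / tr$max_t
  }, numeric(1L))
  .stability_estimate(fr, m_star)
}

.stability_estimate <- function(per_rep, m_star) {
  n <- length(per_rep)
  structure(list(mean = mean(per_rep),
                 sem = if (n > 1L) stats::sd(per_rep) / sqrt(n) else NA_real_,
                 reps = n, m_star = m_star, per_rep = per_rep),
            class = "stability_estimate")
}

#' @export
print.stability_estimate <- function(x, ...) {
  cat(sprintf(
    "mean fraction of time m >= %d: %.4f (SEM %.4f, %d replicates)\n",
    x$m_star, x$mean, x$sem, x$reps))
  invisible(x)
}

#' Stability profile over a range of thresholds
#'
#' @inheritParams occupancy_profile
#' @param thresholds integer vector of threshold positions `m_star`.
#' @return data frame (class `stability_profile`) with columns `m_star`,
#'   `mean_frac`, `sem`, `reps`.
#' @export
stability_profile <- function(trajs, thresholds) {
  trajs <- .as_ensemble(trajs)
  rows <- lapply(thresholds, function(ms) {
    est <- threshold_occupancy(trajs, ms)
    data.frame(m_star = ms, mean_frac = est$mean, sem = est$sem,
               reps = est$reps)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stability_profile", "data.frame")
  out
}

#' First-passage lifetime to drop below a threshold
#'
#' Simulates replicates started at `start_m` and records the first time the
#' R-loop shrinks below `m_star` (e.g. the lifetime from full invasion to
#' re-annealing below position 16). Replicates that never drop below the
#' threshold before `max_t` are censored and reported separately; the mean is
#' taken over uncensored replicates only.
#'
#' @param system an `rloop_system` or `rate_table`.
#' @param start_m initial R-loop length (> `m_star`).
#' @param m_star threshold position; the passage event is `m < m_star`.
#' @param reps number of replicates.
#' @param max_t censoring horizon.
#' @param seed optional integer seed.
#' @param boundary boundary at `m = 0` (irrelevant for `m_star >= 1`, where
#'   passage happens before any absorption).
#' @return list with `mean` (NA if all replicates censored), `times`
#'   (per-replicate passage times, NA = censored), `censored_fraction`,
#'   `reps`.
#' @export
lifetime_to_below <- function(system, start_m, m_star, reps = 1000,
                              max_t = 1e5, seed = NULL,
                              boundary = c("absorbing", "reflecting")) {
  rates <- .as_rates(system)
  boundary <- match.arg(boundary)
  stopifnot(start_m > m_star, m_star >= 0)
  tt <- with_seed(seed, .kmc_first_passage_reps_cpp(
    rates$v_f, rates$v_r, as.integer(start_m), as.integer(m_star), max_t,
    boundary == "absorbing", as.integer(reps)))
  ok <- !is.na(tt)
  list(mean = if (any(ok)) mean(tt[ok]) else NA_real_,
       times = tt, censored_fraction = mean(!ok), reps = reps)
}

#' Fall-off probability before a stop event
#'
#' With the absorbing boundary at `m = 0` (guide dissociation), the fraction
#' of replicates that fall off the protospacer before the stop event:
#' reaching full invasion (`m = N`) or traversing a mismatch (reaching
#' `m >= mismatch_position`). Replicates censored before either event are
#' excluded from the point estimate and reported.
#'
#' @inheritParams lifetime_to_below
#' @param m0 initial R-loop length (default 10, mid-invasion).
#' @param stop `"full_invasion"` or `"past_mismatch"`.
#' @param mismatch_position required when `stop = "past_mismatch"`; defaults
#'   to the pair's single annotated mismatch when `system` is an
#'   `rloop_system`.
#' @return list with `estimate`, exact binomial `conf_int` (95%), counts
#'   `n_falloff`, `n_stop`, `n_censored`, `reps`.
#' @export
falloff_probability <- function(system, m0 = 10,
                                stop = c("full_invasion", "past_mismatch"),
                                mismatch_position = NULL, reps = 1000,
                                max_t = 100, seed = NULL,
                                boundary = "absorbing") {
  rates <- .as_rates(system)
  stop <- match.arg(stop)
  if (!identical(boundary, "absorbing")) {
    base::stop("fall-off probability is defined only for the absorbing boundary")
  }
  stop_state <- if (stop == "full_invasion") rates$n_positions else {
    if (is.null(mismatch_position) && inherits(system, "rloop_system")) {
      mmp <- system$pair$mismatches$position
      if (length(mmp) == 1L) mismatch_position <- mmp
    }
    if (is.null(mismatch_position)) {
      base::stop("mismatch_position required for stop = 'past_mismatch'")
    }
    as.integer(mismatch_position)
  }
  res <- with_seed(seed, .kmc_falloff_reps_cpp(
    rates$v_f, rates$v_r, as.integer(m0), stop_state, max_t,
    as.integer(reps)))
  n_fall <- sum(res == 1L, na.rm = TRUE)
  n_stop <- sum(res == 0L, na.rm = TRUE)
  n_cens <- sum(is.na(res))
  n_dec <- n_fall + n_stop
  ci <- if (n_dec > 0L) as.numeric(stats::binom.test(n_fall, n_dec)$conf.int)
        else c(NA_real_, NA_real_)
  list(estimate = if (n_dec > 0L) n_fall / n_dec else NA_real_,
       conf_int = ci, n_falloff = n_fall, n_stop = n_stop,
       n_censored = n_cens, reps = reps, stop_state = stop_state)
}

#' Count re-trapping events behind a mismatch
#'
#' After the first time a trajectory invades to `m >= p`, counts the maximal
#' excursions back to `m < p` (each excursion is one re-trapping of the
#' R-loop behind the mismatch). Returns 0 when `p` is never reached.
#'
#' @param traj an `rloop_trajectory`.
#' @param p mismatch position, `1..N`.
#' @return integer count.
#' @export
retrap_count <- function(traj, p) {
  stopifnot(inherits(traj, "rloop_trajectory"), p >= 1, p <= traj$N)
  above <- traj$states >= p
  first <- match(TRUE, above)
  if (is.na(first)) return(0L)
  above <- above[first:length(above)]
  # number of TRUE -> FALSE transitions
  sum(above[-length(above)] & !above[-1L])
}
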