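# Rate construction and the rloop_system model object. The R-loop length m
# performs a birth-death walk on 0..N with sequence-dependent rates
#   v_f(m) = k0 exp(-ddG(m+1) / 2RT)   (m -> m+1, m = 0..N-1)
#   v_r(m) = k0 exp(+ddG(m)   / 2RT)   (m -> m-1, m = 1..N)
# where ddG(m) is the per-position exchange energy. The factor 1/2 splits the
# energy change symmetrically between the forward and reverse rates so that
# v_f(m)/v_r(m+1) = exp(-ddG(m+1)/RT), i.e. detailed balance with Boltzmann
# stationary law pi(m) ~ exp(-G(m)/RT), G(m) = sum_{j<=m} ddG(j).

#' Build the KMC rate table for a guide/target pair
#'
#' @inheritParams step_exchange_energy
#' @param k0 rate prefactor (1/time, arbitrary units); sets the time scale.
#' @return object of class `rate_table`: list with `n_positions`, `v_f`
#'   (rates of `m -> m+1` for `m = 0..N-1`), `v_r` (rates of `m -> m-1` for
#'   `m = 1..N`), `k0`, and the exchange-energy profile `ddG`.
#' @export
build_rate_table <- function(pair, model, k0 = 1) {
  stopifnot(k0 >= 0, is.finite(k0))
  ddG <- exchange_profile(pair, model)
  rt2 <- 2 * model$R * model$T
  x <- ddG / rt2
  if (any(abs(x) > 700)) {
    stop(sprintf("exchange energy at position %d overflows exp()",
                 which(abs(x) > 700)[1L]))
  }
  structure(list(n_positions = pair$N,
                 v_f = k0 * exp(-x),
                 v_r = k0 * exp(+x),
                 k0 = k0, ddG = ddG, RT = model$R * model$T),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("KMC rate table: N = %d positions, k0 = %g\n",
              x$n_positions, x$k0))
  print(data.frame(m = seq_len(x$n_positions), ddG = x$ddG,
                   v_f = x$v_f, v_r = x$v_r), row.names = FALSE)
  invisible(x)
}

#' R-loop strand-invasion system
#'
#' Couples a guide/target pair with an energy model into a simulatable
#' model object; `simulate()` draws trajectory ensembles from it.
#'
#' @inheritParams build_rate_table
#' @return object of class `rloop_system`.
#' @export
rloop_system <- function(pair, model = default_energy_model(), k0 = 1) {
  structure(list(pair = pair, model = model,
                 rates = build_rate_table(pair, model, k0)),
            class = "rloop_system")
}

#' @export
print.rloop_system <- function(x, ...) {
  cat("R-loop strand-invasion system\n")
  print(x$pair)
  cat(sprintf("  k0 = %g; exchange energies (kcal/mol): %s\n", x$rates$k0,
              paste(sprintf("%.2f", x$rates$ddG), collapse = " ")))
  invisible(x)
}

#' @method summary rloop_system
#' @export
summary.rloop_system <- function(object, ...) {
  p <- boltzmann_occupancy(object$rates)
  cat("R-loop system summary\n")
  cat(sprintf("  N = %d, equilibrium (reflecting) occupancy by state 0..N:\n",
              object$rates$n_positions))
  print(round(p, 4))
  cat(sprintf("  hybrid dG37 = %.2f kcal/mol (incl. init %.2f)\n",
              duplex_binding_energy(object$pair, object$model),
              object$model$dg_init))
  invisible(p)
}

#' Exact Boltzmann stationary occupancy of the reflecting chain
#'
#' Closed-form stationary law of the birth-death walk with both boundaries
#' reflecting: `pi(m)` proportional to `exp(-G(m)/RT)` with
#' `G(m) = sum_{j<=m} ddG(j)`. Used as the analytic reference for the
#' simulated equilibrium occupancy.
#'
#' @param rates a [build_rate_table()] result.
#' @return numeric vector of probabilities over states `0..N`.
#' @export
boltzmann_occupancy <- function(rates) {
  lw <- c(0, cumsum(log(rates$v_f) - log(rates$v_r)))
  w <- exp(lw - max(lw))
  stats::setNames(w / sum(w), 0:rates$n_positions)
}

.as_rates <- function(x) {
  if (inherits(x, "rloop_system")) x$rates
  else if (inherits(x, "rate_table")) x
  else stop("expected an rloop_system or rate_table")
}

#' Run one Gillespie trajectory
#'
#' Exact stochastic simulation of the R-loop length: the waiting time in
#' state `m` is exponential with rate `v_f(m) + v_r(m)` (boundary-adjusted)
#' and the next state is chosen proportionally to the two rates. With the
#' absorbing boundary, reaching `m = 0` (complete guide dissociation)
#' terminates the walk and the remaining time is spent at 0.
#'
#' @param system an `rloop_system` or `rate_table`.
#' @param m0 initial R-loop length in `0..N`.
#' @param max_t censoring horizon (arbitrary time units).
#' @param boundary `"absorbing"` or `"reflecting"` at `m = 0`.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return object of class `rloop_trajectory`: `times` (event times starting
#'   at 0), `states` (state entered at each time), `m0`, `max_t`, `N`,
#'   `absorbed`, `t_abs`, `boundary`.
#' @export
gillespie_run <- function(system, m0, max_t, boundary = c("absorbing",
                                                          "reflecting"),
                          seed = NULL) {
  rates <- .as_rates(system)
  boundary <- match.arg(boundary)
  stopifnot(max_t > 0)
  res <- with_seed(seed, .kmc_path_cpp(rates$v_f, rates$v_r, as.integer(m0),
                                       max_t, boundary == "absorbing"))
  structure(list(times = res$times, states = as.integer(res$states),
                 m0 = as.integer(m0), max_t = max_t,
                 N = rates$n_positions, absorbed = res$absorbed,
                 t_abs = res$t_abs, boundary = boundary),
            class = "rloop_trajectory")
}

#' @export
print.rloop_trajectory <- function(x, ...) {
  cat(sprintf(
    "R-loop trajectory: %d events over [0, %g], m0 = %d, boundary %s%s\n",
    length(x$times) - 1L, x$max_t, x$m0, x$boundary,
    if (isTRUE(x$absorbed)) sprintf(", absorbed at t = %.3g", x$t_abs) else ""))
  invisible(x)
}

#' @method plot rloop_trajectory
#' @export
plot.rloop_trajectory <- function(x, ...) {
  graphics::plot(c(x$times, x$max_t), c(x$states, x$states[length(x$states)]),
                 type = "s", xlab = "time (arbitrary units)",
                 ylab = "R-loop length m", ylim = c(0, x$N), ...)
  invisible(x)
}

#' Simulate trajectory ensembles from an R-loop system
#'
#' @param object an `rloop_system`.
#' @param nsim number of replicate trajectories.
#' @param seed master seed; replicate `i` runs under the derived seed
#'   `derive_seed(seed, i)` so ensembles are reproducible and extendable.
#' @param m0 initial R-loop length (default: full invasion, `N`).
#' @param max_t censoring horizon.
#' @param boundary boundary condition at `m = 0`.
#' @param ... unused.
#' @return list of `rloop_trajectory` objects, class `rloop_ensemble`.
#' @exportS3Method stats::simulate
simulate.rloop_system <- function(object, nsim = 1, seed = NULL,
                                  m0 = object$rates$n_positions,
                                  max_t = 10000,
                                  boundary = c("absorbing", "reflecting"),
                                  ...) {
  boundary <- match.arg(boundary)
  seeds <- if (is.null(seed)) vector("list", nsim) else
    as.list(derive_seed(seed, seq_len(nsim)))
  out <- lapply(seeds, function(s) gillespie_run(object, m0, max_t,
                                                 boundary, seed = s))
  class(out) <- "rloop_ensemble"
  out
}

#' @export
print.rloop_ensemble <- function(x, ...) {
  cat(sprintf("R-loop ensemble: %d trajectories (m0 = %d, max_t = %g, %s)\n",
              length(x), x[[1L]]$m0, x[[1L]]$max_t, x[[1L]]$boundary))
  invisible(x)
}
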