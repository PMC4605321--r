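# Ensemble observables: occupancy profiles, threshold occupancy,
# first-passage lifetimes, fall-off probabilities, re-trapping.

test_that("a hand-scripted trajectory integrates to hand-computed fractions", {
  # path: m=2 on [0,1), 3 on [1,2.5), 2 on [2.5,4), 1 on [4,10); max_t = 10
  traj <- make_traj(times = c(0, 1, 2.5, 4), states = c(2, 3, 2, 1),
                    max_t = 10, N = 4)
  prof <- occupancy_profile(traj)
  expect_equal(unname(prof),
               c(0, 6, 1 + 1.5, 1.5, 0) / 10)
  expect_equal(sum(prof), 1)
})

test_that("absorbed time accrues to m = 0 and fractions stay normalized", {
  rt <- make_rates(v_f = rep(0.1, 3), v_r = rep(5, 3))
  trajs <- simulate(structure(list(rates = rt), class = "rloop_system"),
                    nsim = 20, seed = 2, m0 = 2, max_t = 100,
                    boundary = "absorbing")
  prof <- occupancy_profile(trajs)
  expect_equal(sum(prof), 1)
  expect_gt(prof[["0"]], 0.9)  # strongly re-annealing chain dissociates fast
})

test_that("threshold occupancy is the tail sum of the occupancy profile", {
  sys <- rloop_system(aavs1_pair("sgRNA"))
  trajs <- simulate(sys, nsim = 10, seed = 3, m0 = 20, max_t = 200)
  prof <- occupancy_profile(trajs)
  for (ms in c(0L, 5L, 16L, 20L)) {
    est <- threshold_occupancy(trajs, ms)
    expect_equal(est$mean, sum(prof[(ms + 1L):21L]), tolerance = 1e-12)
  }
  expect_equal(threshold_occupancy(trajs, 0L)$mean, 1)
})

test_that("threshold occupancy is non-increasing in the threshold", {
  sys <- rloop_system(aavs1_pair("tru-gRNA"))
  trajs <- simulate(sys, nsim = 20, seed = 4, m0 = 10, max_t = 100)
  prof <- stability_profile(trajs, 0:18)
  expect_true(all(diff(prof$mean_frac) <= 1e-12))
  expect_true(all(prof$sem >= 0 | is.na(prof$sem)))
})

test_that("an energetic penalty at one position cannot raise distal occupancy", {
  model <- default_energy_model()
  base <- guide_target_pair(strrep("A", 20), strrep("A", 20))
  weak <- inject_mismatch(base, 12, "rA.dA")   # positive offset at 12/13
  pi_base <- boltzmann_occupancy(build_rate_table(base, model))
  pi_weak <- boltzmann_occupancy(build_rate_table(weak, model))
  for (ms in 13:20) {
    expect_lte(sum(pi_weak[(ms + 1L):21L]), sum(pi_base[(ms + 1L):21L]) + 1e-12)
  }
})

test_that("lifetimes: no reverse rates means every replicate is censored", {
  rt <- make_rates(v_f = rep(1, 5), v_r = rep(0, 5))
  lt <- lifetime_to_below(rt, start_m = 5, m_star = 3, reps = 50,
                          max_t = 10, seed = 1)
  expect_identical(lt$censored_fraction, 1)
  expect_true(is.na(lt$mean))
})

test_that("uniform-chain first-passage times match the linear-solve oracle", {
  vf <- rep(1, 8); vr <- rep(1, 8)
  rt <- make_rates(vf, vr)
  expected <- oracle_mfpt(vf, vr, start = 8L, target = 4L)
  lt <- lifetime_to_below(rt, start_m = 8, m_star = 5, reps = 4000,
                          max_t = 1e4, seed = 11)
  expect_identical(lt$censored_fraction, 0)
  se <- stats::sd(lt$times) / sqrt(lt$reps)
  expect_lt(abs(lt$mean - expected), 4 * se)
})

test_that("fall-off probability reproduces the gambler's ruin law", {
  vf <- rep(1, 10); vr <- rep(1, 10)
  rt <- make_rates(vf, vr)
  for (m0 in c(3L, 7L)) {
    fo <- falloff_probability(rt, m0 = m0, stop = "full_invasion",
                              reps = 3000, max_t = 1e4, seed = m0)
    expect_identical(fo$n_censored, 0L)
    p <- 1 - m0 / 10
    se <- sqrt(p * (1 - p) / 3000)
    expect_lt(abs(fo$estimate - p), 4 * se)
    expect_true(fo$conf_int[1] <= p && p <= fo$conf_int[2])
  }
})

test_that("a tiny asymmetric chain matches first-step analysis exactly", {
  vf <- c(0.8, 1.9, 0.4); vr <- c(1.2, 0.3, 2.5)
  rt <- make_rates(vf, vr)
  expected <- oracle_hit_zero_first(vf, vr, m0 = 2L, stop_state = 3L)
  fo <- falloff_probability(rt, m0 = 2, stop = "full_invasion", reps = 5000,
                            max_t = 1e4, seed = 21)
  se <- sqrt(expected * (1 - expected) / 5000)
  expect_lt(abs(fo$estimate - expected), 4 * se)
})

test_that("no downward rates means zero fall-off", {
  rt <- make_rates(v_f = rep(1, 5), v_r = rep(0, 5))
  fo <- falloff_probability(rt, m0 = 2, stop = "full_invasion", reps = 100,
                            max_t = 100, seed = 1)
  expect_identical(fo$estimate, 0)
})

test_that("fall-off is undefined for a reflecting boundary", {
  rt <- make_rates(rep(1, 5), rep(1, 5))
  expect_error(falloff_probability(rt, m0 = 2, boundary = "reflecting"),
               "absorbing")
})

test_that("re-trap counts match hand counts on scripted paths", {
  path <- c(10, 14, 13, 15, 13, 20)
  traj <- make_traj(times = seq(0, 5), states = path, max_t = 6, N = 20)
  expect_identical(retrap_count(traj, 14), 2L)
  mono <- make_traj(times = 0:5, states = 10:15, max_t = 6, N = 20)
  expect_identical(retrap_count(mono, 14), 0L)
  low <- make_traj(times = 0:3, states = c(5, 6, 5, 6), max_t = 4, N = 20)
  expect_identical(retrap_count(low, 14), 0L)
})

test_that("tru-gRNA R-loops are more volatile than sgRNA on the same target", {
  sg <- rloop_system(aavs1_pair("sgRNA"))
  tru <- rloop_system(aavs1_pair("tru-gRNA"))
  e_sg <- simulate(sg, nsim = 50, seed = 7, m0 = 20, max_t = 500)
  e_tru <- simulate(tru, nsim = 50, seed = 7, m0 = 18, max_t = 500)
  var_state <- function(e) mean(vapply(e, function(tr) {
    occ <- rloopkmc:::.state_times(tr) / tr$max_t
    mu <- sum((0:tr$N) * occ)
    sum(((0:tr$N) - mu)^2 * occ)
  }, numeric(1)))
  expect_gt(var_state(e_tru), var_state(e_sg))
  expect_lt(threshold_occupancy(e_tru, 16)$mean - 0.02,
            threshold_occupancy(e_sg, 16)$mean)
  expect_error(occupancy_profile(list()), "empty")
})
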