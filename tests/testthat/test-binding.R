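# Binding statistics: 1/k-weighted histograms, empirical Gaussian peak
# fits, and the Kd/Ka estimators.

test_that("single-contact proteins increment every covered bp by one", {
  ev <- binding_events("d1", 10, 20)
  h <- binding_histogram(ev, 50)
  expect_equal(h[10:20], rep(1, 11))
  expect_equal(sum(h[-(10:20)]), 0)
  expect_equal(attr(h, "protein_mass"), 1)
})

test_that("multi-contact proteins spread 1/k weight over each contact", {
  ev <- binding_events(rep("d1", 2), c(5, 30), c(10, 35),
                       contact_index = 1:2, n_contacts = 2L)
  h <- binding_histogram(ev, 40)
  expect_equal(h[5:10], rep(0.5, 6))
  expect_equal(h[30:35], rep(0.5, 6))
  expect_equal(attr(h, "protein_mass"), 1)
})

test_that("histogram mass equals the protein count for any 1/k layout", {
  set.seed(6)
  n_prot <- 20L
  rows <- lapply(seq_len(n_prot), function(i) {
    k <- sample(1:3, 1)
    s <- sort(sample(1:180, k))
    binding_events(rep(sprintf("d%02d", i), k), s, s + 10,
                   contact_index = seq_len(k), n_contacts = k)
  })
  ev <- do.call(rbind, rows)
  h <- binding_histogram(ev, 200)
  expect_equal(attr(h, "protein_mass"), n_prot, tolerance = 1e-12)
  expect_equal(sum(1 / ev$n_contacts), n_prot, tolerance = 1e-12)
})

test_that("events outside the substrate are rejected by name", {
  ev <- binding_events("molX", 95, 105)
  expect_error(binding_histogram(ev, 100), "molX")
  expect_error(binding_events("d", 10, 5), "contact_end")
})

test_that("empty event tables give a zero histogram", {
  ev <- binding_events(character(), integer(), integer(), integer(),
                       integer())
  expect_equal(as.numeric(binding_histogram(ev, 25)), rep(0, 25))
})

test_that("a noiseless empirical Gaussian is recovered to 0.1%", {
  mu <- 151.3; w <- 51.46
  x <- 1:500
  h <- 12 * exp(-((x - mu) / w)^2)
  fit <- fit_gaussian_peak(h, c(50, 320))
  expect_lt(abs(fit$mu - mu) / mu, 0.001)
  expect_lt(abs(fit$w - w) / w, 0.001)
  expect_equal(unname(coef(fit)[["amplitude"]]), 12, tolerance = 1e-3)
})

test_that("a symmetric histogram centers the fitted peak exactly", {
  h <- numeric(41)
  h[17:25] <- c(1, 2, 4, 7, 9, 7, 4, 2, 1)
  fit <- fit_gaussian_peak(h, c(10, 32))
  expect_equal(fit$mu, 21, tolerance = 1e-6)
})

test_that("peak fitting is translation-equivariant", {
  x <- 1:400
  set.seed(2)
  noise <- rnorm(400, 0, 0.05)
  base <- pmax(5 * exp(-((x - 120) / 30)^2) + noise, 0)
  f0 <- fit_gaussian_peak(base, c(60, 180))
  shifted <- c(numeric(50), base[1:350])
  f1 <- fit_gaussian_peak(shifted, c(110, 230))
  expect_equal(f1$mu - f0$mu, 50, tolerance = 1e-3)
  expect_equal(f1$w, f0$w, tolerance = 1e-6)
})

test_that("degenerate windows fail loudly", {
  expect_error(fit_gaussian_peak(rep(1, 50), c(10, 30)), "flat|mass")
  expect_error(fit_gaussian_peak(c(rep(0, 48), 1, 1), c(1, 50)),
               "fewer than 5")
})

test_that("confidence intervals cover the true center at nominal rate", {
  x <- 1:300
  mu <- 140; w <- 45
  cover <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    h <- with_seed(1000 + i,
                   rpois(300, 8 * exp(-((x - mu) / w)^2)))
    fit <- fit_gaussian_peak(h, c(40, 260))
    if (fit$mu_ci[1] <= mu && mu <= fit$mu_ci[2]) cover <- cover + 1L
  }
  expect_gte(cover / n_rep, 0.90)
})

test_that("bootstrap CIs widen appropriately for footprint-correlated bins", {
  sp <- generator_spec(seed = 55, n_molecules = 300, background_rate = 0)
  ds <- synth_binding_dataset(sp)
  h <- binding_histogram(ds$events, sp$substrate_length)
  plain <- fit_gaussian_peak(h, c(20, 330))
  boot <- fit_gaussian_peak(h, c(20, 330), events = ds$events, n_boot = 100,
                            seed = 3)
  expect_equal(boot$mu, plain$mu)
  # each protein paints ~78 correlated bp, so per-bin sandwich errors are
  # far too small; the protein-level bootstrap must be wider
  expect_gt(diff(boot$mu_ci), diff(plain$mu_ci))
  boot2 <- fit_gaussian_peak(h, c(20, 330), events = ds$events, n_boot = 100,
                             seed = 3)
  expect_identical(boot$mu_ci, boot2$mu_ci)
})

test_that("the dissociation-constant formulas match hand arithmetic", {
  expect_equal(overall_kd(0.5, 1, 50, 2.5), 47.5)
  expect_equal(overall_kd(1, 0, 50, 2.5), 0)
  expect_error(overall_kd(0, 1, 50, 2.5), "theta")
  expect_error(overall_kd(0.5, 30, 50, 2.5), "free")
  expect_equal(site_affinity(0.5, 10), 0.1)
  expect_error(site_affinity(1, 10), "theta_ss")
  expect_error(site_affinity(0.5, 0), "free")
})

test_that("site affinity is strictly increasing in occupancy", {
  th <- seq(0.05, 0.95, by = 0.1)
  ka <- vapply(th, site_affinity, numeric(1), free_protein = 25)
  expect_true(all(diff(ka) > 0))
})

test_that("overall and site estimators agree in the dilute single-site limit", {
  ka_true <- 0.02  # 1/nM, Kd = 50 nM
  free <- 30
  theta <- ka_true * free / (1 + ka_true * free)
  # one site per molecule, negligible DNA: n_bound = theta, protein0 ~ free
  kd_overall <- overall_kd(theta, theta, free, dna0 = 1e-9)
  expect_equal(kd_overall, 1 / ka_true, tolerance = 1e-6)
  expect_equal(site_affinity(theta, free), ka_true, tolerance = 1e-9)
})
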