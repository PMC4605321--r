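# Off-target pipeline: filtering, stability metrics, permutation
# correlation, and pipeline determinism.

make_record <- function(pair) {
  data.frame(guide_id = if (is.null(pair$id)) "g" else pair$id,
             guide_seq = pair$guide, target_seq = pair$protospacer,
             cutting_frequency = 0.5, stringsAsFactors = FALSE)
}

test_that("the distal single-mismatch filter keeps exactly the compliant records", {
  polyA <- guide_target_pair(strrep("A", 20), strrep("A", 20))
  recs <- rbind(
    make_record(inject_mismatch(polyA, 12, "rA.dA")),      # compliant
    make_record(inject_mismatch(polyA, 16, "rA.dA")),      # compliant
    make_record(inject_mismatch(polyA, 20, "rA.dA")),      # compliant
    make_record(polyA),                                    # no mismatch
    make_record(inject_mismatch(polyA, 5, "rA.dA")),       # PAM-proximal
    {r <- make_record(inject_mismatch(inject_mismatch(polyA, 12, "rA.dA"),
                                      17, "rA.dA")); r},   # two mismatches
    {p <- strrep("A", 20); substr(p, 7, 7) <- "G"          # rA.dC: other
     data.frame(guide_id = "other", guide_seq = strrep("A", 20),
                target_seq = p, cutting_frequency = 0.5)}
  )
  recs$guide_id <- paste0("r", seq_len(nrow(recs)))
  out <- filter_offtarget_set(recs)
  expect_identical(nrow(out), 3L)
  expect_setequal(out$mismatch_position, c(12L, 16L, 20L))
  rej <- attr(out, "rejections")
  expect_identical(unname(rej["multiple_or_no_mismatch"]), 2L)
  expect_identical(unname(rej["pam_proximal"]), 1L)
  expect_identical(unname(rej["unparameterized_type"]), 1L)
  expect_identical(nrow(filter_offtarget_set(recs[0, ])), 0L)
})

test_that("a frozen chain below threshold has exactly zero stability", {
  pair <- random_pair(5)
  st <- stability_metric(pair, m_star = 16, reps = 20, m0 = 10, max_t = 10,
                         k0 = 0, seed = 1)
  expect_identical(st$mean, 0)
  expect_identical(st$sem, 0)
})

test_that("the stability metric delegates to threshold occupancy", {
  pair <- random_pair(6)
  # under a shared seed, the single-replicate fast path consumes the same
  # RNG stream as the full trajectory, so the two computations must agree
  for (seed in c(10L, 20L)) {
    st <- stability_metric(pair, m_star = 16, reps = 1, m0 = 10, max_t = 50,
                           seed = seed)
    traj <- gillespie_run(rloop_system(pair), m0 = 10, max_t = 50,
                          boundary = "absorbing", seed = seed)
    expect_equal(st$mean, threshold_occupancy(traj, 16)$mean,
                 tolerance = 1e-12)
  }
})

test_that("a strongly penalized mismatch strictly lowers stability", {
  base <- guide_target_pair(strrep("G", 20), strrep("G", 20))
  mm <- inject_mismatch(base, 12, "rG.dG")
  s_base <- stability_metric(base, m_star = 16, reps = 300, seed = 2)
  s_mm <- stability_metric(mm, m_star = 16, reps = 300, seed = 2)
  expect_lt(s_mm$mean, s_base$mean)
})

test_that("perfect correlation attains the smallest smoothed p-value", {
  x <- c(0.1, 0.4, 0.5, 0.9, 0.95, 0.2, 0.7, 0.35)
  cc <- correlate_with_cleavage(x, x, n_perm = 200, seed = 1)
  expect_equal(cc$r, 1)
  expect_equal(cc$p_perm, 1 / 201)
})

test_that("exact permutation p-values match brute-force enumeration", {
  x <- c(0.2, 0.8, 0.4, 0.6)
  y <- c(1.1, 0.5, 2.0, 0.3)
  cc <- correlate_with_cleavage(x, y, exact = TRUE)
  perms <- oracle_perms(4L)
  r_all <- vapply(perms, function(p) stats::cor(x, y[p]), numeric(1))
  expect_identical(cc$n_perm, 24L)
  expect_equal(cc$p_perm, mean(abs(r_all) >= abs(stats::cor(x, y)) - 1e-12))
})

test_that("permutation p is invariant to affine rescaling of frequencies", {
  set.seed(9)
  x <- runif(12); y <- runif(12)
  a <- correlate_with_cleavage(x, y, n_perm = 500, seed = 3)
  b <- correlate_with_cleavage(x, 2.5 * y + 7, n_perm = 500, seed = 3)
  d <- correlate_with_cleavage(x, -1.5 * y + 2, n_perm = 500, seed = 3)
  expect_equal(a$p_perm, b$p_perm)
  expect_equal(a$p_perm, d$p_perm)
  expect_equal(a$r, b$r)
  expect_equal(a$r, -d$r)
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(correlate_with_cleavage(rep(1, 5), runif(5)), "variance")
  expect_error(correlate_with_cleavage(1:2, 1:2), "at least 3")
  expect_error(correlate_with_cleavage(1:5, 1:4), "length")
})

test_that("per-record seeds make metrics stable under dataset growth", {
  sp <- generator_spec(seed = 31, n_pairs = 6, truth_reps = 30)
  ds <- synth_cleavage_dataset(sp)
  small <- specificity_analysis(ds$records[1:4, ], reps = 50, n_perm = 99,
                                seed = 17)
  full <- specificity_analysis(ds$records, reps = 50, n_perm = 99,
                               seed = 17)
  expect_equal(small$records$stability,
               full$records$stability[1:4])
})

test_that("the full pipeline is reproducible bit-for-bit under one seed", {
  sp <- generator_spec(seed = 32, n_pairs = 8, truth_reps = 30)
  ds <- synth_cleavage_dataset(sp)
  f1 <- specificity_analysis(ds$records, reps = 80, n_perm = 199, seed = 23)
  f2 <- specificity_analysis(ds$records, reps = 80, n_perm = 199, seed = 23)
  expect_identical(f1$records$stability, f2$records$stability)
  expect_identical(f1$correlation$r, f2$correlation$r)
  expect_identical(f1$correlation$p_perm, f2$correlation$p_perm)
})

test_that("spearman correlation is available as an option", {
  set.seed(4)
  x <- runif(10); y <- x^3 + rnorm(10, 0, 0.01)
  cc <- correlate_with_cleavage(x, y, n_perm = 99, seed = 2,
                                method = "spearman")
  expect_equal(cc$r, stats::cor(x, y, method = "spearman"))
})
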