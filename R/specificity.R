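# Off-target specificity pipeline: dataset filtering, per-pair KMC stability
# metrics, and permutation-tested correlation with experimental cleavage
# frequencies.

#' Read a guide/target pair table
#'
#' Tab-separated file with a header row and '#' comment lines; columns
#' `guide_id`, `guide_seq`, `target_seq`, `cutting_frequency`. This is the
#' loader for externally published single-mismatch cleavage datasets (which
#' are not redistributed with the package) and for synthetic datasets from
#' [synth_cleavage_dataset()].
#'
#' @param path TSV path.
#' @return data frame of records.
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("guide_id", "guide_seq", "target_seq", "cutting_frequency")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("pair table missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Filter records to isolated PAM-distal single mismatches
#'
#' Keeps records whose guide/target alignment shows exactly one mismatch, at
#' a PAM-distal position (`>= distal_cutoff` from the PAM), of one of the
#' four parameterized types (rG.dG, rC.dC, rA.dA, rU.dT). Per-reason
#' rejection counts are attached as the `"rejections"` attribute.
#'
#' @param records data frame with `guide_seq`, `target_seq` columns (see
#'   [read_pairs_tsv()]).
#' @param distal_cutoff minimum mismatch position (default 10).
#' @return the compliant subset, with added columns `mismatch_position` and
#'   `mismatch_type`.
#' @export
filter_offtarget_set <- function(records, distal_cutoff = 10) {
  stopifnot(is.data.frame(records))
  reasons <- c(multiple_or_no_mismatch = 0L, pam_proximal = 0L,
               unparameterized_type = 0L)
  keep <- logical(nrow(records))
  pos <- integer(nrow(records)); typ <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    ann <- annotate_mismatches(records$guide_seq[i], records$target_seq[i])
    if (nrow(ann) != 1L) {
      reasons["multiple_or_no_mismatch"] <- reasons["multiple_or_no_mismatch"] + 1L
    } else if (ann$position < distal_cutoff) {
      reasons["pam_proximal"] <- reasons["pam_proximal"] + 1L
    } else if (!(ann$type %in% CANONICAL_MISMATCHES)) {
      reasons["unparameterized_type"] <- reasons["unparameterized_type"] + 1L
    } else {
      keep[i] <- TRUE
      pos[i] <- ann$position
      typ[i] <- ann$type
    }
  }
  out <- records[keep, , drop = FALSE]
  out$mismatch_position <- pos[keep]
  out$mismatch_type <- typ[keep]
  attr(out, "rejections") <- reasons
  out
}

#' Per-pair R-loop stability metric
#'
#' The mean fraction of simulation time the R-loop covers position `m_star`
#' or beyond, for strand invasion started at `m0` with the absorbing
#' dissociation boundary: replicated Gillespie runs reduced by
#' [threshold_occupancy()]. Defaults correspond to the invasion analysis of
#' single-mismatch off-target sites (`m0 = 10`, `m_star = 16`,
#' `reps = 1000`, `max_t = 100`).
#'
#' @param pair a [guide_target_pair()].
#' @param model an [energy_model()].
#' @param m_star threshold position.
#' @param reps number of replicate trajectories.
#' @param m0 initial R-loop length.
#' @param max_t censoring horizon (arbitrary units).
#' @param k0 rate prefactor.
#' @param seed optional integer seed.
#' @param boundary boundary condition at `m = 0`.
#' @return a `stability_estimate` (mean, SEM, replicate count).
#' @export
stability_metric <- function(pair, model = default_energy_model(),
                             m_star = 16, reps = 1000, m0 = 10, max_t = 100,
                             k0 = 1, seed = NULL,
                             boundary = c("absorbing", "reflecting")) {
  boundary <- match.arg(boundary)
  rates <- build_rate_table(pair, model, k0)
  stopifnot(m_star >= 0, m_star <= rates$n_positions)
  fr <- with_seed(seed, .kmc_threshold_reps_cpp(
    rates$v_f, rates$v_r, as.integer(m0), max_t, as.integer(m_star),
    boundary == "absorbing", as.integer(reps)))
  .stability_estimate(fr, m_star)
}

#' Permutation-tested correlation with cleavage frequencies
#'
#' Pearson (or Spearman) correlation between a stability metric vector and
#' experimental cleavage frequencies, with a two-sided permutation p-value:
#' the pairing is permuted `n_perm` times under a fixed seed and
#' `p = (1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)` (add-one smoothing, so
#' the attainable minimum is `1/(n_perm + 1)`). With `exact = TRUE` all `n!`
#' pairings are enumerated instead (only for small `n`) and the unsmoothed
#' exact p-value is returned.
#'
#' @param stability numeric vector of per-record stability metrics.
#' @param frequency numeric vector of cleavage frequencies, same length.
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutation stream.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param exact enumerate all pairings (requires `length(stability) <= 8`).
#' @return object of class `cleavage_correlation`: list with `r`, `p_perm`,
#'   `n`, `n_perm`, `method`, `exact`.
#' @export
correlate_with_cleavage <- function(stability, frequency, n_perm = 100000,
                                    seed = NULL,
                                    method = c("pearson", "spearman"),
                                    exact = FALSE) {
  method <- match.arg(method)
  x <- as.numeric(stability); y <- as.numeric(frequency)
  n <- length(x)
  if (length(y) != n) stop("stability and frequency differ in length")
  if (n < 3L) stop("need at least 3 paired records")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in stability or frequency vector")
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  r_obs <- sum(xs * ys) / (n - 1)
  tol <- 1e-12
  if (exact) {
    if (n > 8L) stop("exact enumeration limited to n <= 8")
    perms <- .permutations(n)
    r_perm <- vapply(perms, function(p) sum(xs * ys[p]) / (n - 1), numeric(1L))
    p <- mean(abs(r_perm) >= abs(r_obs) - tol)
    n_perm <- length(perms)
  } else {
    hits <- with_seed(seed, {
      h <- 0L
      for (b in seq_len(n_perm)) {
        r_b <- sum(xs * ys[sample.int(n)]) / (n - 1)
        if (abs(r_b) >= abs(r_obs) - tol) h <- h + 1L
      }
      h
    })
    p <- (1 + hits) / (1 + n_perm)
  }
  structure(list(r = r_obs, p_perm = p, n = n, n_perm = n_perm,
                 method = method, exact = exact),
            class = "cleavage_correlation")
}

# all permutations of 1..n (n small)
.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in sub) {
      k <- k + 1L
      q <- integer(n); q[i] <- n
      q[-i] <- p
      out[[k]] <- q
    }
  }
  out
}

#' @export
print.cleavage_correlation <- function(x, ...) {
  cat(sprintf(
    "%s correlation r = %.4f, permutation p = %.3g (n = %d, %s%d permutations)\n",
    x$method, x$r, x$p_perm, x$n, if (x$exact) "all " else "", x$n_perm))
  invisible(x)
}

#' Full specificity analysis
#'
#' Runs the off-target pipeline end to end: filters the records to isolated
#' PAM-distal single mismatches of the four parameterized types, computes the
#' per-record KMC stability metric (each record under a seed derived from the
#' master seed and the record index, so adding records never changes existing
#' metrics), and correlates stability with cleavage frequency by permutation
#' test.
#'
#' @param records data frame from [read_pairs_tsv()] or
#'   [synth_cleavage_dataset()].
#' @param model an [energy_model()].
#' @param m_star,reps,m0,max_t,k0 KMC settings, see [stability_metric()].
#' @param n_perm,method permutation-test settings, see
#'   [correlate_with_cleavage()].
#' @param seed master seed for the whole pipeline.
#' @param distal_cutoff PAM-distal filter cutoff.
#' @param transform optional function applied to cleavage frequencies before
#'   correlation (default identity).
#' @return object of class `specificity_fit`: list with the filtered
#'   `records` table (plus `stability`, `stability_sem` columns), the
#'   `correlation`, filter `rejections` and the `settings` used.
#' @export
specificity_analysis <- function(records, model = default_energy_model(),
                                 m_star = 16, reps = 1000, m0 = 10,
                                 max_t = 100, k0 = 1, n_perm = 100000,
                                 seed = 1, distal_cutoff = 10,
                                 method = "pearson", transform = identity) {
  filtered <- filter_offtarget_set(records, distal_cutoff)
  if (nrow(filtered) < 3L) {
    stop("fewer than 3 records survive filtering; cannot correlate")
  }
  est <- lapply(seq_len(nrow(filtered)), function(i) {
    pair <- guide_target_pair(filtered$guide_seq[i], filtered$target_seq[i],
                              id = filtered$guide_id[i])
    stability_metric(pair, model, m_star = m_star, reps = reps, m0 = m0,
                     max_t = max_t, k0 = k0,
                     seed = derive_seed(seed, i))
  })
  filtered$stability <- vapply(est, `[[`, numeric(1L), "mean")
  filtered$stability_sem <- vapply(est, `[[`, numeric(1L), "sem")
  corr <- correlate_with_cleavage(filtered$stability,
                                  transform(filtered$cutting_frequency),
                                  n_perm = n_perm,
                                  seed = derive_seed(seed, 0L),
                                  method = method)
  structure(list(records = filtered, correlation = corr,
                 rejections = attr(filtered, "rejections"),
                 settings = list(m_star = m_star, reps = reps, m0 = m0,
                                 max_t = max_t, k0 = k0, n_perm = n_perm,
                                 seed = seed, distal_cutoff = distal_cutoff,
                                 method = method)),
            class = "specificity_fit")
}

#' @export
print.specificity_fit <- function(x, ...) {
  cat(sprintf("Specificity analysis: %d records after filtering\n",
              nrow(x$records)))
  cat(sprintf("  rejections: %s\n",
              paste(names(x$rejections), x$rejections, sep = "=",
                    collapse = ", ")))
  cat(sprintf("  KMC: m0 = %d, m_star = %d, reps = %d, max_t = %g\n",
              x$settings$m0, x$settings$m_star, x$settings$reps,
              x$settings$max_t))
  cat("  ")
  print(x$correlation)
  invisible(x)
}
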