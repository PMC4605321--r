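# Synthetic-data generators. Every generator is deterministic under
# (spec, seed) and writes ground truth separately from observations, so the
# pipeline can be validated against known answers without experimental input.

#' Generator specification
#'
#' Bundles the knobs of the synthetic-data generators with their defaults,
#' which describe the emulated study conditions: 20-nt guides at balanced GC,
#' single injected PAM-distal mismatches, cleavage frequencies that follow a
#' noisy logistic function of simulated R-loop stability, and binding-event
#' tables with Gaussian position noise in the tens-of-bp range typical of
#' single-molecule footprint mapping.
#'
#' @param seed master RNG seed.
#' @param n_pairs number of guide/target records.
#' @param guide_length guide length in nt (default 20).
#' @param gc_fraction expected GC content of generated guides.
#' @param mismatch_positions candidate positions for the injected single
#'   mismatch (default PAM-distal, 10..guide_length).
#' @param link `"logistic"` (expected frequency
#'   `plogis(intercept + slope * s)`) or `"identity"`
#'   (`intercept + slope * s`); slope 0 makes the true association null.
#' @param link_intercept,link_slope parameters of the stability -> frequency
#'   link.
#' @param noise_sd Gaussian noise added to the expected frequency (truncated
#'   at 0, which slightly biases the null upward near 0).
#' @param truth_reps,m_star,m0,max_t KMC settings used to compute the
#'   generator's own (ground-truth) stability.
#' @param substrate_length binding substrate length (bp).
#' @param sites data frame of binding sites: columns `name`, `center` (bp),
#'   `ka` (true association constant, 1/nM).
#' @param sigma_bp apparent peak standard deviation of the binding
#'   histogram, in bp; the emulated peak-width parameter is
#'   `w = sqrt(2) * sigma_bp`. Because each footprint smears its weight over
#'   `footprint_bp` consecutive bp, footprint centers are drawn with a
#'   smaller position noise, calibrated numerically so that the empirical
#'   Gaussian fitted to the noiseless site profile returns exactly
#'   `w = sqrt(2) * sigma_bp` (this requires `sigma_bp` to exceed the width
#'   floor set by the footprint itself).
#' @param footprint_bp apparent protein footprint length (bp).
#' @param background_rate mean number of non-specific background proteins
#'   per DNA molecule (Poisson).
#' @param n_molecules number of DNA molecules imaged.
#' @param protein0,dna0 incubation concentrations (nM).
#' @return list of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1, n_pairs = 60, guide_length = 20,
                           gc_fraction = 0.5,
                           mismatch_positions = 10:guide_length,
                           link = c("logistic", "identity"),
                           link_intercept = -2, link_slope = 6,
                           noise_sd = 0.1,
                           truth_reps = 300, m_star = 16, m0 = 10,
                           max_t = 100,
                           substrate_length = 989,
                           sites = data.frame(name = "full_site",
                                              center = 151.3,
                                              ka = 1 / 44.67),
                           sigma_bp = 36.4, footprint_bp = 78,
                           background_rate = 0.2, n_molecules = 500,
                           protein0 = 50, dna0 = 2.5) {
  link <- match.arg(link)
  stopifnot(sigma_bp > 0, gc_fraction >= 0, gc_fraction <= 1,
            n_pairs >= 1, guide_length >= 2,
            all(mismatch_positions >= 1),
            all(mismatch_positions <= guide_length))
  structure(as.list(environment()), class = "generator_spec")
}

#' Generate a perfectly complementary guide/target pair
#'
#' Draws a uniformly random guide at the requested GC fraction; the
#' protospacer is its exact DNA counterpart on the guide-matching strand and
#' a legal NGG PAM is appended. Deterministic under `(spec$seed, index)`.
#'
#' @param spec a [generator_spec()].
#' @param index record index (drives the derived seed).
#' @return a [guide_target_pair()] with zero mismatches.
#' @export
make_pair <- function(spec, index = 1L) {
  with_seed(derive_seed(spec$seed, 1000000 + index), {
    p_gc <- spec$gc_fraction
    probs <- c(A = (1 - p_gc) / 2, C = p_gc / 2, G = p_gc / 2,
               U = (1 - p_gc) / 2)
    g <- paste(sample(names(probs), spec$guide_length, replace = TRUE,
                      prob = probs), collapse = "")
    pam <- paste0(sample(c("A", "C", "G", "T"), 1L), "GG")
    guide_target_pair(g, rna_to_dna(g), pam = pam,
                      id = sprintf("synth_%04d", index))
  })
}

#' Inject a single mismatch into a pair
#'
#' Substitutes the target-strand base at `position` so the guide base faces
#' the identical base (rG.dG, rC.dC, rA.dA or rU.dT). The requested type must
#' be achievable given the guide base at that position, and the position must
#' currently be matched.
#'
#' @param pair a [guide_target_pair()].
#' @param position protospacer position (from the PAM).
#' @param type one of `"rG.dG"`, `"rC.dC"`, `"rA.dA"`, `"rU.dT"`.
#' @return the modified pair (exactly one annotated mismatch at `position`).
#' @export
inject_mismatch <- function(pair, position, type) {
  stopifnot(inherits(pair, "guide_target_pair"),
            position >= 1, position <= pair$N)
  if (!(type %in% CANONICAL_MISMATCHES)) {
    stop("unknown mismatch type: ", type)
  }
  if (position %in% pair$mismatches$position) {
    stop(sprintf("position %d is already mismatched", position))
  }
  g <- .guide_base(pair, position)
  need_guide <- sub("^r(.).*$", "\\1", type)        # rX.dY -> X
  target_base <- sub("^.*d(.)$", "\\1", type)       # rX.dY -> Y
  if (g != need_guide) {
    stop(sprintf("mismatch %s unachievable at position %d: guide base is %s",
                 type, position, g))
  }
  # protospacer stores the guide-matching strand; the target strand carries
  # target_base, so the stored letter becomes its complement
  idx <- pair$L + 1L - position
  proto <- pair$protospacer
  substr(proto, idx, idx) <- dna_complement(target_base)
  guide_target_pair(pair$guide, proto, pam = pair$pam, id = pair$id)
}

# the one canonical mismatch type achievable for a given guide base
.type_for_guide_base <- function(g) {
  c(A = "rA.dA", C = "rC.dC", G = "rG.dG", U = "rU.dT")[[g]]
}

#' Synthetic single-mismatch cleavage dataset
#'
#' For each record, draws a random pair, injects one isolated PAM-distal
#' mismatch (the canonical type dictated by the guide base at a randomly
#' chosen allowed position), computes the generator's own ground-truth
#' stability metric under a dedicated seed stream, and draws the observed
#' cleavage frequency as `plogis(intercept + slope * stability)` plus
#' truncated Gaussian noise.
#'
#' @param spec a [generator_spec()].
#' @param model an [energy_model()] used for the ground-truth KMC.
#' @return list with `records` (guide_id, guide_seq, target_seq,
#'   cutting_frequency -- the pipeline input) and `truth` (adds
#'   `true_stability`, `expected_frequency`, `mismatch_position`,
#'   `mismatch_type`).
#' @export
synth_cleavage_dataset <- function(spec, model = default_energy_model()) {
  n <- spec$n_pairs
  guide_id <- character(n); guide_seq <- character(n)
  target_seq <- character(n); freq <- numeric(n)
  true_stab <- numeric(n); efreq <- numeric(n)
  mpos <- integer(n); mtyp <- character(n)
  for (i in seq_len(n)) {
    pair <- make_pair(spec, i)
    pos <- with_seed(derive_seed(spec$seed, 2000000 + i),
                     sample(spec$mismatch_positions, 1L))
    type <- .type_for_guide_base(.guide_base(pair, pos))
    pair <- inject_mismatch(pair, pos, type)
    st <- stability_metric(pair, model, m_star = spec$m_star,
                           reps = spec$truth_reps, m0 = spec$m0,
                           max_t = spec$max_t,
                           seed = derive_seed(spec$seed, 3000000 + i))
    eta <- spec$link_intercept + spec$link_slope * st$mean
    mu <- if (spec$link == "identity") eta else stats::plogis(eta)
    f <- with_seed(derive_seed(spec$seed, 4000000 + i),
                   max(0, mu + stats::rnorm(1L, 0, spec$noise_sd)))
    guide_id[i] <- pair$id; guide_seq[i] <- pair$guide
    target_seq[i] <- pair$protospacer; freq[i] <- f
    true_stab[i] <- st$mean; efreq[i] <- mu; mpos[i] <- pos; mtyp[i] <- type
  }
  records <- data.frame(guide_id = guide_id, guide_seq = guide_seq,
                        target_seq = target_seq, cutting_frequency = freq,
                        stringsAsFactors = FALSE)
  truth <- cbind(records,
                 data.frame(true_stability = true_stab,
                            expected_frequency = efreq,
                            mismatch_position = mpos, mismatch_type = mtyp,
                            stringsAsFactors = FALSE))
  list(records = records, truth = truth)
}

#' Synthetic single-molecule binding dataset
#'
#' Emulates footprint observations on a linear substrate: per DNA molecule,
#' each annotated site is occupied with the single-site isotherm probability
#' `theta = Ka * free / (1 + Ka * free)` (free protein solved
#' self-consistently against depletion by binding), occupied sites produce a
#' footprint whose center is Gaussian-displaced with standard deviation
#' `sigma_bp`, and a Poisson number of background proteins bind uniformly.
#' All footprints are single-contact (`k = 1`).
#'
#' @param spec a [generator_spec()].
#' @return list with `events` (a `binding_events` table), `truth` (per-site
#'   true occupancy fractions, free protein, and the spec's Kd), and
#'   `summary` (theta, mean proteins per molecule).
#' @export
synth_binding_dataset <- function(spec) {
  with_seed(derive_seed(spec$seed, 5000000), {
    n_mol <- spec$n_molecules
    sites <- spec$sites
    # self-consistent free protein: free = protein0 - n_bound_mean * dna0
    free <- spec$protein0
    for (it in 1:50) {
      theta_s <- sites$ka * free / (1 + sites$ka * free)
      n_mean <- sum(theta_s) + spec$background_rate
      free_new <- max(spec$protein0 - n_mean * spec$dna0, 1e-9)
      if (abs(free_new - free) < 1e-12) break
      free <- free_new
    }
    theta_s <- sites$ka * free / (1 + sites$ka * free)
    half <- floor(spec$footprint_bp / 2)
    sd_pos <- .calibrate_position_noise(spec$sigma_bp, spec$footprint_bp)
    rows <- list()
    occ_count <- numeric(nrow(sites))
    for (mol in seq_len(n_mol)) {
      id <- sprintf("mol_%05d", mol)
      for (s in seq_len(nrow(sites))) {
        if (stats::runif(1L) < theta_s[s]) {
          occ_count[s] <- occ_count[s] + 1
          center <- round(sites$center[s] + stats::rnorm(1L, 0, sd_pos))
          lo <- max(1L, center - half)
          hi <- min(spec$substrate_length, center + half)
          if (lo <= hi) rows[[length(rows) + 1L]] <- c(id, lo, hi)
        }
      }
      nbg <- stats::rpois(1L, spec$background_rate)
      for (b in seq_len(nbg)) {
        center <- sample.int(spec$substrate_length, 1L)
        lo <- max(1L, center - half)
        hi <- min(spec$substrate_length, center + half)
        rows[[length(rows) + 1L]] <- c(id, lo, hi)
      }
    }
    m <- do.call(rbind, rows)
    events <- binding_events(dna_id = m[, 1L],
                             contact_start = as.integer(m[, 2L]),
                             contact_end = as.integer(m[, 3L]))
    n_per_mol <- table(factor(events$dna_id,
                              levels = sprintf("mol_%05d", seq_len(n_mol))))
    truth <- data.frame(site = sites$name, center = sites$center,
                        ka = sites$ka, kd = 1 / sites$ka,
                        theta_true = theta_s,
                        theta_observed = occ_count / n_mol,
                        free_protein = free, stringsAsFactors = FALSE)
    list(events = events, truth = truth,
         summary = list(theta = mean(n_per_mol > 0),
                        n_bound = mean(n_per_mol),
                        n_molecules = n_mol,
                        protein0 = spec$protein0, dna0 = spec$dna0))
  })
}

# Solve for the footprint-center noise sd such that the least-squares
# empirical Gaussian fitted to the noiseless box-convolved site profile has
# width parameter exactly sqrt(2) * sigma_bp.
.calibrate_position_noise <- function(sigma_bp, footprint_bp) {
  target_w <- sqrt(2) * sigma_bp
  fitted_w <- function(s) {
    dx <- min(1, sigma_bp / 10)
    span <- 4 * sigma_bp + footprint_bp
    x <- seq(-span, span, by = dx)
    y <- stats::pnorm((x + footprint_bp / 2) / s) -
      stats::pnorm((x - footprint_bp / 2) / s)
    sse <- function(p) sum((y - p[1] * exp(-((x - p[2]) / p[3])^2))^2)
    fit <- stats::optim(c(max(y), 0, target_w), sse, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    abs(fit$par[3])
  }
  lo <- sigma_bp / 20; hi <- 1.5 * sigma_bp
  if (fitted_w(lo) >= target_w) {
    stop("sigma_bp is below the apparent-width floor set by footprint_bp")
  }
  stats::uniroot(function(s) fitted_w(s) - target_w, c(lo, hi),
                 tol = 1e-3 * sigma_bp)$root
}

#' Write a synthetic cleavage dataset to TSV (+ FASTA)
#'
#' Observations and ground truth go to separate files so pipeline inputs can
#' never leak truth.
#'
#' @param ds result of [synth_cleavage_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cleavage_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(records = file.path(dir, "pairs.tsv"),
             truth = file.path(dir, "pairs_truth.tsv"),
             fasta = file.path(dir, "guides.fa"))
  utils::write.table(ds$records, paths["records"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(as.vector(rbind(paste0(">", ds$records$guide_id),
                             ds$records$guide_seq)), paths["fasta"])
  invisible(paths)
}
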