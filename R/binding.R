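# Single-molecule binding statistics: 1/k-weighted per-bp binding histograms,
# empirical Gaussian peak fits, and occupancy -> dissociation/association
# constant estimators. Coordinates are 1-based inclusive bp intervals
# measured from the labelled end of the substrate.

#' Build a binding-event table
#'
#' @param dna_id molecule identifiers (one row per protein-DNA contact).
#' @param contact_start,contact_end 1-based inclusive bp interval of each
#'   contact.
#' @param contact_index index of the contact within its protein (1..k).
#' @param n_contacts number of contacts `k` of the protein the row belongs
#'   to; each contact carries weight `1/k` so a protein's weights sum to 1.
#' @return data frame of class `binding_events`.
#' @export
binding_events <- function(dna_id, contact_start, contact_end,
                           contact_index = 1L,
                           n_contacts = 1L) {
  df <- data.frame(dna_id = dna_id,
                   contact_start = as.integer(contact_start),
                   contact_end = as.integer(contact_end),
                   contact_index = as.integer(contact_index),
                   n_contacts = as.integer(n_contacts),
                   stringsAsFactors = FALSE)
  if (any(df$contact_end < df$contact_start)) {
    stop("contact_end < contact_start")
  }
  if (any(df$contact_index < 1L | df$contact_index > df$n_contacts)) {
    stop("contact_index outside 1..n_contacts")
  }
  class(df) <- c("binding_events", "data.frame")
  df
}

#' Read a binding-event TSV
#'
#' Columns `dna_id`, `contact_start`, `contact_end`, `contact_index`,
#' `n_contacts`; one row per contact, rows of a multi-contact protein grouped
#' by `contact_index = 1..k`.
#'
#' @param path TSV path.
#' @return `binding_events` data frame.
#' @export
read_binding_events <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  do.call(binding_events, df[c("dna_id", "contact_start", "contact_end",
                               "contact_index", "n_contacts")])
}

#' 1/k-weighted binding histogram
#'
#' Maps each bound protein to the bp it overlaps: every bp covered by a
#' contact is incremented by the contact's weight `1/k`, where `k` is the
#' number of distinct sites the protein appears to touch. The number of
#' proteins (the sum of per-protein weights) is attached as attribute
#' `protein_mass`.
#'
#' @param events a `binding_events` data frame.
#' @param substrate_length substrate length in bp.
#' @return numeric vector of per-bp weighted occupancy (length
#'   `substrate_length`).
#' @export
binding_histogram <- function(events, substrate_length) {
  stopifnot(is.data.frame(events), substrate_length >= 1)
  h <- numeric(substrate_length)
  for (i in seq_len(nrow(events))) {
    s <- events$contact_start[i]; e <- events$contact_end[i]
    if (s < 1L || e > substrate_length) {
      stop(sprintf(
        "contact %d of molecule %s spans %d-%d, outside substrate 1-%d",
        events$contact_index[i], as.character(events$dna_id[i]), s, e,
        substrate_length))
    }
    h[s:e] <- h[s:e] + 1 / events$n_contacts[i]
  }
  attr(h, "protein_mass") <- sum(1 / events$n_contacts)
  h
}

#' Fit an empirical Gaussian to a binding-histogram peak
#'
#' Least-squares fit of `A * exp(-((x - mu)/w)^2)` to the histogram within a
#' window. `mu` is the peak center and `w` the width parameter
#' (`w = sqrt(2) * sigma`); the amplitude `A` is a free nuisance parameter.
#' 95% confidence intervals come from a heteroscedasticity-consistent
#' (sandwich) covariance estimate, since count histograms have variance that
#' scales with their local mean.
#'
#' @param histogram per-bp occupancy vector (see [binding_histogram()]).
#' @param window integer vector of bp positions to fit over (e.g.
#'   `140:360`), or `c(lo, hi)` bounds.
#' @param baseline also fit a constant background level `b`
#'   (`A*exp(...) + b`); use when the window carries appreciable
#'   non-specific binding.
#' @param events optional `binding_events` table the histogram was built
#'   from. When supplied together with `n_boot > 0`, confidence intervals
#'   come from a protein-resampling bootstrap instead of the sandwich
#'   formula -- the right choice for real binding histograms, whose adjacent
#'   bp are correlated because every protein covers a whole footprint.
#' @param substrate_length substrate length used to rebuild bootstrap
#'   histograms (defaults to `length(histogram)`).
#' @param n_boot number of bootstrap resamples (0 = sandwich CIs).
#' @param seed seed for the bootstrap resampling.
#' @return object of class `peak_fit`: `mu`, `w`, `amplitude` (and `baseline`
#'   when requested), `mu_ci`, `w_ci`, `window`, and the underlying
#'   `nls`-style fit.
#' @export
fit_gaussian_peak <- function(histogram, window, baseline = FALSE,
                              events = NULL,
                              substrate_length = length(histogram),
                              n_boot = 0, seed = NULL) {
  if (length(window) == 2L && diff(window) > 1) window <- window[1L]:window[2L]
  window <- as.integer(window)
  stopifnot(all(window >= 1L), all(window <= length(histogram)))
  y <- histogram[window]; x <- as.numeric(window)
  if (sum(y > 0) < 5L) stop("window contains fewer than 5 bins with mass")
  if (stats::sd(y) == 0) stop("degenerate (flat) window; cannot fit a peak")
  cf <- .fit_peak_ls(x, y, baseline)
  if (!is.null(events) && n_boot > 0) {
    blocks <- split(seq_len(nrow(events)),
                    cumsum(events$contact_index == 1L))
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        take <- sample.int(length(blocks), replace = TRUE)
        ev_b <- events[unlist(blocks[take]), , drop = FALSE]
        h_b <- binding_histogram(ev_b, substrate_length)
        tryCatch({
          co_b <- attr(.fit_peak_ls(x, h_b[window], baseline), "coef")
          c(co_b[["mu"]], abs(co_b[["w"]]))
        }, error = function(e) c(NA_real_, NA_real_))
      }, numeric(2L))
    })
    mu_ci <- unname(stats::quantile(boot[1L, ], c(0.025, 0.975),
                                    na.rm = TRUE))
    w_ci <- unname(stats::quantile(boot[2L, ], c(0.025, 0.975),
                                   na.rm = TRUE))
  } else {
    se <- .sandwich_se(attr(cf, "coef"), x, y, baseline)
    z <- stats::qnorm(0.975)
    mu_ci <- unname(attr(cf, "coef")[["mu"]] + c(-1, 1) * z * se[["mu"]])
    w_ci <- unname(abs(attr(cf, "coef")[["w"]]) + c(-1, 1) * z * se[["w"]])
  }
  co <- attr(cf, "coef")
  structure(list(mu = co[["mu"]], w = abs(co[["w"]]),
                 amplitude = co[["A"]],
                 baseline = if (baseline) co[["b"]] else NULL,
                 mu_ci = mu_ci, w_ci = w_ci,
                 window = range(window), fit = cf),
            class = "peak_fit")
}

# least-squares empirical-Gaussian fit; returns the nls fit with a "coef"
# attribute
.fit_peak_ls <- function(x, y, baseline = FALSE) {
  mu0 <- sum(x * pmax(y, 0)) / sum(pmax(y, 0))
  s0 <- sqrt(max(sum(pmax(y, 0) * (x - mu0)^2) / sum(pmax(y, 0)), 1))
  fit <- tryCatch({
    if (baseline) {
      minpack.lm::nlsLM(y ~ A * exp(-((x - mu) / w)^2) + b,
                        start = list(A = max(y), mu = mu0,
                                     w = sqrt(2) * s0, b = 0),
                        lower = c(A = 0, mu = min(x), w = 1e-6, b = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ A * exp(-((x - mu) / w)^2),
                        start = list(A = max(y), mu = mu0, w = sqrt(2) * s0),
                        lower = c(A = 0, mu = min(x), w = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) stop("Gaussian peak fit failed: ",
                              conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  if (!baseline) cf <- c(cf, b = 0)
  attr(fit, "coef") <- as.list(cf)
  fit
}

# heteroscedasticity-consistent standard errors for the empirical-Gaussian
# fit: V = (J'J)^-1 J' diag(r^2) J (J'J)^-1 with the analytic Jacobian
.sandwich_se <- function(cf, x, y, baseline = FALSE) {
  A <- cf[["A"]]; mu <- cf[["mu"]]; w <- cf[["w"]]; b <- cf[["b"]]
  e <- exp(-((x - mu) / w)^2)
  J <- cbind(A = e,
             mu = A * e * 2 * (x - mu) / w^2,
             w = A * e * 2 * (x - mu)^2 / w^3)
  if (baseline) J <- cbind(J, b = rep(1, length(x)))
  r <- y - A * e - b
  B <- solve(crossprod(J))
  V <- B %*% crossprod(J, J * r^2) %*% B
  stats::setNames(sqrt(diag(V)), colnames(J))
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian peak fit over bp %d-%d:\n  mu = %.1f bp (95%% CI %.1f-%.1f)\n  w  = %.2f bp (95%% CI %.2f-%.2f) [w = sqrt(2)*sigma]\n",
    x$window[1L], x$window[2L], x$mu, x$mu_ci[1L], x$mu_ci[2L],
    x$w, x$w_ci[1L], x$w_ci[2L]))
  invisible(x)
}

#' @method coef peak_fit
#' @export
coef.peak_fit <- function(object, ...) {
  c(amplitude = object$amplitude, mu = object$mu, w = object$w)
}

#' @method confint peak_fit
#' @export
confint.peak_fit <- function(object, parm = c("mu", "w"), level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  out <- rbind(mu = object$mu_ci, w = object$w_ci)[parm, , drop = FALSE]
  colnames(out) <- c("2.5 %", "97.5 %")
  out
}

#' @method plot peak_fit
#' @export
plot.peak_fit <- function(x, histogram = NULL, ...) {
  xs <- seq(x$window[1L], x$window[2L], length.out = 200)
  ys <- x$amplitude * exp(-((xs - x$mu) / x$w)^2)
  if (!is.null(histogram)) {
    graphics::plot(seq_along(histogram), histogram, type = "h",
                   xlab = "bp from labelled end", ylab = "weighted occupancy",
                   ...)
    graphics::lines(xs, ys, lwd = 2)
  } else {
    graphics::plot(xs, ys, type = "l", xlab = "bp from labelled end",
                   ylab = "fitted occupancy", ...)
  }
  invisible(x)
}

#' Overall apparent dissociation constant
#'
#' `Kd = (1 - theta) * (protein0 - n_bound * dna0) / theta`, from the
#' fraction of DNA molecules carrying at least one protein (`theta`), the
#' mean number of proteins bound per DNA molecule (`n_bound`, averaged over
#' all molecules), and the incubation concentrations. The same routine serves
#' the site-restricted Kd when the caller supplies a `theta` restricted to
#' molecules bound within one peak width of a site.
#'
#' @param theta fraction of DNA molecules bound, in `(0, 1]`.
#' @param n_bound mean proteins per DNA molecule.
#' @param protein0 total protein concentration (nM).
#' @param dna0 total DNA concentration (nM).
#' @return Kd in nM.
#' @export
overall_kd <- function(theta, n_bound, protein0, dna0) {
  if (!(theta > 0 && theta <= 1)) stop("theta must lie in (0, 1]")
  free <- protein0 - n_bound * dna0
  if (free <= 0) stop("free-protein concentration is non-positive")
  (1 - theta) * free / theta
}

#' Site-specific association constant
#'
#' `Ka = 1/Kd_site` with `Kd_site = (1 - theta_ss) * free / theta_ss`, from
#' the fraction of a specific site occupied by protein and the free protein
#' concentration.
#'
#' @param theta_ss site occupancy fraction, strictly in `(0, 1)`.
#' @param free_protein free protein concentration (nM).
#' @return Ka in 1/nM.
#' @export
site_affinity <- function(theta_ss, free_protein) {
  if (!(theta_ss > 0 && theta_ss < 1)) stop("theta_ss must lie strictly in (0, 1)")
  if (free_protein <= 0) stop("free_protein must be positive")
  theta_ss / ((1 - theta_ss) * free_protein)
}
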