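# Nearest-neighbour free-energy model: Watson-Crick DNA:DNA and RNA:DNA
# doublet tables, a synthetic per-type mismatch offset table, the duplex
# initiation term and the thermal scale RT. All energies are dG37 in kcal/mol;
# more negative = more stable.

#' Construct a nearest-neighbour energy model
#'
#' @param dna_dna named numeric vector of DNA:DNA doublet free energies
#'   (kcal/mol), keyed `"XY/ZW"` with the top strand 5'->3'; the 10 unique
#'   Watson-Crick doublets must be reachable (reverse-complement orientations
#'   are resolved automatically).
#' @param rna_dna named numeric vector of RNA:DNA hybrid doublet free
#'   energies, keyed by the RNA strand 5'->3' (e.g. `"GU/CA"`); all 16
#'   doublets required.
#' @param mismatch_offsets named numeric vector of destabilization offsets
#'   (kcal/mol) per mismatch type (`"rG.dG"`, `"rC.dC"`, `"rA.dA"`,
#'   `"rU.dT"`), added to the Watson-Crick hybrid stack of the guide doublet
#'   for each stack flanking a mismatched position.
#' @param dg_init duplex initiation term (kcal/mol) added to whole-duplex
#'   hybrid binding energies. Default -3.1. Note the published hybrid
#'   initiation term has the opposite sign (+3.1, a penalty); the default
#'   follows the strand-invasion model's printed convention and can be
#'   overridden.
#' @param temperature_K temperature in Kelvin (default 310.15, i.e. 37 C).
#' @param R_kcal gas constant in kcal mol^-1 K^-1.
#' @param salt_label free-text provenance tag for the parameter set.
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(dna_dna, rna_dna, mismatch_offsets = numeric(),
                         dg_init = -3.1, temperature_K = 310.15,
                         R_kcal = 1.987e-3, salt_label = "1 M NaCl") {
  stopifnot(is.numeric(dna_dna), !is.null(names(dna_dna)),
            is.numeric(rna_dna), !is.null(names(rna_dna)),
            is.numeric(dg_init), length(dg_init) == 1L,
            temperature_K > 0, R_kcal > 0)
  dd <- .top_strand_table(dna_dna)
  rd <- .top_strand_table(rna_dna)
  if (any(!is.finite(dd)) || any(!is.finite(rd)) || !is.finite(dg_init)) {
    stop("all free energies must be finite")
  }
  # completeness: 16 DNA doublets via reverse-complement identification,
  # 16 RNA doublets directly
  dna_keys <- as.vector(outer(DNA_ALPHABET, DNA_ALPHABET, paste0))
  miss <- dna_keys[vapply(dna_keys, function(k) {
    !(k %in% names(dd)) && !(dna_revcomp(k) %in% names(dd))
  }, logical(1L))]
  if (length(miss) > 0L) {
    stop("DNA:DNA table missing doublet(s): ", paste(miss, collapse = ", "))
  }
  rna_keys <- as.vector(outer(RNA_ALPHABET, RNA_ALPHABET, paste0))
  miss <- setdiff(rna_keys, names(rd))
  if (length(miss) > 0L) {
    stop("RNA:DNA table missing doublet(s): ", paste(miss, collapse = ", "))
  }
  if (length(mismatch_offsets) > 0L) {
    stopifnot(is.numeric(mismatch_offsets), !is.null(names(mismatch_offsets)))
  }
  structure(
    list(dna_dna = dd, rna_dna = rd,
         mismatch_offsets = mismatch_offsets,
         dg_init = dg_init, T = temperature_K, R = R_kcal,
         salt_label = salt_label),
    class = "energy_model")
}

# strip an optional "/bottom-strand" part from table keys: "AA/TT" -> "AA"
.top_strand_table <- function(x) {
  nm <- sub("/.*$", "", names(x))
  stats::setNames(as.numeric(x), nm)
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Nearest-neighbour energy model (dG37, kcal/mol)\n")
  cat(sprintf("  DNA:DNA doublets: %d   RNA:DNA doublets: %d\n",
              length(x$dna_dna), length(x$rna_dna)))
  cat(sprintf("  mismatch types parameterized: %s\n",
              if (length(x$mismatch_offsets)) {
                paste(names(x$mismatch_offsets), collapse = ", ")
              } else "none"))
  cat(sprintf("  dg_init = %.2f kcal/mol, T = %.2f K (%s), RT = %.4f kcal/mol\n",
              x$dg_init, x$T, x$salt_label, x$R * x$T))
  invisible(x)
}

#' Load the default transcribed parameter set
#'
#' Reads the Watson-Crick doublet tables shipped in
#' `inst/extdata/nn_dg37.json` (unified DNA:DNA and Sugimoto RNA:DNA hybrid
#' parameters, 1 M NaCl, 37 C) and the synthetic mismatch offsets in
#' `inst/extdata/mismatch_offsets_synthetic.json`.
#'
#' @return an `energy_model`.
#' @export
default_energy_model <- function() {
  read_energy_model(
    system.file("extdata", "nn_dg37.json", package = "rloopkmc",
                mustWork = TRUE),
    system.file("extdata", "mismatch_offsets_synthetic.json",
                package = "rloopkmc", mustWork = TRUE))
}

#' Read an energy model from JSON configuration
#'
#' @param path JSON file with fields `dna_dna`, `rna_dna`, `dg_init`,
#'   `temperature_K` and optionally `R_kcal`, `salt_label`,
#'   `mismatch_offsets`.
#' @param mismatch_path optional second JSON carrying `mismatch_offsets`.
#' @return an `energy_model`.
#' @export
read_energy_model <- function(path, mismatch_path = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  mm <- cfg$mismatch_offsets
  if (!is.null(mismatch_path)) {
    mm <- jsonlite::read_json(mismatch_path,
                              simplifyVector = TRUE)$mismatch_offsets
  }
  if (is.null(mm)) mm <- numeric()
  energy_model(
    dna_dna = unlist(cfg$dna_dna), rna_dna = unlist(cfg$rna_dna),
    mismatch_offsets = unlist(mm),
    dg_init = if (is.null(cfg$dg_init)) -3.1 else cfg$dg_init,
    temperature_K = if (is.null(cfg$temperature_K)) 310.15 else cfg$temperature_K,
    R_kcal = if (is.null(cfg$R_kcal)) 1.987e-3 else cfg$R_kcal,
    salt_label = if (is.null(cfg$salt_label)) "" else cfg$salt_label)
}

# --- doublet lookups ---------------------------------------------------------

# DNA:DNA stack for a 5'->3' top-strand doublet, resolving via the
# reverse-complement orientation when needed.
dna_stack <- function(model, doublet) {
  v <- model$dna_dna[doublet]
  if (is.na(v)) v <- model$dna_dna[dna_revcomp(doublet)]
  if (is.na(v)) {
    stop(sprintf("no DNA:DNA parameter for doublet %s", doublet),
         call. = FALSE)
  }
  unname(v)
}

# Watson-Crick RNA:DNA hybrid stack, keyed by the RNA doublet 5'->3'.
rna_stack <- function(model, doublet) {
  v <- model$rna_dna[doublet]
  if (is.na(v)) {
    stop(sprintf("no RNA:DNA parameter for doublet %s", doublet),
         call. = FALSE)
  }
  unname(v)
}

mismatch_offset <- function(model, type, position) {
  v <- model$mismatch_offsets[type]
  if (is.null(v) || is.na(v)) {
    stop(sprintf(
      "no mismatch parameter for type %s at position %d (parameterized types: %s)",
      type, position,
      paste(names(model$mismatch_offsets), collapse = ", ")), call. = FALSE)
  }
  unname(v)
}

# --- per-position energies ---------------------------------------------------

# Internal worker: the RNA:DNA and DNA:DNA stack energies attributed to
# position m of a pair. The doublet spanning positions (m-1, m) is assigned to
# m; position 1 carries no stack energy. Mismatches at either endpoint of the
# doublet add their per-type offsets to the Watson-Crick hybrid stack of the
# guide doublet.
.position_stacks <- function(pair, m, model) {
  if (m < 1L || m > pair$N) {
    stop(sprintf("position m = %d outside 1..%d", m, pair$N))
  }
  if (m == 1L) return(c(hybrid = 0, dna = 0))
  # 5'->3' on the guide-matching strand = decreasing position index
  d <- paste0(.proto_base(pair, m), .proto_base(pair, m - 1L))
  g <- paste0(.guide_base(pair, m), .guide_base(pair, m - 1L))
  hyb <- rna_stack(model, g)
  mm <- pair$mismatches
  for (p in c(m, m - 1L)) {
    hit <- which(mm$position == p)
    if (length(hit) > 0L) {
      hyb <- hyb + mismatch_offset(model, mm$type[hit[1L]], p)
    }
  }
  c(hybrid = hyb, dna = dna_stack(model, d))
}

#' Per-position exchange free energy
#'
#' The nearest-neighbour free-energy difference attributed to extending the
#' R-loop to position `m`: the RNA:DNA hybrid stack minus the DNA:DNA duplex
#' stack for the doublet spanning positions `m-1` and `m` (position 1 carries
#' no stack; the initiation term is handled separately). Negative values
#' favour strand invasion.
#'
#' @param pair a [guide_target_pair()].
#' @param m position in `1..N`, counted from the PAM-proximal end; may be a
#'   vector.
#' @param model an [energy_model()].
#' @return numeric vector of exchange energies (kcal/mol).
#' @export
step_exchange_energy <- function(pair, m, model) {
  stopifnot(inherits(pair, "guide_target_pair"),
            inherits(model, "energy_model"))
  vapply(as.integer(m), function(mi) {
    s <- .position_stacks(pair, mi, model)
    s[["hybrid"]] - s[["dna"]]
  }, numeric(1L))
}

#' Exchange-energy profile over all positions
#'
#' @inheritParams step_exchange_energy
#' @return numeric vector of length `N`, `[m]` holding the exchange energy of
#'   position `m`.
#' @export
exchange_profile <- function(pair, model) {
  step_exchange_energy(pair, seq_len(pair$N), model)
}

#' Whole-duplex binding free energy
#'
#' Sums the nearest-neighbour stack energies over the guide footprint
#' (mismatch-aware for the hybrid) and, for the hybrid strand system, adds the
#' initiation term `dg_init`.
#'
#' @inheritParams step_exchange_energy
#' @param strands `"hybrid"` for the guide RNA : target-strand duplex,
#'   `"dna"` for the protospacer DNA:DNA duplex over the same footprint.
#' @param include_init add `dg_init` (hybrid only by convention; ignored with
#'   a warning for `strands = "dna"`).
#' @return binding free energy dG37 (kcal/mol).
#' @export
duplex_binding_energy <- function(pair, model, strands = c("hybrid", "dna"),
                                  include_init = strands == "hybrid") {
  strands <- match.arg(strands)
  stacks <- vapply(seq_len(pair$N), function(m) {
    .position_stacks(pair, m, model)[[if (strands == "hybrid") "hybrid" else "dna"]]
  }, numeric(1L))
  total <- sum(stacks)
  include_init <- isTRUE(include_init)
  if (include_init && strands == "dna") {
    warning("initiation term is applied to the hybrid duplex only; ignored")
    include_init <- FALSE
  }
  if (include_init) total <- total + model$dg_init
  total
}
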