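# Sequence utilities shared across the package. Sequences are plain uppercase
# character scalars; DNA over ACGT, RNA over ACGU. Protospacer positions are
# numbered 1..N from the PAM-proximal end, i.e. position 1 is the 3'-most base
# of the guide-matching protospacer strand.

DNA_ALPHABET <- c("A", "C", "G", "T")
RNA_ALPHABET <- c("A", "C", "G", "U")

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Validate and normalize a nucleic-acid sequence
#'
#' Uppercases the input, converts T<->U according to the declared molecule
#' type, and errors (naming the offending position) on any other character.
#'
#' @param x character scalar sequence.
#' @param type `"DNA"` or `"RNA"`.
#' @param warn_converted warn when a T is found in RNA input (or U in DNA).
#' @return normalized character scalar.
#' @export
normalize_seq <- function(x, type = c("DNA", "RNA"), warn_converted = FALSE) {
  type <- match.arg(type)
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- toupper(gsub("[[:space:]]", "", x))
  wrong <- if (type == "DNA") "U" else "T"
  right <- if (type == "DNA") "T" else "U"
  if (grepl(wrong, x, fixed = TRUE)) {
    if (warn_converted) {
      warning(sprintf("%s sequence contains %s; converted to %s",
                      type, wrong, right), call. = FALSE)
    }
    x <- gsub(wrong, right, x, fixed = TRUE)
  }
  ok <- if (type == "DNA") DNA_ALPHABET else RNA_ALPHABET
  cc <- chars(x)
  bad <- which(!cc %in% ok)
  if (length(bad) > 0L) {
    stop(sprintf("illegal character '%s' at position %d in %s sequence",
                 cc[bad[1L]], bad[1L], type), call. = FALSE)
  }
  x
}

#' @rdname normalize_seq
#' @export
dna_complement <- function(x) chartr("ACGT", "TGCA", x)

#' @rdname normalize_seq
#' @export
dna_revcomp <- function(x) {
  paste(rev(chars(dna_complement(x))), collapse = "")
}

dna_to_rna <- function(x) chartr("T", "U", x)
rna_to_dna <- function(x) chartr("U", "T", x)

#' Evaluate code under a temporary RNG seed
#'
#' Installs `seed` into R's RNG, evaluates `code`, and restores the previous
#' RNG state on exit, so seeded computations never perturb the caller's
#' random stream. A `NULL` seed evaluates the code on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed
#'
#' Deterministically maps a (master seed, stream index) pair to a 31-bit
#' integer seed, so that per-record or per-replicate seed streams never
#' collide with, or depend on, each other's consumption of random numbers.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index (vectorized).
#' @return integer vector of derived seeds in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.numeric(index))
  m <- 2147483647  # 2^31 - 1, prime
  x <- (as.double(master) %% m)
  # one multiplicative-congruential step per component keeps everything exact
  # in double arithmetic (products stay < 2^53)
  x <- (x * 48271) %% m
  out <- ((x + as.double(index) + 1) * 69621) %% m
  as.integer(out)
}
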