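# Guide/target pair container. The protospacer is stored 5'->3' on the strand
# whose sequence matches the guide (the non-target strand); the PAM follows
# its 3' end. Positions are numbered 1..N from the PAM-proximal end, so
# position i sits at string index L+1-i of the protospacer and N+1-i of the
# guide. The guide RNA anneals antiparallel with its 3' end PAM-proximal.

.proto_base <- function(pair, i) substr(pair$protospacer,
                                        pair$L + 1L - i, pair$L + 1L - i)
.guide_base <- function(pair, i) substr(pair$guide,
                                        pair$N + 1L - i, pair$N + 1L - i)

# canonical, parameterized mismatch classes: guide base X opposite
# target-strand base Y with X = Y in DNA lettering (rU.dT counts U ~ T)
CANONICAL_MISMATCHES <- c("rG.dG", "rC.dC", "rA.dA", "rU.dT")

#' Construct a guide/target pair
#'
#' @param guide guide RNA, 5'->3' over ACGU (T accepted, converted), length
#'   `N` (typically 18-20: 20 for an sgRNA, 18 for a 5'-truncated tru-gRNA).
#' @param protospacer protospacer DNA, 5'->3' on the guide-matching strand
#'   (typically 20 bp), PAM side at the 3' end; length must be >= `N`.
#' @param pam 3-nt PAM motif immediately 3' of the protospacer.
#' @param id optional identifier carried through pipelines.
#' @return an object of class `guide_target_pair` with fields `guide`,
#'   `protospacer`, `pam`, `N` (guide length), `L` (protospacer length), and
#'   `mismatches`, a data frame of per-position annotations (`position`,
#'   `type`, `guide_base`, `target_base`, `isolated`).
#' @export
guide_target_pair <- function(guide, protospacer, pam = "TGG", id = NULL) {
  guide <- normalize_seq(guide, "RNA")
  protospacer <- normalize_seq(protospacer, "DNA")
  pam <- normalize_seq(pam, "DNA")
  N <- nchar(guide); L <- nchar(protospacer)
  if (N < 2L) stop("guide must be at least 2 nt")
  if (L < N) stop(sprintf("protospacer (%d bp) shorter than guide (%d nt)", L, N))
  if (nchar(pam) != 3L) stop("PAM must be 3 nt")
  pair <- structure(list(guide = guide, protospacer = protospacer, pam = pam,
                         N = N, L = L, id = id, mismatches = NULL),
                    class = "guide_target_pair")
  pair$mismatches <- annotate_mismatches(pair)
  pair
}

#' Annotate mismatches between a guide and its target
#'
#' Compares the guide with the PAM-proximal `N` positions of the target and
#' classifies each non-complementary position into one of the four
#' parameterized classes (rG.dG, rC.dC, rA.dA, rU.dT -- guide base opposite
#' the identical target-strand base) or `"other"`. Positions count from the
#' PAM. The `isolated` flag marks mismatches with no mismatched neighbour.
#'
#' @param guide a `guide_target_pair`, or a guide RNA string.
#' @param target protospacer DNA string (guide-matching strand) when `guide`
#'   is a string.
#' @return data frame with columns `position`, `type`, `guide_base`,
#'   `target_base`, `isolated` (zero rows for a perfect complement).
#' @export
annotate_mismatches <- function(guide, target = NULL) {
  if (inherits(guide, "guide_target_pair")) {
    pair <- guide
  } else {
    pair <- guide_target_pair(guide, target)
    return(pair$mismatches)
  }
  pos <- integer(); type <- character(); gb <- character(); tb <- character()
  for (i in seq_len(pair$N)) {
    g <- .guide_base(pair, i)
    d <- .proto_base(pair, i)
    if (g != dna_to_rna(d)) {
      y <- dna_complement(d)  # base actually present on the target strand
      t_i <- paste0("r", g, ".d", y)
      if (!(t_i %in% CANONICAL_MISMATCHES)) t_i <- "other"
      pos <- c(pos, i); type <- c(type, t_i); gb <- c(gb, g); tb <- c(tb, y)
    }
  }
  iso <- if (length(pos)) {
    !(pos - 1L) %in% pos & !(pos + 1L) %in% pos
  } else logical(0)
  data.frame(position = pos, type = type, guide_base = gb, target_base = tb,
             isolated = iso, stringsAsFactors = FALSE)
}

#' @export
print.guide_target_pair <- function(x, ...) {
  cat(sprintf("guide/target pair%s: guide %d nt, protospacer %d bp, PAM %s\n",
              if (is.null(x$id)) "" else paste0(" '", x$id, "'"),
              x$N, x$L, x$pam))
  cat(sprintf("  protospacer 5'-%s-3' %s (PAM)\n", x$protospacer, x$pam))
  cat(sprintf("  guide       3'-%s-5'%s\n",
              paste(rev(chars(x$guide)), collapse = ""),
              if (x$L > x$N) sprintf(" (positions 1-%d)", x$N) else ""))
  if (nrow(x$mismatches) == 0L) {
    cat("  perfect complement over the guide footprint\n")
  } else {
    cat(sprintf("  mismatches: %s\n",
                paste(sprintf("%s@%d", x$mismatches$type,
                              x$mismatches$position), collapse = ", ")))
  }
  invisible(x)
}
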