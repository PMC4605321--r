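#' Example AAVS1 guide/target pairs
#'
#' The canonical AAVS1 (T2) protospacer (human chromosome 19, PAM TGG),
#' shipped in `inst/extdata/aavs1.fa`, as ready-made pairs: the full 20-nt
#' sgRNA and the 18-nt tru-gRNA obtained by truncating two nucleotides from
#' the guide's 5' (PAM-distal) end.
#'
#' @param variant `"sgRNA"` (20 nt) or `"tru-gRNA"` (18 nt).
#' @return a [guide_target_pair()].
#' @export
aavs1_pair <- function(variant = c("sgRNA", "tru-gRNA")) {
  variant <- match.arg(variant)
  fa <- load_sequences(system.file("extdata", "aavs1.fa",
                                   package = "rloopkmc", mustWork = TRUE),
                       type = "DNA")
  proto <- fa$seq[fa$id == "AAVS1_protospacer"]
  guide <- dna_to_rna(proto)
  if (variant == "tru-gRNA") guide <- substr(guide, 3L, nchar(guide))
  guide_target_pair(guide, proto, pam = "TGG",
                    id = paste0("AAVS1_", variant))
}
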