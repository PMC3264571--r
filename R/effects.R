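# Codon-level effect classification shared by the simulator's truth records
# and the divergence annotator.

BASES <- c("A", "C", "G", "T")

comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

revcomp_chars <- function(x) rev(comp_base(x))

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify the effect of a single-codon substitution
#'
#' Translates the reference and alternate codons with the standard genetic
#' code and reports the effect class: `stop_gained` when the alternate codon
#' is a stop and the reference is not, `stop_lost` for the converse,
#' otherwise `synonymous` or `nonsynonymous` by amino-acid identity.
#'
#' @param ref_codon,alt_codon 3-letter codons on the coding (transcript)
#'   strand.
#' @return list with `effect`, `aa_ref`, `aa_alt` (stop written `*`).
#' @export
classify_codon_change <- function(ref_codon, alt_codon) {
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  effect <-
    if (aa_alt == "*" && aa_ref != "*") "stop_gained"
    else if (aa_ref == "*" && aa_alt != "*") "stop_lost"
    else if (aa_ref == aa_alt) "synonymous"
    else "nonsynonymous"
  list(effect = effect, aa_ref = aa_ref, aa_alt = aa_alt)
}

SENSE_CODONS <- local({
  all64 <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

STOP_CODONS <- c("TAA", "TAG", "TGA")

# sense codons one substitution away from a stop codon, with the position
# (1..3) and replacement base realising it
stop_gaining_edits <- function(codon) {
  out <- list()
  cc <- strsplit(codon, "")[[1]]
  for (i in 1:3) for (b in setdiff(BASES, cc[i])) {
    alt <- cc; alt[i] <- b
    if (paste(alt, collapse = "") %in% STOP_CODONS)
      out[[length(out) + 1L]] <- list(pos = i, base = b)
  }
  out
}
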