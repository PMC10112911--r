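# Standard nuclear codon table, written out rather than taken from an
# annotation package so that tests can check it against an independent
# implementation.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Translate a coding sequence
#'
#' Standard nuclear genetic code; stop codons become `"*"` and translation
#' does not stop at them (no read-through suppression either — every codon is
#' rendered, so premature stops are visible in the peptide).
#'
#' @param cds character scalar of A/C/G/T with length divisible by 3.
#' @return one-letter peptide string (`""` for empty input).
#' @examples
#' translate("ATGAAATAA")  # "MK*"
#' @export
translate <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (nchar(cds) == 0L) return("")
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length ", nchar(cds), " is not divisible by 3")
  if (grepl("[^ACGT]", cds))
    stop("CDS contains characters outside ACGT")
  starts <- seq(1L, nchar(cds), by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  paste(CODON_TABLE[codons], collapse = "")
}
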