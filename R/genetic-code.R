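# Standard genetic code in the RNA (U) convention. Families follow the CodonW
# convention: Leu/Ser/Arg are single 6-fold families, Ile is the sole 3-fold
# family; Met and Trp are non-degenerate.

.codon_table <- local({
  bases <- c("U", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- c(
    UUU = "Phe", UUC = "Phe", UUA = "Leu", UUG = "Leu",
    CUU = "Leu", CUC = "Leu", CUA = "Leu", CUG = "Leu",
    AUU = "Ile", AUC = "Ile", AUA = "Ile", AUG = "Met",
    GUU = "Val", GUC = "Val", GUA = "Val", GUG = "Val",
    UCU = "Ser", UCC = "Ser", UCA = "Ser", UCG = "Ser",
    CCU = "Pro", CCC = "Pro", CCA = "Pro", CCG = "Pro",
    ACU = "Thr", ACC = "Thr", ACA = "Thr", ACG = "Thr",
    GCU = "Ala", GCC = "Ala", GCA = "Ala", GCG = "Ala",
    UAU = "Tyr", UAC = "Tyr", UAA = "Stop", UAG = "Stop",
    CAU = "His", CAC = "His", CAA = "Gln", CAG = "Gln",
    AAU = "Asn", AAC = "Asn", AAA = "Lys", AAG = "Lys",
    GAU = "Asp", GAC = "Asp", GAA = "Glu", GAG = "Glu",
    UGU = "Cys", UGC = "Cys", UGA = "Stop", UGG = "Trp",
    CGU = "Arg", CGC = "Arg", CGA = "Arg", CGG = "Arg",
    AGU = "Ser", AGC = "Ser", AGA = "Arg", AGG = "Arg",
    GGU = "Gly", GGC = "Gly", GGA = "Gly", GGG = "Gly"
  )
  aa[codons]
})

.stop_codons <- names(.codon_table)[.codon_table == "Stop"]
.sense_codons <- names(.codon_table)[.codon_table != "Stop"]

# amino acid -> synonymous codons (sense only)
.aa_families <- split(.sense_codons, .codon_table[.sense_codons])

# degeneracy per amino acid
.aa_degeneracy <- vapply(.aa_families, length, integer(1))

# ENC degeneracy classes: counts of amino acids per class are fixed by the code
.enc_classes <- list(
  `2` = names(.aa_degeneracy)[.aa_degeneracy == 2L],
  `3` = names(.aa_degeneracy)[.aa_degeneracy == 3L],
  `4` = names(.aa_degeneracy)[.aa_degeneracy == 4L],
  `6` = names(.aa_degeneracy)[.aa_degeneracy == 6L]
)

# PR2 codon families: third-position composition is read over fourfold-
# degenerate codon boxes. "strict" keeps the five amino acids encoded by
# exactly four codons; "extended" (default) adds the fourfold boxes of the
# 6-fold families (CUN of Leu, UCN of Ser, CGN of Arg).
.pr2_boxes <- list(
  strict   = c("GC", "GG", "CC", "AC", "GU"),
  extended = c("GC", "GG", "CC", "AC", "GU", "CG", "CU", "UC")
)

#' Genetic-code lookup tables
#'
#' Accessors for the standard genetic code as used throughout the package
#' (RNA alphabet, CodonW-style synonymous families).
#'
#' @return `codon_to_aa()`: named character vector mapping all 64 codons to
#'   three-letter amino-acid names (`"Stop"` for UAA/UAG/UGA).
#'   `synonymous_families()`: list of sense-codon vectors, one per amino acid.
#' @examples
#' codon_to_aa()[["AUG"]]
#' synonymous_families()$Ala
#' @export
codon_to_aa <- function() .codon_table

#' @rdname codon_to_aa
#' @export
synonymous_families <- function() .aa_families
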