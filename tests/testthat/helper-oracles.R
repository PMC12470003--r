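# Independent brute-force oracles, deliberately implemented from first
# principles (families derived from Biostrings::GENETIC_CODE, explicit loops)
# rather than through the package's own code paths.

oracle_codons <- function(cds) {
  cds <- toupper(gsub("U", "T", cds))
  substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
}

# Wright's ENC via explicit per-amino-acid homozygosity
oracle_enc <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  cods <- oracle_codons(cds)
  cods <- cods[cods %in% names(code)]
  aa <- code[cods]
  cods <- cods[aa != "*"]; aa <- aa[aa != "*"]
  degeneracy <- table(code[code != "*"])
  F_by_class <- list("2" = numeric(0), "3" = numeric(0),
                     "4" = numeric(0), "6" = numeric(0))
  for (a in unique(aa)) {
    k <- as.integer(degeneracy[[a]])
    if (k == 1L) next
    n <- sum(aa == a)
    if (n < 2L) next
    counts <- table(cods[aa == a])
    p <- as.numeric(counts) / n
    Fa <- (n * sum(p^2) - 1) / (n - 1)
    F_by_class[[as.character(k)]] <- c(F_by_class[[as.character(k)]], Fa)
  }
  Fbar <- vapply(F_by_class, function(v) if (length(v)) mean(v) else NA_real_,
                 numeric(1))
  if (is.na(Fbar[["3"]])) Fbar[["3"]] <- mean(c(Fbar[["2"]], Fbar[["4"]]))
  if (any(is.na(Fbar)) || any(Fbar <= 0)) return(NA_real_)
  enc <- 2 + 9 / Fbar[["2"]] + 1 / Fbar[["3"]] + 5 / Fbar[["4"]] + 3 / Fbar[["6"]]
  min(max(enc, 20), 61)
}

# RSCU via explicit family normalization
oracle_rscu <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  cods <- oracle_codons(cds)
  aa <- code[cods]
  cods <- cods[aa != "*"]; aa <- aa[aa != "*"]
  out <- c()
  for (a in unique(aa)) {
    fam <- names(code)[code == a]
    counts <- vapply(fam, function(cn) sum(cods == cn), numeric(1))
    vals <- counts / (sum(counts) / length(fam))
    names(vals) <- gsub("T", "U", fam)
    out <- c(out, vals)
  }
  out
}

# global nucleotide diversity by explicit pair/column loops, complete deletion
oracle_global_pi <- function(aln) {
  M <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  good <- apply(M, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  M <- M[, good, drop = FALSE]
  n <- nrow(M)
  total <- 0; npair <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    diffs <- 0
    for (k in seq_len(ncol(M))) if (M[i, k] != M[j, k]) diffs <- diffs + 1
    total <- total + diffs / ncol(M)
    npair <- npair + 1
  }
  total / npair
}

# OLS slope by direct summation
oracle_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
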