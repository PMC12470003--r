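#' Count codons in a coding sequence
#'
#' Counts non-overlapping triplets 5'->3' with T read as U. Codons containing
#' an ambiguity symbol are skipped. Stop codons are tallied but excluded from
#' the sense-codon total used by all downstream statistics.
#'
#' @param cds DNA (or RNA) string with length divisible by 3.
#' @return A `codon_counts` list: `counts` (named integer vector over the 64
#'   codons, RNA alphabet), `total` (sense-codon count), `n_ambiguous`
#'   (skipped codons).
#' @export
count_codons <- function(cds) {
  cods <- codon_split(cds)
  clean <- grepl("^[ACGU]{3}$", cods)
  tab <- table(factor(cods[clean], levels = names(.codon_table)))
  counts <- as.integer(tab)
  names(counts) <- names(.codon_table)
  structure(
    list(counts = counts,
         total = sum(counts[.sense_codons]),
         n_ambiguous = sum(!clean)),
    class = "codon_counts"
  )
}

#' @export
`+.codon_counts` <- function(e1, e2) {
  structure(list(counts = e1$counts + e2$counts,
                 total = e1$total + e2$total,
                 n_ambiguous = e1$n_ambiguous + e2$n_ambiguous),
            class = "codon_counts")
}

#' Positional GC content of a gene
#'
#' GC percentage at each codon position over sense codons, plus the usual
#' composites: `gc12 = (gc1 + gc2)/2` and `gc_all = (gc1 + gc2 + gc3)/3`.
#'
#' @param counts A `codon_counts` object with `total > 0`.
#' @return Named numeric vector `gc1`, `gc2`, `gc3`, `gc12`, `gc_all`
#'   (percentages in \[0, 100\]).
#' @export
gc_by_position <- function(counts) {
  if (counts$total == 0L) stop("no sense codons: GC content undefined", call. = FALSE)
  n <- counts$counts[.sense_codons]
  gc_at <- function(k) {
    base_k <- substr(.sense_codons, k, k)
    100 * sum(n[base_k %in% c("G", "C")]) / counts$total
  }
  gc1 <- gc_at(1L); gc2 <- gc_at(2L); gc3 <- gc_at(3L)
  c(gc1 = gc1, gc2 = gc2, gc3 = gc3,
    gc12 = (gc1 + gc2) / 2, gc_all = (gc1 + gc2 + gc3) / 3)
}

#' Relative synonymous codon usage (RSCU)
#'
#' A codon's count divided by the mean count of its synonymous family: 1 means
#' no preference; values above 1 mark preferred codons. Families with zero
#' usage in the gene are returned as `NA` (undefined); stop codons are
#' excluded. Met (AUG) and Trp (UGG) have RSCU 1 whenever used.
#'
#' @param counts A `codon_counts` object with `total > 0`.
#' @return Named numeric vector over the 61 sense codons.
#' @export
compute_rscu <- function(counts) {
  n <- counts$counts[.sense_codons]
  out <- rep(NA_real_, length(.sense_codons))
  names(out) <- .sense_codons
  for (fam in .aa_families) {
    tot <- sum(n[fam])
    if (tot > 0L) out[fam] <- n[fam] / (tot / length(fam))
  }
  out
}

#' Wright's effective number of codons (ENC)
#'
#' Summarizes a gene's overall codon bias on the scale 20 (one codon per amino
#' acid) to 61 (uniform synonymous usage). For each amino acid used n >= 2
#' times the codon homozygosity is `F = (n * sum(p_i^2) - 1) / (n - 1)`; F is
#' averaged within degeneracy classes (2-, 3-, 4-, 6-fold; Leu/Ser/Arg are
#' 6-fold, Ile 3-fold) and `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, clamped to
#' \[20, 61\]. When the 3-fold class (Ile) is not estimable, `(F2 + F4)/2` is
#' substituted; if any other class average is missing or non-positive the ENC
#' is undefined (`NA`).
#'
#' @param counts A `codon_counts` object with `total > 0`.
#' @return ENC value in \[20, 61\], or `NA` if not estimable.
#' @export
compute_enc <- function(counts) {
  n <- counts$counts[.sense_codons]
  aa_F <- vapply(names(.aa_families), function(aa) {
    cn <- n[.aa_families[[aa]]]
    tot <- sum(cn)
    if (tot < 2L) return(NA_real_)
    p <- cn / tot
    (tot * sum(p^2) - 1) / (tot - 1)
  }, numeric(1))
  class_mean <- vapply(.enc_classes, function(aas) {
    f <- aa_F[aas]
    f <- f[!is.na(f)]
    if (length(f) == 0L) NA_real_ else mean(f)
  }, numeric(1))
  if (is.na(class_mean[["3"]]) &&
      !is.na(class_mean[["2"]]) && !is.na(class_mean[["4"]])) {
    class_mean[["3"]] <- (class_mean[["2"]] + class_mean[["4"]]) / 2
  }
  if (any(is.na(class_mean)) || any(class_mean <= 0)) return(NA_real_)
  enc <- 2 + 9 / class_mean[["2"]] + 1 / class_mean[["3"]] +
    5 / class_mean[["4"]] + 3 / class_mean[["6"]]
  min(max(enc, 20), 61)
}

#' Expected ENC under mutation alone
#'
#' The standard null curve for the ENC-plot: a gene whose codon usage is
#' shaped only by mutational GC pressure at silent sites is expected to have
#' `ENC = 2 + X + 29 / (X^2 + (1 - X)^2)` where `X` is its GC3 fraction.
#'
#' @param gc3 GC3 as a fraction strictly inside (0, 1). Vectorized.
#' @return Expected ENC value(s).
#' @examples
#' expected_enc(0.5) # 60.5
#' @export
expected_enc <- function(gc3) {
  if (any(gc3 <= 0 | gc3 >= 1)) {
    stop("gc3 must lie strictly inside (0, 1)", call. = FALSE)
  }
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' PR2 parity coordinates of a gene
#'
#' Third-position base composition restricted to fourfold-degenerate codon
#' boxes, summarized as `x = G3/(G3 + C3)` and `y = A3/(A3 + T3)`. The point
#' (0.5, 0.5) is parity-rule-2 equilibrium (A = T and G = C at silent sites);
#' displacement from it measures strand-specific bias.
#'
#' @param counts A `codon_counts` object.
#' @param families `"extended"` (default; the five 4-fold amino acids plus the
#'   fourfold boxes CUN, UCN, CGN of the 6-fold families) or `"strict"` (the
#'   five 4-fold amino acids only).
#' @return Named numeric vector `a3`, `t3`, `g3`, `c3`, `x`, `y`; `x`/`y` are
#'   `NA` when a denominator is zero.
#' @export
pr2_coordinates <- function(counts, families = c("extended", "strict")) {
  families <- match.arg(families)
  boxes <- .pr2_boxes[[families]]
  cods <- .sense_codons[substr(.sense_codons, 1L, 2L) %in% boxes]
  n <- counts$counts[cods]
  third <- substr(cods, 3L, 3L)
  tally <- vapply(c(A = "A", U = "U", G = "G", C = "C"),
                  function(b) sum(n[third == b]), numeric(1))
  x <- if (tally[["G"]] + tally[["C"]] > 0) tally[["G"]] / (tally[["G"]] + tally[["C"]]) else NA_real_
  y <- if (tally[["A"]] + tally[["U"]] > 0) tally[["A"]] / (tally[["A"]] + tally[["U"]]) else NA_real_
  c(a3 = tally[["A"]], t3 = tally[["U"]], g3 = tally[["G"]], c3 = tally[["C"]],
    x = x, y = y)
}

#' Per-gene codon-usage profiles
#'
#' Computes the full profile table used by the bias analyses: codon number,
#' positional GC, ENC, and PR2 third-position tallies and coordinates for each
#' gene.
#'
#' @param cds Named character vector of in-frame coding sequences, or a
#'   `cds_set` from [filter_cds()].
#' @param pr2_families Passed to [pr2_coordinates()].
#' @return Data frame with one row per gene and columns `gene`, `n_codons`,
#'   `gc1`, `gc2`, `gc3`, `gc12`, `gc_all`, `enc`, `a3`, `t3`, `g3`, `c3`,
#'   `pr2_x`, `pr2_y`.
#' @export
codon_profiles <- function(cds, pr2_families = "extended") {
  if (inherits(cds, "cds_set")) cds <- cds$entries
  stopifnot(length(cds) > 0L)
  rows <- lapply(names(cds), function(g) {
    cc <- count_codons(cds[[g]])
    gc <- gc_by_position(cc)
    pr2 <- pr2_coordinates(cc, families = pr2_families)
    data.frame(gene = g, n_codons = cc$total,
               gc1 = gc[["gc1"]], gc2 = gc[["gc2"]], gc3 = gc[["gc3"]],
               gc12 = gc[["gc12"]], gc_all = gc[["gc_all"]],
               enc = compute_enc(cc),
               a3 = pr2[["a3"]], t3 = pr2[["t3"]],
               g3 = pr2[["g3"]], c3 = pr2[["c3"]],
               pr2_x = pr2[["x"]], pr2_y = pr2[["y"]])
  })
  do.call(rbind, rows)
}

#' Pooled codon counts of a gene set
#'
#' @param cds Named character vector of coding sequences (or `cds_set`).
#' @param genes Optional subset of gene names to pool.
#' @return A `codon_counts` object for the pooled set.
#' @export
pooled_counts <- function(cds, genes = NULL) {
  if (inherits(cds, "cds_set")) cds <- cds$entries
  if (!is.null(genes)) cds <- cds[genes]
  Reduce(`+`, lapply(cds, count_codons))
}
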