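#' Extract coding sequences from an annotated genome record
#'
#' Concatenates the exon intervals of every CDS feature in transcript order,
#' reverse-complementing minus-strand features. On circular records intervals
#' may run past the sequence end and are wrapped. Inverted-repeat duplicates
#' (same gene name, identical sequence) are collapsed to a single entry; copies
#' with the same name but different sequence keep a numeric `copy_tag` suffix.
#'
#' @param record A `genome_record` with at least one CDS feature.
#' @return Named character vector, gene name -> DNA coding sequence (5'->3').
#' @export
extract_cds <- function(record) {
  cds_feats <- Filter(function(f) f$kind == "CDS", record$features)
  if (length(cds_feats) == 0L) stop("record has no CDS features", call. = FALSE)
  seqs <- vapply(cds_feats, function(f) feature_sequence(f, record), character(1))
  names(seqs) <- vapply(cds_feats, `[[`, character(1), "gene")

  out <- character(0)
  for (nm in unique(names(seqs))) {
    copies <- unique(unname(seqs[names(seqs) == nm]))
    if (length(copies) == 1L) {
      out[nm] <- copies
    } else {
      out[sprintf("%s_%d", nm, seq_along(copies))] <- copies
    }
  }
  out
}

# transcript sequence of one feature on a record (wraps on circular genomes)
feature_sequence <- function(feature, record) {
  len <- record$length
  parts <- apply(feature$intervals, 1L, function(iv) {
    s <- iv[1L]; e <- iv[2L]
    if (e > len || s > len || e < s) {
      if (!record$circular) {
        stop("interval ", s, "..", e, " outside linear sequence of ", len, " bp",
             call. = FALSE)
      }
      circular_substr(record$sequence, s, e, len)
    } else {
      substr(record$sequence, s, e)
    }
  })
  tx <- paste(parts, collapse = "")
  if (feature$strand == "-") tx <- revcomp_chr(tx)
  tx
}

#' Filter coding sequences for codon-usage analysis
#'
#' Keeps sequences that (1) start with ATG, (2) end with a canonical stop
#' (TAA/TAG/TGA), (3) contain no premature in-frame stop codon, (4) are
#' strictly longer than `min_len`, (5) have length divisible by three, and
#' (6) have at most 1\% ambiguous codons. A per-gene rejection log records the
#' first failing rule.
#'
#' @param raw Named character vector of candidate coding sequences (DNA).
#' @param min_len Minimum length in bp; sequences of exactly `min_len` are
#'   rejected (strict inequality). Default 300.
#' @param max_ambiguous_frac Maximum tolerated fraction of codons containing a
#'   non-ACGT symbol. Default 0.01.
#' @return A `cds_set` list: `entries` (named vector of retained sequences) and
#'   `log` (data frame with columns `gene`, `length`, `status`, `reason`).
#' @export
filter_cds <- function(raw, min_len = 300L, max_ambiguous_frac = 0.01) {
  stopifnot(length(raw) > 0L, !is.null(names(raw)))
  reasons <- vapply(raw, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n %% 3L != 0L) return("frame_incomplete")
    if (n <= min_len) return("too_short")
    if (substr(s, 1L, 3L) != "ATG") return("no_start_codon")
    if (!substr(s, n - 2L, n) %in% c("TAA", "TAG", "TGA")) return("no_stop_codon")
    cods <- codon_split(s)
    internal <- cods[-length(cods)]
    clean <- grepl("^[ACGU]{3}$", internal)
    if (mean(!clean) > max_ambiguous_frac) return("excess_ambiguity")
    if (any(internal[clean] %in% .stop_codons)) return("internal_stop")
    "ok"
  }, character(1))
  keep <- reasons == "ok"
  structure(
    list(
      entries = raw[keep],
      log = data.frame(gene = names(raw), length = nchar(raw),
                       status = ifelse(keep, "retained", "rejected"),
                       reason = reasons, row.names = NULL)
    ),
    class = "cds_set"
  )
}

#' @export
print.cds_set <- function(x, ...) {
  cat(sprintf("<cds_set> %d retained / %d input sequences\n",
              length(x$entries), nrow(x$log)))
  invisible(x)
}

#' Summarize the annotation of a genome record
#'
#' Counts annotated gene occurrences by kind (IR duplicates counted as
#' separate occurrences, as in published plastome gene totals) and tabulates
#' introns per feature (exon count minus one).
#'
#' @param record A `genome_record`.
#' @return List with `counts` (named integer vector: `genes`, `CDS`, `tRNA`,
#'   `rRNA`) and `introns` (data frame `gene`, `kind`, `n_exons`, `n_introns`).
#' @export
gene_inventory <- function(record) {
  feats <- Filter(function(f) f$kind %in% c("CDS", "tRNA", "rRNA"), record$features)
  kinds <- vapply(feats, `[[`, character(1), "kind")
  counts <- c(
    genes = length(feats),
    CDS = sum(kinds == "CDS"),
    tRNA = sum(kinds == "tRNA"),
    rRNA = sum(kinds == "rRNA")
  )
  introns <- data.frame(
    gene = vapply(feats, `[[`, character(1), "gene"),
    kind = kinds,
    n_exons = vapply(feats, function(f) nrow(f$intervals), integer(1))
  )
  introns$n_introns <- introns$n_exons - 1L
  list(counts = counts, introns = introns)
}

#' Read coding sequences from a FASTA file
#'
#' @param path FASTA file of CDS records; the first whitespace-delimited token
#'   of each header is used as the gene name.
#' @return Named character vector of DNA sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  out
}

#' Write coding sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
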