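#' Read a GenBank flat file into a genome record
#'
#' Parses a single-record GenBank flat file (LOCUS/FEATURES/ORIGIN) into a
#' `genome_record`: the nucleotide sequence plus an ordered list of gene
#' features with 1-based inclusive exon intervals. `join()` locations are kept
#' as multi-interval features; `complement()` anywhere in a location marks the
#' minus strand.
#'
#' @param path Path to a `.gb`/`.gbk` flat file containing one record with a
#'   sequence.
#' @return A `genome_record` list with fields `id`, `length`, `circular`,
#'   `sequence` (uppercase DNA string) and `features` (list of `gene_feature`
#'   lists with fields `gene`, `kind`, `strand`, `intervals`, `copy_tag`).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("not a GenBank flat file: no LOCUS line", call. = FALSE)
  locus <- strsplit(trimws(lines[locus_i[1L]]), "\\s+")[[1L]]
  id <- locus[2L]
  stated_len <- suppressWarnings(as.integer(locus[3L]))
  circular <- any(tolower(locus) == "circular")

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0L) stop("GenBank record has no ORIGIN sequence block", call. = FALSE)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1L]][1L] else length(lines) + 1L
  seq_lines <- if (end_i - 1L > origin_i[1L]) {
    lines[seq(origin_i[1L] + 1L, end_i - 1L)]
  } else character(0)
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("GenBank record has an empty sequence", call. = FALSE)

  feat_i <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat_i)) {
    block <- lines[seq(feat_i[1L] + 1L, origin_i[1L] - 1L)]
    features <- parse_feature_block(block)
  }

  rec <- genome_record(id = id, sequence = sequence, circular = circular,
                       features = features)
  if (!is.na(stated_len) && stated_len != rec$length) {
    warning("LOCUS states ", stated_len, " bp but sequence has ", rec$length, " bp")
  }
  rec
}

#' Construct a genome record
#'
#' @param id Accession or identifier string.
#' @param sequence Nucleotide string over A/C/G/T/N.
#' @param circular Is the molecule circular?
#' @param features List of `gene_feature` objects (see [gene_feature()]).
#' @return A `genome_record` list.
#' @export
genome_record <- function(id, sequence, circular = TRUE, features = list()) {
  sequence <- toupper(sequence)
  structure(
    list(id = id, length = nchar(sequence), circular = circular,
         sequence = sequence, features = features),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s, %d features\n",
              x$id, x$length, if (x$circular) "circular" else "linear",
              length(x$features)))
  invisible(x)
}

#' Construct a gene feature
#'
#' @param gene Gene name.
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`, `"gene"`.
#' @param strand `"+"` or `"-"`.
#' @param intervals Integer matrix with columns `start`, `end` (1-based,
#'   inclusive), one row per exon, ordered along the genome.
#' @param copy_tag Optional disambiguator for IR-duplicated copies.
#' @return A `gene_feature` list.
#' @export
gene_feature <- function(gene, kind = "CDS", strand = "+", intervals,
                         copy_tag = NA_character_) {
  if (is.vector(intervals)) intervals <- matrix(intervals, ncol = 2L, byrow = TRUE)
  storage.mode(intervals) <- "integer"
  colnames(intervals) <- c("start", "end")
  stopifnot(nrow(intervals) >= 1L, kind %in% c("CDS", "tRNA", "rRNA", "gene"),
            strand %in% c("+", "-"))
  structure(list(gene = gene, kind = kind, strand = strand,
                 intervals = intervals, copy_tag = copy_tag),
            class = "gene_feature")
}

# --- internal: feature-table parsing ---------------------------------------

parse_feature_block <- function(block) {
  # feature key lives in columns 6-20; continuation lines are blank there
  is_key <- grepl("^ {5}\\S", block)
  key_idx <- which(is_key)
  features <- list()
  synth <- 0L
  for (i in seq_along(key_idx)) {
    from <- key_idx[i]
    to <- if (i < length(key_idx)) key_idx[i + 1L] - 1L else length(block)
    entry <- block[from:to]
    key <- sub("^\\s*(\\S+).*$", "\\1", entry[1L])
    if (!key %in% c("CDS", "tRNA", "rRNA", "gene")) next
    # location = first line remainder plus continuation lines w/o qualifiers
    loc <- sub("^\\s*\\S+\\s*", "", entry[1L])
    j <- 2L
    while (j <= length(entry) && !grepl("^\\s+/", entry[j])) {
      loc <- paste0(loc, trimws(entry[j]))
      j <- j + 1L
    }
    quals <- entry[seq_len(length(entry)) >= j]
    gene <- NA_character_
    hit <- grep('/gene="', quals, fixed = TRUE, value = TRUE)
    if (length(hit)) gene <- sub('.*?/gene="([^"]*)".*', "\\1", hit[1L])
    if (is.na(gene)) {
      synth <- synth + 1L
      gene <- sprintf("%s_feature_%03d", key, synth)
      warning("feature without /gene qualifier retained as ", gene, call. = FALSE)
    }
    parsed <- parse_location(loc)
    features[[length(features) + 1L]] <-
      gene_feature(gene, kind = key, strand = parsed$strand,
                   intervals = parsed$intervals)
  }
  features
}

parse_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  strand <- if (grepl("complement\\(", loc)) "-" else "+"
  inner <- gsub("complement\\(|join\\(|order\\(", "", loc)
  inner <- gsub(")", "", inner, fixed = TRUE)
  parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
  parts <- gsub("[<>]", "", parts)
  ivs <- t(vapply(parts, function(p) {
    se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    if (length(se) == 1L) se <- c(se, se)
    se
  }, integer(2)))
  list(strand = strand, intervals = ivs)
}

# --- writer ----------------------------------------------------------------

#' Write a genome record as a GenBank flat file
#'
#' Emits a minimal but standards-conformant record (LOCUS, FEATURES, ORIGIN
#' with 60-base lines) that round-trips through [read_genbank()] and is
#' readable by third-party parsers.
#'
#' @param record A `genome_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  topo <- if (record$circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s PLN 01-JAN-2026",
                   record$id, record$length, topo),
           sprintf("DEFINITION  %s synthetic plastome record.", record$id),
           sprintf("ACCESSION   %s", record$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", record$length))
  for (f in record$features) {
    spans <- sprintf("%d..%d", f$intervals[, 1L], f$intervals[, 2L])
    loc <- if (length(spans) > 1L) sprintf("join(%s)", paste(spans, collapse = ",")) else spans
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out,
             sprintf("     %-15s %s", f$kind, loc),
             sprintf("                     /gene=\"%s\"", f$gene))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(record$sequence)
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
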