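#' Detect the quadripartite architecture of a circular plastome
#'
#' Searches for the maximal pair of disjoint, reverse-complement-identical
#' segments of at least `min_ir` bp on the circular genome (the inverted
#' repeats), then assigns the longer inter-IR arc as the large single-copy
#' region (LSC) and the shorter as the small single-copy region (SSC).
#' Detection is rotation-invariant: the reported lengths do not depend on
#' where the circular sequence happens to start. When no exact repeat pair is
#' found, a fallback pass allows up to `max_mismatch_frac` mismatches during
#' extension and flags the result as approximate.
#'
#' @param record A circular `genome_record` with `length > 4 * min_ir`.
#' @param min_ir Minimum inverted-repeat length in bp (default 1000).
#' @param max_mismatch_frac Mismatch tolerance of the fallback pass (0.001).
#' @return A `quadripartite_structure` list: intervals `lsc`, `irb`, `ssc`,
#'   `ira` (1-based inclusive `c(start, end)`; `start > end` means the
#'   interval wraps past the origin), `lengths` (named vector), `approximate`,
#'   `genome_length`.
#' @export
detect_inverted_repeats <- function(record, min_ir = 1000L,
                                    max_mismatch_frac = 0.001) {
  stopifnot(inherits(record, "genome_record"))
  if (!record$circular) stop("quadripartite detection requires a circular record", call. = FALSE)
  L <- record$length
  if (L <= 4L * min_ir) stop("genome too short for min_ir = ", min_ir, call. = FALSE)

  best <- find_ir_pair(record$sequence, min_ir, mismatch_frac = 0)
  approximate <- FALSE
  if (max_mismatch_frac > 0) {
    # a rare SNV between the two IR copies splits the exact repeat in half;
    # take the mismatch-tolerant pair only when it is substantially longer
    # than the best exact one
    appr <- find_ir_pair(record$sequence, min_ir, mismatch_frac = max_mismatch_frac)
    if (!is.null(appr) && appr$mismatches > 0L &&
        (is.null(best) || appr$len > 1.2 * best$len)) {
      best <- appr
      approximate <- TRUE
    }
  }
  if (is.null(best)) {
    stop("no_quadripartite: no inverted repeat pair of >= ", min_ir, " bp",
         call. = FALSE)
  }

  f1 <- best$f1; f2 <- best$f2; r1 <- best$r1; r2 <- best$r2
  len <- best$len
  gap1 <- (wrap_pos(r1, L) - wrap_pos(f2, L) - 1L) %% L  # arc after fwd IR
  gap2 <- (wrap_pos(f1, L) - wrap_pos(r2, L) - 1L) %% L  # arc after rev IR
  if (2L * len + gap1 + gap2 != L) {
    stop("overlapping inverted-repeat candidates", call. = FALSE)
  }
  iv <- function(s, e) c(start = wrap_pos(s, L), end = wrap_pos(e, L))
  if (gap1 >= gap2) {
    lsc <- iv(f2 + 1L, r1 - 1L); irb <- iv(r1, r2)
    ssc <- iv(r2 + 1L, f1 - 1L); ira <- iv(f1, f2)
    lsc_len <- gap1; ssc_len <- gap2
  } else {
    lsc <- iv(r2 + 1L, f1 - 1L); irb <- iv(f1, f2)
    ssc <- iv(f2 + 1L, r1 - 1L); ira <- iv(r1, r2)
    lsc_len <- gap2; ssc_len <- gap1
  }
  structure(
    list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
         lengths = c(lsc = lsc_len, irb = len, ssc = ssc_len, ira = len),
         approximate = approximate, genome_length = L),
    class = "quadripartite_structure"
  )
}

#' @export
print.quadripartite_structure <- function(x, ...) {
  cat(sprintf("<quadripartite_structure> %d bp: LSC %d | IRb %d | SSC %d | IRa %d%s\n",
              x$genome_length, x$lengths[["lsc"]], x$lengths[["irb"]],
              x$lengths[["ssc"]], x$lengths[["ira"]],
              if (x$approximate) " (approximate match)" else ""))
  invisible(x)
}

# seed-and-extend search for the maximal reverse-complement segment pair;
# returns NULL when nothing >= min_ir is found. Coordinates are on the
# doubled sequence (f* anchored in 1..L).
find_ir_pair <- function(seq, min_ir, mismatch_frac = 0) {
  L <- nchar(seq)
  D <- paste0(seq, seq)
  Dc <- strsplit(D, "", fixed = TRUE)[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seedlen <- max(50L, min(400L, min_ir %/% 2L))
  step <- max(1L, min_ir - seedlen)
  Dset <- Biostrings::DNAString(D)

  best <- NULL
  seen <- character(0)
  for (p in seq(1L, L, by = step)) {
    seed <- substr(D, p, p + seedlen - 1L)
    if (grepl("[^ACGT]", seed)) next
    hits <- Biostrings::start(Biostrings::matchPattern(revcomp_chr(seed), Dset))
    hits <- hits[hits <= L + seedlen]  # one representative per circle position
    for (q in hits) {
      ext <- extend_rc_pair(Dc, L, p, p + seedlen - 1L, q, q + seedlen - 1L,
                            comp, mismatch_frac)
      if (is.null(ext) || ext$len < min_ir) next
      key <- paste(sort(c(wrap_pos(ext$f1, L), wrap_pos(ext$r1, L))), ext$len,
                   collapse = "_")
      if (key %in% seen) next
      seen <- c(seen, key)
      if (is.null(best) || ext$len > best$len) best <- ext
    }
  }
  best
}

# greedily extend an anchored reverse-complement pair in both directions,
# stopping before the two segments collide on the circle or cover > L/2 each
extend_rc_pair <- function(Dc, L, f1, f2, r1, r2, comp, mismatch_frac) {
  circ <- function(i) ((i - 1L) %% L) + 1L
  overlaps <- function(pos, s, e) {
    # is circle position pos inside circle segment s..e (given as D coords)?
    rel <- (pos - circ(s)) %% L
    rel <= ((e - s) %% L)
  }
  len <- f2 - f1 + 1L
  mm <- 0L
  budget <- function(l) floor(mismatch_frac * l)
  # grow left of fwd / right of rev; pending tracks mismatches at the tip so
  # the segment never ends on a mismatch (trimmed back after the loop)
  pending <- 0L
  repeat {
    if (2L * (len + 1L) > L) break
    nf <- f1 - 1L; nr <- r2 + 1L
    if (nf < 1L || nr > 2L * L) break
    if (overlaps(circ(nf), r1, r2) || overlaps(circ(nr), f1, f2)) break
    match <- identical(unname(comp[Dc[nf]]), Dc[circ(nr)])
    if (!match && mm + 1L > budget(len + 1L)) break
    mm <- mm + as.integer(!match)
    pending <- if (match) 0L else pending + 1L
    f1 <- nf; r2 <- nr; len <- len + 1L
  }
  f1 <- f1 + pending; r2 <- r2 - pending; len <- len - pending; mm <- mm - pending
  # grow right of fwd / left of rev
  pending <- 0L
  repeat {
    if (2L * (len + 1L) > L) break
    nf <- f2 + 1L; nr <- r1 - 1L
    if (nr < 1L || nf > 2L * L) break
    if (overlaps(circ(nf), r1, r2) || overlaps(circ(nr), f1, f2)) break
    match <- identical(unname(comp[Dc[circ(nf)]]), Dc[circ(nr)])
    if (!match && mm + 1L > budget(len + 1L)) break
    mm <- mm + as.integer(!match)
    pending <- if (match) 0L else pending + 1L
    f2 <- nf; r1 <- nr; len <- len + 1L
  }
  f2 <- f2 - pending; r1 <- r1 + pending; len <- len - pending; mm <- mm - pending
  if (circ(f1) == circ(r1) && circ(f2) == circ(r2)) return(NULL)  # self-palindrome
  list(f1 = f1, f2 = f2, r1 = r1, r2 = r2, len = len, mismatches = mm)
}

#' Report genes at the four inverted-repeat junctions
#'
#' For each junction (JLB = LSC/IRb, JSB = IRb/SSC, JSA = SSC/IRa,
#' JLA = IRa/LSC) reports features spanning the junction with the number of
#' bases on each side, and features whose nearest end lies within `near` bp of
#' the junction.
#'
#' @param structure A `quadripartite_structure`.
#' @param record The annotated `genome_record` the structure was detected on.
#' @param near Distance cutoff in bp for nearby genes (default 1000).
#' @return Data frame: `junction`, `gene`, `kind`, `strand`, `relation`
#'   (`"spans"` or `"nearby"`), `bp_left`, `bp_right` (bases of a spanning
#'   gene inside the left/right flanking region), `distance`, `side` (for
#'   nearby genes).
#' @export
junction_report <- function(structure, record, near = 1000L) {
  L <- structure$genome_length
  junctions <- c(
    JLB = structure$lsc[["end"]],
    JSB = structure$irb[["end"]],
    JSA = structure$ssc[["end"]],
    JLA = structure$ira[["end"]]
  )
  feats <- Filter(function(f) f$kind %in% c("CDS", "tRNA", "rRNA"), record$features)
  rows <- list()
  for (jn in names(junctions)) {
    b <- junctions[[jn]]  # last base of the left region; right region starts b+1
    for (f in feats) {
      gs <- min(f$intervals[, 1L]); ge <- max(f$intervals[, 2L])
      glen <- ge - gs + 1L
      s_rot <- (gs - b - 1L) %% L  # 0-based offset of gene start right of junction
      if (s_rot + glen > L) {      # wraps the junction => spans it
        bp_right <- s_rot + glen - L
        bp_left <- glen - bp_right
        rows[[length(rows) + 1L]] <- data.frame(
          junction = jn, gene = f$gene, kind = f$kind, strand = f$strand,
          relation = "spans", bp_left = bp_left, bp_right = bp_right,
          distance = 0L, side = NA_character_)
      } else {
        d_right <- s_rot
        d_left <- L - (s_rot + glen)
        d <- min(d_right, d_left)
        if (d <= near) {
          rows[[length(rows) + 1L]] <- data.frame(
            junction = jn, gene = f$gene, kind = f$kind, strand = f$strand,
            relation = "nearby", bp_left = NA_integer_, bp_right = NA_integer_,
            distance = d,
            side = if (d_right < d_left) "right" else "left")
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(junction = character(0), gene = character(0),
                      kind = character(0), strand = character(0),
                      relation = character(0), bp_left = integer(0),
                      bp_right = integer(0), distance = integer(0),
                      side = character(0)))
  }
  do.call(rbind, rows)
}
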