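#' Specification for the synthetic-data generators
#'
#' Bundles every knob of the seeded generators with defaults mirroring the
#' study conditions the pipeline targets: 50 protein-coding genes longer than
#' 300 bp, an AT-rich third codon position (target GC3 28.2\%), a circular
#' quadripartite genome, and a 3-sequence alignment with localized mutation
#' hotspots. The same spec and seed always produce byte-identical output.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param n_genes Number of coding genes to simulate (default 50).
#' @param length_range CDS length bounds in bp; both multiples of 3 and
#'   `> 300` (default `c(306, 1602)`).
#' @param regime Codon-usage regime: `"uniform"` (no bias; synonymous codons
#'   equiprobable, `target_gc3` ignored), `"mutation_driven"` (each gene gets
#'   one GC level applied at all three positions, so GC3 tracks GC12), or
#'   `"selection_driven"` (amino-acid usage varies per gene but third-position
#'   codon weights are shared and calibrated to `target_gc3`).
#' @param target_gc3 Target third-position GC fraction (default 0.282).
#' @param gc_spread Half-width of the per-gene GC interval in the
#'   mutation-driven regime (default 0.15).
#' @param bias_strength Dispersion of per-family codon weights in the
#'   selection-driven regime; weights are Dirichlet with concentration
#'   `1/bias_strength`, so larger values mean stronger bias (default 1).
#' @param aa_conc Dirichlet concentration for per-gene amino-acid frequencies
#'   in the selection-driven regime (default 10).
#' @param gc3_jitter Standard deviation of the per-gene GC3 optimum around
#'   `target_gc3` in the selection-driven regime, drawn independently of the
#'   amino-acid composition (default 0.04).
#' @param lsc_len,ssc_len,ir_len Region lengths in bp for the genome builder
#'   (defaults 20000, 4000, 6000; `lsc_len > ssc_len`).
#' @param aln_len Alignment length for the alignment builder (default 20000).
#' @param n_seq Number of aligned sequences (default 3).
#' @param background_rate Per-site substitution probability outside hotspots
#'   (default 0.005).
#' @param hotspots Data frame `start`, `end`, `rate` of planted hotspot
#'   windows; default one 800-bp hotspot at 10x the background rate in the
#'   middle of the alignment.
#' @param gap_frac Fraction of alignment columns gapped in one sequence
#'   (default 0).
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed,
                           n_genes = 50L,
                           length_range = c(306L, 1602L),
                           regime = c("uniform", "mutation_driven", "selection_driven"),
                           target_gc3 = 0.282,
                           gc_spread = 0.15,
                           bias_strength = 1,
                           aa_conc = 10,
                           gc3_jitter = 0.04,
                           lsc_len = 20000L, ssc_len = 4000L, ir_len = 6000L,
                           aln_len = 20000L, n_seq = 3L,
                           background_rate = 0.005,
                           hotspots = NULL,
                           gap_frac = 0) {
  regime <- match.arg(regime)
  stopifnot(length(length_range) == 2L, length_range[1L] > 300L,
            length_range[1L] %% 3L == 0L, length_range[2L] %% 3L == 0L,
            length_range[2L] >= length_range[1L],
            target_gc3 > 0, target_gc3 < 1,
            bias_strength > 0, aa_conc > 0, gc3_jitter >= 0,
            lsc_len > ssc_len, ssc_len > 0, ir_len > 0,
            aln_len > 0, n_seq >= 2L,
            background_rate > 0, background_rate < 1,
            gap_frac >= 0, gap_frac < 0.5)
  if (is.null(hotspots)) {
    mid <- aln_len %/% 2L
    hotspots <- data.frame(start = mid - 399L, end = mid + 400L,
                           rate = 10 * background_rate)
  }
  stopifnot(all(hotspots$rate > 0), all(hotspots$rate < 1),
            all(hotspots$start >= 1L), all(hotspots$end <= aln_len),
            all(hotspots$end >= hotspots$start))
  if (any(hotspots$rate <= background_rate)) {
    stop("hotspot rates must exceed the background rate", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         length_range = as.integer(length_range), regime = regime,
         target_gc3 = target_gc3, gc_spread = gc_spread,
         bias_strength = bias_strength, aa_conc = aa_conc,
         gc3_jitter = gc3_jitter,
         lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
         ir_len = as.integer(ir_len),
         aln_len = as.integer(aln_len), n_seq = as.integer(n_seq),
         background_rate = background_rate, hotspots = hotspots,
         gap_frac = gap_frac),
    class = "synthetic_spec"
  )
}

# symmetric Dirichlet draw
rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

# codon probabilities for one family under a third-position GC tilt: codon
# weights are normalized within the A/U-ending and G/C-ending groups and the
# G/C group receives total mass t, so the family's GC3 probability is exactly
# t whenever both endings are available (Met/Trp stay fixed at 1)
tilted_family_probs <- function(w, t) {
  third_gc <- substr(names(w), 3L, 3L) %in% c("G", "C")
  q <- numeric(length(w))
  names(q) <- names(w)
  s_gc <- sum(w[third_gc]); s_au <- sum(w[!third_gc])
  if (s_gc > 0 && s_au > 0) {
    q[third_gc] <- t * w[third_gc] / s_gc
    q[!third_gc] <- (1 - t) * w[!third_gc] / s_au
  } else {
    q <- w / sum(w)
  }
  q
}

# expected GC3 fraction given amino-acid frequencies, per-family codon
# weights, and a third-position GC tilt t
expected_gc3_given <- function(t, aa_freq, fam_weights) {
  aa <- names(.aa_families)
  gcp <- vapply(aa, function(a) {
    q <- tilted_family_probs(fam_weights[[a]], t)
    third_gc <- substr(names(q), 3L, 3L) %in% c("G", "C")
    sum(q[third_gc])
  }, numeric(1))
  sum(aa_freq[aa] * gcp)
}

# solve the tilt so that expected GC3 hits the target. Small shortfalls
# (< 0.05) caused by a gene's particular amino-acid draw (Met/Trp force
# G-ending codons and raise the floor) are clamped to the nearest achievable
# value; larger gaps mean the target itself is unreachable and error out.
solve_gc3_tilt <- function(target, aa_freq, fam_weights) {
  f <- function(t) expected_gc3_given(t, aa_freq, fam_weights) - target
  lo <- f(1e-6); hi <- f(1 - 1e-6)
  if (lo > 0 || hi < 0) {
    gap <- if (lo > 0) lo else -hi
    if (gap > 0.05) {
      stop("infeasible target_gc3 = ", target, ": achievable range is [",
           round(target + lo, 4), ", ", round(target + hi, 4), "]", call. = FALSE)
    }
    return(if (lo > 0) 1e-6 else 1 - 1e-6)
  }
  stats::uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-9)$root
}

#' Simulate a set of coding sequences with known codon-usage ground truth
#'
#' Builds `n_genes` in-frame genes codon by codon (ATG start, canonical stop,
#' no internal stops, length > 300 bp), under one of three regimes:
#' `"uniform"` draws every synonymous codon equiprobably (the no-bias control,
#' ENC near 61); `"mutation_driven"` gives each gene a single GC level that
#' shapes all three codon positions alike (so GC12 tracks GC3 across genes);
#' `"selection_driven"` varies amino-acid composition between genes while the
#' third position follows fixed, shared family weights calibrated so each
#' gene's expected GC3 equals `target_gc3`.
#'
#' @param spec A `synthetic_spec`.
#' @return List: `cds` (named character vector of DNA sequences that all pass
#'   [filter_cds()]), `truth` (data frame `gene`, `length`, `regime`,
#'   `gene_gc`, `target_gc3`, `realized_gc3`), `fam_weights` (the realized
#'   per-family codon weight vectors), `spec`.
#' @export
simulate_cds_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    aa <- names(.aa_families)
    fam_weights <- lapply(aa, function(a) {
      k <- length(.aa_families[[a]])
      w <- switch(spec$regime,
        uniform = rep(1 / k, k),
        mutation_driven = rep(1 / k, k),
        selection_driven = rdirichlet1(k, 1 / spec$bias_strength))
      stats::setNames(w, .aa_families[[a]])
    })
    names(fam_weights) <- aa

    lens <- sample(seq(spec$length_range[1L], spec$length_range[2L], by = 3L),
                   spec$n_genes, replace = TRUE)
    genes <- character(spec$n_genes)
    gene_gc <- rep(NA_real_, spec$n_genes)
    tgt <- rep(NA_real_, spec$n_genes)

    for (i in seq_len(spec$n_genes)) {
      n_int <- lens[i] %/% 3L - 2L
      if (spec$regime == "mutation_driven") {
        g <- stats::runif(1, max(0.05, spec$target_gc3 - spec$gc_spread),
                          min(0.95, spec$target_gc3 + spec$gc_spread))
        gene_gc[i] <- g
        pb <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, U = (1 - g) / 2)
        pc <- pb[substr(.sense_codons, 1, 1)] *
          pb[substr(.sense_codons, 2, 2)] *
          pb[substr(.sense_codons, 3, 3)]
        internal <- sample(.sense_codons, n_int, replace = TRUE, prob = pc)
      } else {
        aa_freq <- if (spec$regime == "selection_driven") {
          stats::setNames(rdirichlet1(length(aa), spec$aa_conc), aa)
        } else {
          stats::setNames(rep(1 / length(aa), length(aa)), aa)
        }
        aas <- sample(aa, n_int, replace = TRUE, prob = aa_freq)
        internal <- character(n_int)
        if (spec$regime == "selection_driven") {
          tgt_i <- min(max(spec$target_gc3 + stats::rnorm(1, 0, spec$gc3_jitter),
                           0.05), 0.95)
          t <- solve_gc3_tilt(tgt_i, aa_freq, fam_weights)
          tgt[i] <- tgt_i
          for (a in unique(aas)) {
            q <- tilted_family_probs(fam_weights[[a]], t)
            idx <- which(aas == a)
            internal[idx] <- sample(names(q), length(idx), replace = TRUE, prob = q)
          }
        } else {  # uniform: every synonymous codon equiprobable
          for (a in unique(aas)) {
            fam <- .aa_families[[a]]
            idx <- which(aas == a)
            internal[idx] <- sample(fam, length(idx), replace = TRUE)
          }
        }
      }
      stop_c <- sample(.stop_codons, 1L)
      genes[i] <- gsub("U", "T", paste(c("AUG", internal, stop_c), collapse = ""))
    }
    names(genes) <- sprintf("g%03d", seq_len(spec$n_genes))

    realized <- vapply(genes, function(s) {
      gc_by_position(count_codons(s))[["gc3"]] / 100
    }, numeric(1))
    list(cds = genes,
         truth = data.frame(gene = names(genes), length = lens,
                            regime = spec$regime, gene_gc = gene_gc,
                            target_gc3 = tgt, realized_gc3 = unname(realized)),
         fam_weights = fam_weights,
         spec = spec)
  })
}

#' Simulate a circular quadripartite genome with planted genes
#'
#' Builds a circular genome LSC + IRb + SSC + IRa where IRa is the exact
#' reverse complement of IRb, splices planted gene sequences into the
#' background, and annotates them as GenBank-style features. Genes planted
#' fully inside IRb are automatically mirrored into IRa as duplicate copies on
#' the opposite strand (the plastome IR duplication). Planted genes may
#' straddle region boundaries; they must lie within LSC..SSC (IRa is derived).
#'
#' @param spec A `synthetic_spec` (uses `lsc_len`, `ssc_len`, `ir_len`,
#'   `seed`).
#' @param planted_genes List of placements, each a list with fields `gene`,
#'   `seq` (DNA string), `start` (1-based genome coordinate) or `intervals`
#'   (matrix of exon spans whose total length equals `nchar(seq)`), optional
#'   `kind` (default `"CDS"`) and `strand` (default `"+"`; the written genome
#'   carries the reverse complement for minus-strand genes so that extraction
#'   recovers `seq`).
#' @param rotate Rotate the finished circle so it starts at this offset
#'   (0 = no rotation); features are remapped accordingly.
#' @return A `genome_record`.
#' @export
simulate_genome <- function(spec, planted_genes = list(), rotate = 0L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 1L, {
    lsc <- spec$lsc_len; ir <- spec$ir_len; ssc <- spec$ssc_len
    total <- lsc + 2L * ir + ssc
    irb_start <- lsc + 1L; irb_end <- lsc + ir
    ssc_end <- lsc + ir + ssc
    core_len <- ssc_end  # LSC + IRb + SSC; IRa derived afterwards
    core <- sample(c("A", "C", "G", "T"), core_len, replace = TRUE)

    features <- list()
    for (pg in planted_genes) {
      kind <- pg$kind %||% "CDS"
      strand <- pg$strand %||% "+"
      s <- toupper(pg$seq)
      ivs <- if (!is.null(pg$intervals)) {
        m <- pg$intervals
        if (is.vector(m)) m <- matrix(m, ncol = 2L, byrow = TRUE)
        m
      } else {
        matrix(c(pg$start, pg$start + nchar(s) - 1L), ncol = 2L)
      }
      storage.mode(ivs) <- "integer"
      if (sum(ivs[, 2L] - ivs[, 1L] + 1L) != nchar(s)) {
        stop("planted gene ", pg$gene, ": interval lengths do not match sequence",
             call. = FALSE)
      }
      if (any(ivs < 1L) || any(ivs > core_len)) {
        stop("planted gene ", pg$gene, " exceeds region bounds (must lie in LSC..SSC)",
             call. = FALSE)
      }
      written <- if (strand == "-") revcomp_chr(s) else s
      # genomic (plus-strand) pieces in genome order
      offset <- 0L
      for (r in seq_len(nrow(ivs))) {
        w <- ivs[r, 2L] - ivs[r, 1L] + 1L
        piece <- substr(written, offset + 1L, offset + w)
        core[ivs[r, 1L]:ivs[r, 2L]] <- strsplit(piece, "")[[1L]]
        offset <- offset + w
      }
      features[[length(features) + 1L]] <-
        gene_feature(pg$gene, kind = kind, strand = strand, intervals = ivs)
    }

    # make the planted IR pair maximal: a chance complementary base just
    # outside both repeat copies would let the true maximal repeat exceed the
    # planted length, so break such pairs at the four junction flanks
    covered <- unlist(lapply(features, function(f) {
      unlist(apply(f$intervals, 1L, function(iv) iv[1L]:iv[2L], simplify = FALSE))
    }))
    comp1 <- c(A = "T", C = "G", G = "C", T = "A")
    break_pair <- function(core, i, j) {
      if (core[i] != comp1[[core[j]]]) return(core)
      if (!(i %in% covered)) {
        core[i] <- setdiff(c("A", "C", "G", "T"), comp1[[core[j]]])[1L]
      } else if (!(j %in% covered)) {
        core[j] <- setdiff(c("A", "C", "G", "T"), comp1[[core[i]]])[1L]
      }
      core
    }
    core <- break_pair(core, lsc, 1L)              # LSC end vs LSC start (JLA side)
    core <- break_pair(core, irb_end + 1L, ssc_end) # SSC start vs SSC end

    # IRa = reverse complement of IRb
    irb_seq <- paste(core[irb_start:irb_end], collapse = "")
    sequence <- paste0(paste(core, collapse = ""), revcomp_chr(irb_seq))

    # mirror genes fully inside IRb into IRa (duplicates, opposite strand)
    ira_start <- ssc_end + 1L
    for (f in features) {
      gs <- min(f$intervals[, 1L]); ge <- max(f$intervals[, 2L])
      if (gs >= irb_start && ge <= irb_end) {
        m_ivs <- cbind(ira_start + (irb_end - f$intervals[, 2L]),
                       ira_start + (irb_end - f$intervals[, 1L]))
        m_ivs <- m_ivs[rev(seq_len(nrow(m_ivs))), , drop = FALSE]
        features[[length(features) + 1L]] <-
          gene_feature(f$gene, kind = f$kind,
                       strand = if (f$strand == "+") "-" else "+",
                       intervals = m_ivs,
                       copy_tag = "IRa")
      }
    }

    rec <- genome_record(id = sprintf("SYN%07d", spec$seed %% 10000000L),
                         sequence = sequence, circular = TRUE,
                         features = features)
    if (rotate != 0L) rec <- rotate_genome(rec, rotate) else rec
  })
}

#' Rotate a circular genome record
#'
#' Moves the origin of a circular record by `offset` bases; feature intervals
#' are remapped (intervals running past the new end wrap, expressed with
#' `end > length`, which [extract_cds()] handles on circular records).
#'
#' @param record A circular `genome_record`.
#' @param offset Number of bases to rotate by (new origin = old
#'   `offset + 1`).
#' @return The rotated `genome_record`.
#' @export
rotate_genome <- function(record, offset) {
  stopifnot(record$circular)
  L <- record$length
  offset <- offset %% L
  if (offset == 0L) return(record)
  seq2 <- paste0(substr(record$sequence, offset + 1L, L),
                 substr(record$sequence, 1L, offset))
  feats <- lapply(record$features, function(f) {
    iv <- f$intervals
    ns <- wrap_pos(iv[, 1L] - offset, L)
    width <- iv[, 2L] - iv[, 1L]
    f$intervals <- cbind(start = as.integer(ns), end = as.integer(ns + width))
    f
  })
  genome_record(record$id, seq2, circular = TRUE, features = feats)
}

#' Simulate an alignment with planted mutation hotspots
#'
#' Generates `n_seq` sequences by mutating a common ancestor independently at
#' each site, with per-site substitution probability given by the background
#' rate except inside the planted hotspot windows. Optional gap blocks are
#' placed in the last sequence. Returns the true hotspot intervals for
#' recovery tests.
#'
#' @param spec A `synthetic_spec` (uses `aln_len`, `n_seq`,
#'   `background_rate`, `hotspots`, `gap_frac`, `seed`).
#' @param ancestor Optional ancestor string (e.g. a simulated genome
#'   sequence); its length overrides `aln_len`.
#' @return List: `aln` (named character vector of aligned sequences),
#'   `truth` (hotspot data frame), `ancestor`.
#' @export
simulate_alignment <- function(spec, ancestor = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 2L, {
    bases <- c("A", "C", "G", "T")
    if (is.null(ancestor)) {
      L <- spec$aln_len
      anc <- sample(bases, L, replace = TRUE)
    } else {
      anc <- strsplit(toupper(ancestor), "")[[1L]]
      L <- length(anc)
    }
    rate <- rep(spec$background_rate, L)
    hs <- spec$hotspots
    for (r in seq_len(nrow(hs))) {
      to <- min(hs$end[r], L)
      rate[hs$start[r]:to] <- hs$rate[r]
    }
    aln <- vapply(seq_len(spec$n_seq), function(k) {
      s <- anc
      hit <- which(stats::runif(L) < rate)
      if (length(hit)) {
        s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1L),
                         character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    names(aln) <- sprintf("ind%d", seq_len(spec$n_seq))
    if (spec$gap_frac > 0) {
      n_gap <- round(spec$gap_frac * L)
      block <- 30L
      starts <- sample(seq_len(L - block), max(1L, n_gap %/% block))
      gchars <- strsplit(aln[[spec$n_seq]], "")[[1L]]
      for (st in starts) gchars[st:(st + block - 1L)] <- "-"
      aln[[spec$n_seq]] <- paste(gchars, collapse = "")
    }
    list(aln = aln, truth = hs[hs$end <= L, , drop = FALSE],
         ancestor = paste(anc, collapse = ""))
  })
}
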