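#' Sliding-window nucleotide diversity over an alignment
#'
#' Computes per-window nucleotide diversity (pi): the mean over sequence pairs
#' of per-site differences, with complete deletion of alignment columns that
#' contain any gap or ambiguity symbol inside the window (the DnaSP default).
#' Windows advance by `step` along alignment coordinates; the terminal partial
#' window is reported with its true span. Columns of the first sequence are
#' also mapped to its ungapped coordinates for downstream labeling.
#'
#' @param aln Named character vector of >= 2 aligned sequences of equal
#'   length, a `DNAStringSet`, or a FASTA file path.
#' @param window Window length in alignment bp (default 800).
#' @param step Step size in alignment bp (default 200).
#' @param gap_mode `"complete"` (default; columns with any gap excluded
#'   within each window) or `"pairwise"` (each pair uses its own gap-free
#'   columns).
#' @return A `diversity_profile` list: `windows` (data frame `start`, `end`,
#'   `midpoint`, `ref_start`, `ref_end`, `n_sites`, `pi`), `window`, `step`,
#'   `n_seq`, `aln_length`, `global_pi`.
#' @export
sliding_window_pi <- function(aln, window = 800L, step = 200L,
                              gap_mode = c("complete", "pairwise")) {
  gap_mode <- match.arg(gap_mode)
  aln <- as_alignment(aln)
  n <- length(aln)
  if (n < 2L) stop("need at least 2 aligned sequences", call. = FALSE)
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("aligned sequences must have equal length", call. = FALSE)
  M <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  valid_col <- colSums(matrix(M %in% c("A", "C", "G", "T"), nrow = n)) == n

  pairs <- utils::combn(n, 2L)
  diff_pair <- lapply(seq_len(ncol(pairs)), function(k) {
    M[pairs[1L, k], ] != M[pairs[2L, k], ]
  })
  pair_valid <- lapply(seq_len(ncol(pairs)), function(k) {
    M[pairs[1L, k], ] %in% c("A", "C", "G", "T") &
      M[pairs[2L, k], ] %in% c("A", "C", "G", "T")
  })

  starts <- seq(1L, max(1L, L - window + 1L), by = step)
  if (max(starts) + window - 1L < L) starts <- c(starts, max(starts) + step)
  ends <- pmin(starts + window - 1L, L)

  ref_pos <- cumsum(M[1L, ] != "-")
  win_pi <- function(s, e) {
    cols <- s:e
    if (gap_mode == "complete") {
      use <- cols[valid_col[cols]]
      ns <- length(use)
      if (ns == 0L) return(c(NA_real_, 0))
      pi <- mean(vapply(diff_pair, function(dv) sum(dv[use]) / ns, numeric(1)))
      c(pi, ns)
    } else {
      vals <- vapply(seq_along(diff_pair), function(k) {
        use <- cols[pair_valid[[k]][cols]]
        if (length(use) == 0L) return(NA_real_)
        sum(diff_pair[[k]][use]) / length(use)
      }, numeric(1))
      c(mean(vals, na.rm = TRUE), sum(valid_col[cols]))
    }
  }
  res <- vapply(seq_along(starts), function(i) win_pi(starts[i], ends[i]),
                numeric(2))
  g <- win_pi(1L, L)
  structure(
    list(windows = data.frame(
           start = starts, end = ends,
           midpoint = (starts + ends) / 2,
           ref_start = ref_pos[starts], ref_end = ref_pos[ends],
           n_sites = as.integer(res[2L, ]), pi = res[1L, ]),
         window = window, step = step, n_seq = n, aln_length = L,
         global_pi = g[1L]),
    class = "diversity_profile"
  )
}

as_alignment <- function(aln) {
  if (is.character(aln) && length(aln) == 1L && file.exists(aln)) {
    aln <- Biostrings::readBStringSet(aln)
  }
  if (methods::is(aln, "XStringSet")) {
    aln <- stats::setNames(as.character(aln), names(aln))
  }
  aln
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat(sprintf("<diversity_profile> %d windows (%d/%d bp) over %d seqs; global pi = %.5f\n",
              nrow(x$windows), x$window, x$step, x$n_seq, x$global_pi))
  invisible(x)
}

#' Call hypervariable regions from a diversity profile
#'
#' Takes the `top_k` windows by pi, merges overlapping windows into disjoint
#' regions, and labels each region by the annotation of the reference record:
#' the overlapping gene with the largest overlap, or the flanking gene pair
#' `"geneA-geneB"` (in genome order) for intergenic regions.
#'
#' @param profile A `diversity_profile`.
#' @param record Optional annotated `genome_record` whose coordinates match
#'   the first alignment sequence (regions are mapped through `ref_start`/
#'   `ref_end`). Without it regions are labelled `region_1`, `region_2`, ...
#' @param top_k Number of top windows to use (default 7).
#' @return Data frame: `start`, `end` (alignment coords), `ref_start`,
#'   `ref_end`, `peak_pi`, `n_windows`, `label`, ordered by decreasing
#'   `peak_pi`.
#' @export
hypervariable_regions <- function(profile, record = NULL, top_k = 7L) {
  w <- profile$windows[!is.na(profile$windows$pi), , drop = FALSE]
  if (top_k > nrow(w)) {
    warning("top_k = ", top_k, " exceeds ", nrow(w), " usable windows; returning all")
    top_k <- nrow(w)
  }
  if (stats::var(w$pi) == 0) {
    warning("flat diversity profile: window ranking is arbitrary (ties)")
  }
  top <- w[order(-w$pi, w$start), ][seq_len(top_k), ]
  top <- top[order(top$start), ]
  # merge overlapping/adjacent windows
  regions <- list()
  cur <- top[1L, ]
  cur$n_windows <- 1L
  for (i in seq_len(nrow(top))[-1L]) {
    if (top$start[i] <= cur$end + 1L) {
      cur$end <- max(cur$end, top$end[i])
      cur$ref_end <- max(cur$ref_end, top$ref_end[i])
      cur$pi <- max(cur$pi, top$pi[i])
      cur$n_windows <- cur$n_windows + 1L
    } else {
      regions[[length(regions) + 1L]] <- cur
      cur <- top[i, ]
      cur$n_windows <- 1L
    }
  }
  regions[[length(regions) + 1L]] <- cur
  out <- do.call(rbind, regions)
  out <- data.frame(start = out$start, end = out$end,
                    ref_start = out$ref_start, ref_end = out$ref_end,
                    peak_pi = out$pi, n_windows = out$n_windows)
  out$label <- if (is.null(record)) {
    sprintf("region_%d", seq_len(nrow(out)))
  } else {
    vapply(seq_len(nrow(out)), function(i) {
      region_label(out$ref_start[i], out$ref_end[i], record)
    }, character(1))
  }
  out[order(-out$peak_pi, out$start), ]
}

# label an interval by overlapping gene (max overlap) or flanking gene pair
region_label <- function(s, e, record) {
  feats <- Filter(function(f) f$kind %in% c("CDS", "tRNA", "rRNA"), record$features)
  if (length(feats) == 0L) return(sprintf("%d-%d", s, e))
  spans <- t(vapply(feats, function(f) {
    c(min(f$intervals[, 1L]), max(f$intervals[, 2L]))
  }, integer(2)))
  genes <- vapply(feats, `[[`, character(1), "gene")
  ov <- pmin(spans[, 2L], e) - pmax(spans[, 1L], s) + 1L
  if (any(ov > 0L)) return(genes[which.max(ov)])
  left <- which(spans[, 2L] < s)
  right <- which(spans[, 1L] > e)
  L <- record$length
  left_gene <- if (length(left)) genes[left[which.max(spans[left, 2L])]] else {
    # wrap: last gene on the circle
    genes[which.max(spans[, 2L])]
  }
  right_gene <- if (length(right)) genes[right[which.min(spans[right, 1L])]] else {
    genes[which.min(spans[, 1L])]
  }
  paste0(left_gene, "-", right_gene)
}
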