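#' Rank genes into putative expression groups by ENC
#'
#' Following the standard low-ENC = strong-bias = high-expression convention,
#' the high-expression group is the `ceiling(fraction * N)` genes with the
#' LOWEST ENC and the low-expression group the same number with the highest
#' ENC. Ties are broken deterministically by gene name. `swap_groups = TRUE`
#' reverses the convention (highest-ENC genes labelled high expression).
#'
#' @param profiles Profile data frame from [codon_profiles()].
#' @param fraction Fraction of genes per group (default 0.10, i.e. 5 of 50).
#' @param swap_groups Reverse the ENC convention.
#' @return List with character vectors `high` and `low` (gene names) and
#'   `group_size`.
#' @export
rank_expression_groups <- function(profiles, fraction = 0.10, swap_groups = FALSE) {
  usable <- profiles[!is.na(profiles$enc), , drop = FALSE]
  k <- ceiling(fraction * nrow(usable))
  if (k < 1L || nrow(usable) <= 2L * k) {
    stop("needs more than ", 2L * max(k, 1L), " genes with defined ENC, have ",
         nrow(usable), call. = FALSE)
  }
  if (length(unique(usable$enc)) == 1L) {
    warning("all ENC values are equal; groups determined by gene-name order")
  }
  ord <- usable[order(usable$enc, usable$gene), ]
  low_enc <- ord$gene[seq_len(k)]
  high_enc <- rev(ord$gene)[seq_len(k)]
  if (swap_groups) {
    list(high = sort(high_enc), low = sort(low_enc), group_size = k)
  } else {
    list(high = sort(low_enc), low = sort(high_enc), group_size = k)
  }
}

#' Star class for a delta-RSCU value
#'
#' Bins preferred codons by the strength of the RSCU difference between the
#' high- and low-expression groups: `*` for 0.08 <= delta < 0.30, `**` for
#' 0.30 <= delta < 0.50, `***` for delta >= 0.50, empty below 0.08.
#'
#' @param delta Numeric vector of RSCU differences.
#' @return Character vector of star marks.
#' @export
delta_rscu_star <- function(delta) {
  out <- character(length(delta))
  out[delta >= 0.08] <- "*"
  out[delta >= 0.30] <- "**"
  out[delta >= 0.50] <- "***"
  out
}

#' Identify optimal codons from high/low-expression gene groups
#'
#' Group RSCU values are computed on POOLED codon counts within each group.
#' `delta_rscu = rscu_high - rscu_low`; codons with delta >= `delta_threshold`
#' are high-expression preferred. High-frequency codons have RSCU > 1 on the
#' pooled full gene set. Optimal codons are the intersection of the two sets.
#'
#' @param cds Named character vector of coding sequences (or `cds_set`)
#'   covering every gene in `profiles`.
#' @param profiles Profile data frame from [codon_profiles()].
#' @param fraction,swap_groups Passed to [rank_expression_groups()].
#' @param delta_threshold Closed lower bound for preferred codons (0.08).
#' @return An `optimal_codon_report` list: `report` (data frame with one row
#'   per sense codon: `amino_acid`, `codon`, `rscu_high`, `n_high`,
#'   `rscu_low`, `n_low`, `rscu_all`, `delta_rscu`, `star_class`,
#'   `is_high_frequency`, `is_optimal`), plus `high_genes`, `low_genes`.
#' @export
identify_optimal_codons <- function(cds, profiles, fraction = 0.10,
                                    delta_threshold = 0.08,
                                    swap_groups = FALSE) {
  if (inherits(cds, "cds_set")) cds <- cds$entries
  groups <- rank_expression_groups(profiles, fraction, swap_groups)
  cnt_high <- pooled_counts(cds, groups$high)
  cnt_low <- pooled_counts(cds, groups$low)
  cnt_all <- pooled_counts(cds, profiles$gene)
  rscu_high <- compute_rscu(cnt_high)
  rscu_low <- compute_rscu(cnt_low)
  rscu_all <- compute_rscu(cnt_all)

  rep <- data.frame(
    amino_acid = unname(.codon_table[.sense_codons]),
    codon = .sense_codons,
    rscu_high = unname(rscu_high),
    n_high = unname(cnt_high$counts[.sense_codons]),
    rscu_low = unname(rscu_low),
    n_low = unname(cnt_low$counts[.sense_codons]),
    rscu_all = unname(rscu_all)
  )
  rep$delta_rscu <- rep$rscu_high - rep$rscu_low
  rep$star_class <- ifelse(is.na(rep$delta_rscu), "",
                           delta_rscu_star(rep$delta_rscu))
  rep$is_high_frequency <- !is.na(rep$rscu_all) & rep$rscu_all > 1
  rep$is_optimal <- !is.na(rep$delta_rscu) &
    rep$delta_rscu >= delta_threshold & rep$is_high_frequency
  rep <- rep[order(rep$amino_acid, rep$codon), ]
  rownames(rep) <- NULL
  structure(list(report = rep, high_genes = groups$high,
                 low_genes = groups$low),
            class = "optimal_codon_report")
}

#' @export
print.optimal_codon_report <- function(x, ...) {
  opt <- x$report[x$report$is_optimal, ]
  cat(sprintf("<optimal_codon_report> %d optimal codons: %s\n",
              nrow(opt), paste(opt$codon, collapse = ", ")))
  invisible(x)
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 (mean of GC1 and GC2) on GC3 across genes.
#' A slope near 1 indicates composition driven by mutation pressure acting on
#' all codon positions alike; a slope near 0 indicates selective constraint on
#' positions 1-2. The slope times 100 is read as the percent contribution of
#' mutation, and its complement as that of natural selection.
#'
#' @param profiles Profile data frame with at least 3 genes.
#' @return List: `slope`, `intercept`, `r`, `p_value` (two-tailed Pearson),
#'   `mutation_pct`, `selection_pct`, `n`.
#' @export
neutrality_analysis <- function(profiles) {
  d <- profiles[!is.na(profiles$gc3) & !is.na(profiles$gc12), , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 genes", call. = FALSE)
  if (stats::var(d$gc3) == 0) stop("GC3 has zero variance: slope undefined", call. = FALSE)
  fit <- stats::lm(gc12 ~ gc3, data = d)
  ct <- stats::cor.test(d$gc3, d$gc12, method = "pearson")
  slope <- unname(stats::coef(fit)[2L])
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1L]),
       r = unname(ct$estimate),
       p_value = ct$p.value,
       mutation_pct = 100 * slope,
       selection_pct = 100 * (1 - slope),
       n = nrow(d))
}

#' ENC-plot analysis against the expected-ENC curve
#'
#' For every gene with a defined ENC, computes the expected ENC at its GC3,
#' the relative departure `enc_ratio = (enc_exp - enc_obs)/enc_exp`, a
#' left-closed histogram of the ratios in bins of width 0.05 aligned so that
#' \[-0.05, 0.05\] spans exactly two bins, and the number of genes whose ratio
#' lies in the closed interval \[-0.05, 0.05\] (genes effectively on the
#' curve, i.e. compatible with mutation pressure alone).
#'
#' @param profiles Profile data frame.
#' @return List: `table` (gene, gc3, enc_obs, enc_exp, enc_ratio), `histogram`
#'   (bin_left, bin_right, count; left-closed bins), `n_within`, `n_outside`.
#' @export
enc_plot_analysis <- function(profiles) {
  d <- profiles[!is.na(profiles$enc) & !is.na(profiles$gc3), , drop = FALSE]
  enc_exp <- expected_enc(d$gc3 / 100)
  ratio <- (enc_exp - d$enc) / enc_exp
  tab <- data.frame(gene = d$gene, gc3 = d$gc3, enc_obs = d$enc,
                    enc_exp = enc_exp, enc_ratio = ratio)
  idx <- floor(round(ratio / 0.05, 9))   # left-closed bins [k*0.05, (k+1)*0.05)
  rng <- seq(min(idx), max(idx))
  hist <- data.frame(bin_left = rng * 0.05, bin_right = (rng + 1) * 0.05,
                     count = as.integer(table(factor(idx, levels = rng))))
  n_within <- sum(ratio >= -0.05 & ratio <= 0.05)
  list(table = tab, histogram = hist,
       n_within = n_within, n_outside = nrow(d) - n_within)
}

#' PR2 quadrant summary
#'
#' Assigns each gene's PR2 coordinates to a quadrant around the parity point
#' (0.5, 0.5) and counts genes with `x > 0.5` (G3 over C3) and `y < 0.5`
#' (T3 over A3).
#'
#' @param profiles Profile data frame (needs `pr2_x`, `pr2_y`).
#' @return List: `table` (gene, x, y, quadrant), `quadrant_counts` (named
#'   vector over upper_left/upper_right/lower_left/lower_right/boundary),
#'   `n_x_gt_half`, `n_y_lt_half`, `n_defined`.
#' @export
pr2_analysis <- function(profiles) {
  d <- profiles[!is.na(profiles$pr2_x) & !is.na(profiles$pr2_y), , drop = FALSE]
  quadrant <- ifelse(d$pr2_x == 0.5 | d$pr2_y == 0.5, "boundary",
              ifelse(d$pr2_x > 0.5,
                     ifelse(d$pr2_y > 0.5, "upper_right", "lower_right"),
                     ifelse(d$pr2_y > 0.5, "upper_left", "lower_left")))
  lvls <- c("upper_left", "upper_right", "lower_left", "lower_right", "boundary")
  counts <- table(factor(quadrant, levels = lvls))
  list(table = data.frame(gene = d$gene, x = d$pr2_x, y = d$pr2_y,
                          quadrant = quadrant),
       quadrant_counts = stats::setNames(as.integer(counts), lvls),
       n_x_gt_half = sum(d$pr2_x > 0.5),
       n_y_lt_half = sum(d$pr2_y < 0.5),
       n_defined = nrow(d))
}

#' Pairwise Pearson correlations among codon parameters
#'
#' Correlates GC1, GC2, GC3, GC_all, ENC and codon number across genes, with
#' two-tailed p-values (t transformation, n - 2 df, as in `cor.test`) and the
#' usual significance stars.
#'
#' @param profiles Profile data frame with at least 3 genes.
#' @return List of matrices `r`, `p`, `stars` over the six parameters.
#' @export
correlation_matrix <- function(profiles) {
  vars <- c(GC1 = "gc1", GC2 = "gc2", GC3 = "gc3", GC_all = "gc_all",
            ENC = "enc", codon_number = "n_codons")
  d <- profiles[stats::complete.cases(profiles[, unname(vars)]), unname(vars)]
  if (nrow(d) < 3L) stop("need at least 3 complete genes", call. = FALSE)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(names(vars), names(vars)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    if (stats::sd(d[[i]]) == 0 || stats::sd(d[[j]]) == 0) {
      warning("constant column: correlation undefined for ",
              names(vars)[i], "/", names(vars)[j])
      next
    }
    ct <- stats::cor.test(d[[i]], d[[j]], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  stars <- matrix("", k, k, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  diag(stars) <- ""
  list(r = r, p = p, stars = stars, n = nrow(d))
}
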