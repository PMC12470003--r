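test_that("expression groups recover planted strongly biased genes via low ENC", {
  spA <- synthetic_spec(seed = 11L, n_genes = 5L, regime = "selection_driven",
                        bias_strength = 10)
  spB <- synthetic_spec(seed = 12L, n_genes = 45L, regime = "uniform")
  cds <- c(setNames(simulate_cds_set(spA)$cds, sprintf("biased%02d", 1:5)),
           setNames(simulate_cds_set(spB)$cds, sprintf("plain%02d", 1:45)))
  prof <- codon_profiles(filter_cds(cds))
  gr <- rank_expression_groups(prof, fraction = 0.10)
  expect_equal(gr$group_size, 5L)
  expect_setequal(gr$high, sprintf("biased%02d", 1:5))
  expect_true(all(grepl("^plain", gr$low)))

  # swap_groups reverses the convention
  sw <- rank_expression_groups(prof, fraction = 0.10, swap_groups = TRUE)
  expect_identical(sw$high, gr$low)

  # ties broken by name, with a warning when all ENC are equal
  tied <- data.frame(gene = c("d", "b", "a", "c"), enc = rep(50, 4))
  expect_warning(grt <- rank_expression_groups(tied, fraction = 0.25), "equal")
  expect_identical(grt$high, "a")
  expect_identical(grt$low, "d")

  # groups must not exhaust the gene set: 4 genes at fraction 0.5 is unusable
  expect_error(rank_expression_groups(prof[1:4, ], fraction = 0.5), "more than")
})

test_that("optimal codons combine pooled delta-RSCU with pooled high frequency", {
  spA <- synthetic_spec(seed = 11L, n_genes = 5L, regime = "selection_driven",
                        bias_strength = 10)
  spB <- synthetic_spec(seed = 12L, n_genes = 45L, regime = "uniform")
  cds <- c(setNames(simulate_cds_set(spA)$cds, sprintf("biased%02d", 1:5)),
           setNames(simulate_cds_set(spB)$cds, sprintf("plain%02d", 1:45)))
  prof <- codon_profiles(filter_cds(cds))
  oc <- identify_optimal_codons(cds, prof)
  rep <- oc$report

  # pooled-count bookkeeping: group RSCU recomputes from the printed counts
  cnt_high <- pooled_counts(cds, oc$high_genes)
  expect_equal(rep$n_high, unname(cnt_high$counts[rep$codon]))
  expect_equal(rep$delta_rscu, rep$rscu_high - rep$rscu_low)

  # the optimal flag is exactly the conjunction
  expect_equal(rep$is_optimal,
               !is.na(rep$delta_rscu) & rep$delta_rscu >= 0.08 & rep$is_high_frequency)
  expect_gt(sum(rep$is_optimal), 0)

  # report is sorted by amino acid then codon and covers all 61 sense codons
  expect_equal(nrow(rep), 61L)
  expect_false(is.unsorted(rep$amino_acid))
})

test_that("identical codon usage in the two groups yields zero optimal codons", {
  g <- dna_gene("AUG", rep(c("GCU", "GCA", "AAA", "CUG", "UUU"), 30), "UAA")
  cds <- setNames(rep(g, 10), sprintf("g%02d", 1:10))
  prof <- codon_profiles(cds)
  expect_warning(oc <- identify_optimal_codons(cds, prof, fraction = 0.10), "equal")
  expect_true(all(oc$report$delta_rscu[!is.na(oc$report$delta_rscu)] == 0))
  expect_equal(sum(oc$report$is_optimal), 0L)
})

test_that("star classes partition the delta-RSCU axis with closed left edges", {
  expect_identical(delta_rscu_star(c(0.079999, 0.08, 0.299999, 0.30, 0.499999, 0.5, 2)),
                   c("", "*", "*", "**", "**", "***", "***"))
  # no gaps/overlaps across a fine grid
  grid <- seq(0.08, 1.2, by = 1e-3)
  stars <- delta_rscu_star(grid)
  expect_true(all(stars %in% c("*", "**", "***")))
  expect_true(!is.unsorted(match(stars, c("*", "**", "***"))))
})

test_that("neutrality regression matches brute-force OLS and its limiting cases", {
  sp <- synthetic_spec(seed = 21L, regime = "mutation_driven")
  prof <- codon_profiles(filter_cds(simulate_cds_set(sp)$cds))
  nt <- neutrality_analysis(prof)
  expect_equal(nt$slope, oracle_slope(prof$gc3, prof$gc12), tolerance = 1e-12)
  expect_equal(nt$mutation_pct + nt$selection_pct, 100)
  expect_equal(nt$r, stats::cor(prof$gc3, prof$gc12), tolerance = 1e-12)

  # pure-mutation limit: GC12 = GC3 exactly
  diag_prof <- data.frame(gene = letters[1:5], gc3 = c(10, 20, 30, 40, 50),
                          gc12 = c(10, 20, 30, 40, 50))
  ntd <- neutrality_analysis(diag_prof)
  expect_equal(ntd$slope, 1)
  expect_equal(ntd$selection_pct, 0)

  # pure-selection limit: GC12 constant (cor.test warns about zero variance)
  flat_prof <- data.frame(gene = letters[1:5], gc3 = c(10, 20, 30, 40, 50),
                          gc12 = rep(40, 5))
  ntf <- suppressWarnings(neutrality_analysis(flat_prof))
  expect_equal(ntf$slope, 0)
  expect_equal(ntf$selection_pct, 100)

  const <- data.frame(gene = letters[1:5], gc3 = rep(30, 5), gc12 = 1:5 * 10)
  expect_error(neutrality_analysis(const), "zero variance")
})

test_that("ENC-plot ratios, histogram and the within-band count are consistent", {
  sp <- synthetic_spec(seed = 22L, regime = "selection_driven", bias_strength = 4)
  prof <- codon_profiles(filter_cds(simulate_cds_set(sp)$cds))
  ep <- enc_plot_analysis(prof)
  expect_equal(ep$table$enc_ratio,
               (ep$table$enc_exp - ep$table$enc_obs) / ep$table$enc_exp)
  expect_equal(sum(ep$histogram$count), nrow(ep$table))
  expect_equal(ep$n_within + ep$n_outside, nrow(ep$table))
  expect_equal(ep$n_within, sum(ep$table$enc_ratio >= -0.05 & ep$table$enc_ratio <= 0.05))
  # bins aligned on multiples of 0.05, so [-0.05, 0.05] spans two whole bins
  edges <- c(ep$histogram$bin_left, ep$histogram$bin_right) / 0.05
  expect_true(all(abs(edges - round(edges)) < 1e-9))

  # order invariance of the histogram
  shuf <- prof[rev(seq_len(nrow(prof))), ]
  expect_equal(enc_plot_analysis(shuf)$histogram, ep$histogram)

  # a gene exactly on the curve has ratio 0 and falls in the band
  on_curve <- data.frame(gene = "x", gc3 = 50, enc = expected_enc(0.5),
                         gc12 = 50)
  ep1 <- enc_plot_analysis(on_curve)
  expect_equal(ep1$table$enc_ratio, 0)
  expect_equal(ep1$n_within, 1L)

  # unbiased genes near GC3 0.5 hug the expected curve
  spu <- synthetic_spec(seed = 23L, regime = "uniform")
  profu <- codon_profiles(filter_cds(simulate_cds_set(spu)$cds))
  epu <- enc_plot_analysis(profu)
  expect_gt(mean(abs(epu$table$enc_ratio) <= 0.05), 0.9)
})

test_that("PR2 quadrant counts follow the planted third-position bias", {
  # strand-symmetric genes (A3 = T3, G3 = C3) sit at the center
  bal <- dna_gene(rep(c("GCA", "GCU", "GCG", "GCC"), 10))
  cds <- setNames(rep(bal, 3), c("a", "b", "c"))
  pa <- pr2_analysis(codon_profiles(cds))
  expect_equal(unname(pa$quadrant_counts["boundary"]), 3L)
  expect_equal(pa$n_x_gt_half, 0L)

  # T- and G-rich third positions -> lower-right quadrant
  biased <- dna_gene(rep(c("GCU", "GCU", "GCU", "GCG", "GCG", "GCA"), 20))
  cds2 <- setNames(rep(biased, 4), letters[1:4])
  pa2 <- pr2_analysis(codon_profiles(cds2))
  expect_equal(unname(pa2$quadrant_counts["lower_right"]), 4L)
  expect_equal(pa2$n_x_gt_half, 4L)
  expect_equal(pa2$n_y_lt_half, 4L)
  expect_equal(sum(pa2$quadrant_counts), pa2$n_defined)
})

test_that("the correlation matrix matches direct Pearson formulas and flags stars", {
  # 4-point hand dataset checked against the summation formula
  x <- c(1, 2, 4, 7); y <- c(2, 1, 5, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  prof <- data.frame(gene = letters[1:4], gc1 = x, gc2 = y,
                     gc3 = c(3, 1, 4, 1), gc_all = (x + y + c(3, 1, 4, 1)) / 3,
                     gc12 = (x + y) / 2,
                     enc = c(45, 52, 38, 41), n_codons = c(100, 120, 90, 300))
  cm <- correlation_matrix(prof)
  expect_equal(cm$r["GC1", "GC2"], r_hand, tolerance = 1e-12)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 6))

  # y = x exactly -> r = 1, p ~ 0, starred
  prof2 <- within(prof, gc2 <- gc1)
  cm2 <- correlation_matrix(prof2)
  expect_equal(cm2$r["GC1", "GC2"], 1)
  expect_lt(cm2$p["GC1", "GC2"], 1e-8)
  expect_identical(cm2$stars["GC1", "GC2"], "**")

  # constant column flagged (one warning per affected pair)
  prof3 <- within(prof, enc <- rep(45, 4))
  ws <- testthat::capture_warnings(cm3 <- correlation_matrix(prof3))
  expect_true(any(grepl("constant column", ws)))
  expect_true(is.na(cm3$r["ENC", "GC1"]))
})
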