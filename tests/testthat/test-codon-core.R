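test_that("count_codons reads triplets 5'->3', skips ambiguity, and is additive", {
  cc <- count_codons("ATGTAA")
  expect_equal(unname(cc$counts["AUG"]), 1L)
  expect_equal(unname(cc$counts["UAA"]), 1L)
  expect_equal(cc$total, 1L)  # stop recorded but not counted as sense

  cc2 <- count_codons("ATGGCTGCTTAA")
  expect_equal(unname(cc2$counts[c("AUG", "GCU")]), c(1L, 2L))
  expect_equal(cc2$total, 3L)

  expect_equal(count_codons("ATGNCTGCT")$n_ambiguous, 1L)
  expect_error(count_codons("ATGT"), "divisible by 3")

  # concatenation invariance for in-frame halves
  x <- dna_gene(rep(c("GCU", "AAA"), 5)); y <- dna_gene(rep(c("CUG", "UUU"), 7))
  expect_equal((count_codons(x) + count_codons(y))$counts,
               count_codons(paste0(x, y))$counts)
})

test_that("positional GC content matches hand arithmetic and the composite identities", {
  # all-GCC gene: GC at every position
  all_gcc <- gc_by_position(count_codons(dna_gene(rep("GCC", 10))))
  expect_true(all(all_gcc == 100))

  # {GCU, AAA}: gc1 = 50, gc2 = 50, gc3 = 0
  gc <- gc_by_position(count_codons("GCTAAA"))
  expect_equal(unname(gc[c("gc1", "gc2", "gc3")]), c(50, 50, 0))
  expect_equal(unname(gc["gc_all"]), 100 / 3, tolerance = 1e-12)
  expect_equal(unname(gc["gc12"]), (gc[["gc1"]] + gc[["gc2"]]) / 2)

  expect_error(gc_by_position(count_codons("TAA")), "undefined")

  # invariance to gene concatenation order
  a <- dna_gene(rep("GCU", 7)); b <- dna_gene(rep("AAA", 11))
  expect_equal(gc_by_position(count_codons(paste0(a, b))),
               gc_by_position(count_codons(paste0(b, a))))
})

test_that("RSCU matches the family-normalization definition and brute force", {
  # Ala {GCU:3, GCA:1}: mean family count 1 -> RSCU 3, 1, 0, 0
  r <- compute_rscu(count_codons(dna_gene(rep("GCU", 3), "GCA")))
  expect_equal(unname(r[c("GCU", "GCA", "GCC", "GCG")]), c(3, 1, 0, 0))

  # Met and Trp are always 1 when used; unused families are NA
  r2 <- compute_rscu(count_codons("ATGTGG"))
  expect_equal(unname(r2[c("AUG", "UGG")]), c(1, 1))
  expect_true(is.na(r2[["GCU"]]))

  # uniform usage within every family -> all RSCU 1
  r3 <- compute_rscu(count_codons(uniform_gene(3L)))
  expect_true(all(abs(r3[!is.na(r3)] - 1) < 1e-12))

  # brute-force cross-check on an arbitrary gene
  gene <- dna_gene("AUG", rep(c("GCU", "GCA", "CUG", "UUA", "AAA", "AGU"),
                              c(5, 2, 4, 1, 7, 3)), "UAA")
  ref <- oracle_rscu(gene)
  mine <- compute_rscu(count_codons(gene))
  expect_equal(mine[names(ref)], ref, tolerance = 1e-12)
})

test_that("RSCU values of a used family always sum to its degeneracy", {
  sp <- synthetic_spec(seed = 31L, n_genes = 10L, regime = "selection_driven",
                       bias_strength = 5)
  sim <- simulate_cds_set(sp)
  fams <- synonymous_families()
  for (g in sim$cds[1:5]) {
    r <- compute_rscu(count_codons(g))
    for (fam in fams) {
      vals <- r[fam]
      if (all(is.na(vals))) next
      expect_equal(sum(vals), length(fam), tolerance = 1e-9)
    }
  }
})

test_that("ENC hits its theoretical limits and survives label permutation", {
  expect_equal(compute_enc(count_codons(one_codon_gene())), 20)
  expect_equal(compute_enc(count_codons(uniform_gene(100L))), 61)

  # permuting codon labels within a family leaves ENC unchanged
  g1 <- dna_gene("AUG", rep(c("GCU", "GCA", "GCC"), c(10, 5, 1)),
                 rep(c("AAA", "AAG"), c(8, 2)), rep("AUU", 4), "UAA")
  g2 <- dna_gene("AUG", rep(c("GCC", "GCG", "GCA"), c(10, 5, 1)),
                 rep(c("AAG", "AAA"), c(8, 2)), rep("AUA", 4), "UAA")
  expect_equal(compute_enc(count_codons(g1)), compute_enc(count_codons(g2)))

  # a gene with no estimable family is undefined
  expect_true(is.na(compute_enc(count_codons("ATGTGG"))))
})

test_that("ENC agrees with an independent homozygosity implementation within 0.1", {
  genes <- character(0)
  for (sd in 1:4) {
    rg <- c("uniform", "mutation_driven", "selection_driven", "selection_driven")[sd]
    sp <- synthetic_spec(seed = 100L + sd, n_genes = 25L, regime = rg,
                         bias_strength = c(1, 1, 2, 8)[sd])
    genes <- c(genes, simulate_cds_set(sp)$cds)
  }
  expect_length(genes, 100L)
  mine <- vapply(genes, function(g) compute_enc(count_codons(g)), numeric(1))
  ref <- vapply(genes, oracle_enc, numeric(1))
  # both implementations agree on which genes have no estimable ENC
  expect_identical(is.na(mine), is.na(ref))
  ok <- !is.na(mine)
  expect_gt(sum(ok), 90L)
  expect_true(all(abs(mine[ok] - ref[ok]) < 0.1))
})

test_that("the expected-ENC curve evaluates the standard formula", {
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(1e-9), 31, tolerance = 1e-6)  # X -> 0 limit
  grid <- seq(0.01, 0.99, length.out = 100)
  expect_equal(expected_enc(grid), 2 + grid + 29 / (grid^2 + (1 - grid)^2),
               tolerance = 1e-12)
  # symmetric about 0.5 up to the linear term
  x <- c(0.1, 0.23, 0.4)
  expect_equal(expected_enc(x) - x, expected_enc(1 - x) - (1 - x))
  expect_error(expected_enc(0), "strictly inside")
  expect_error(expected_enc(1.2), "strictly inside")
})

test_that("PR2 coordinates use fourfold-family third positions only", {
  # fourfold Ala counts with A3=2, T3=6, G3=3, C3=1 -> (0.75, 0.25)
  gene <- dna_gene(rep("GCA", 2), rep("GCU", 6), rep("GCG", 3), "GCC")
  pr <- pr2_coordinates(count_codons(gene))
  expect_equal(unname(pr[c("x", "y")]), c(0.75, 0.25))

  # 2-fold codons contribute nothing (AAA is Lys)
  pr2 <- pr2_coordinates(count_codons(paste0(gene, dna_gene(rep("AAA", 50)))))
  expect_equal(pr, pr2)

  # balanced third positions sit at the parity center
  bal <- dna_gene("GCA", "GCU", "GCG", "GCC")
  expect_equal(unname(pr2_coordinates(count_codons(bal))[c("x", "y")]), c(0.5, 0.5))

  # no fourfold-family codons -> undefined, flagged as NA
  none <- pr2_coordinates(count_codons(dna_gene(rep("AAA", 5))))
  expect_true(all(is.na(none[c("x", "y")])))

  # strict mode drops the 6-fold boxes (CUN Leu)
  leu <- dna_gene(rep("CUA", 4), rep("CUG", 4))
  expect_equal(unname(pr2_coordinates(count_codons(leu), "extended")["g3"]), 4)
  expect_true(is.na(pr2_coordinates(count_codons(leu), "strict")[["x"]]))
})

test_that("codon_profiles assembles consistent per-gene rows", {
  sp <- synthetic_spec(seed = 9L, n_genes = 12L, regime = "mutation_driven")
  sim <- simulate_cds_set(sp)
  prof <- codon_profiles(filter_cds(sim$cds))
  expect_equal(nrow(prof), 12L)
  expect_equal(prof$gc12, (prof$gc1 + prof$gc2) / 2)
  expect_equal(prof$gc_all, (prof$gc1 + prof$gc2 + prof$gc3) / 3)
  expect_true(all(prof$enc >= 20 & prof$enc <= 61, na.rm = TRUE))
  expect_equal(prof$n_codons, nchar(sim$cds) / 3 - 1, ignore_attr = TRUE)  # stop excluded
})
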