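test_that("GenBank writer/reader round-trips sequence, features and join() locations", {
  dg <- demo_genome()
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(dg$record, tf)
  rec <- read_genbank(tf)

  expect_equal(rec$length, dg$record$length)
  expect_identical(rec$sequence, dg$record$sequence)
  expect_true(rec$circular)
  expect_length(rec$features, length(dg$record$features))

  # 2-exon CDS comes back as one feature with 2 intervals (1 intron)
  twoex <- Filter(function(f) f$gene == "twoex", rec$features)[[1L]]
  expect_equal(nrow(twoex$intervals), 2L)
  inv <- gene_inventory(rec)
  expect_equal(inv$introns$n_introns[inv$introns$gene == "twoex"], 1L)
})

test_that("read_genbank rejects records without sequence and tolerates empty feature tables", {
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp DNA circular", "ORIGIN", "//"), tf)
  expect_error(read_genbank(tf), "empty sequence")

  writeLines(c("LOCUS       X 8 bp DNA linear",
               "FEATURES             Location/Qualifiers",
               "ORIGIN", "        1 acgtacgt", "//"), tf)
  rec <- read_genbank(tf)
  expect_length(rec$features, 0L)
  expect_equal(rec$length, 8L)
})

test_that("extract_cds reverse-complements minus-strand genes and wraps on circular records", {
  dg <- demo_genome()
  cds <- extract_cds(dg$record)
  g <- dg$sim$cds
  expect_identical(unname(cds[["minD"]]), unname(g[[4L]]))
  expect_true(startsWith(cds[["minD"]], "ATG"))

  # gene spanning the origin on a rotated circle still extracts exactly
  rot <- rotate_genome(dg$record, 650L)  # origin now inside lscA
  cds_rot <- extract_cds(rot)
  expect_identical(unname(cds_rot[["lscA"]]), unname(g[[1L]]))

  # out-of-range interval on a linear record errors
  lin <- genome_record("L", "ATGAAATAA", circular = FALSE,
                       features = list(gene_feature("x", intervals = c(5L, 40L))))
  expect_error(extract_cds(lin), "outside linear")
})

test_that("identical IR-duplicated copies collapse to one entry, divergent copies keep tags", {
  dg <- demo_genome()
  cds <- extract_cds(dg$record)
  expect_equal(sum(grepl("^dupC", names(cds))), 1L)  # IRa mirror collapsed
  expect_identical(unname(cds[["dupC"]]), unname(dg$sim$cds[[3L]]))

  # same name, different sequence -> copy tags
  rec <- genome_record("D", paste0("ATGAAATAA", "ATGCCCTAA"), circular = FALSE,
                       features = list(
                         gene_feature("dup", intervals = c(1L, 9L)),
                         gene_feature("dup", intervals = c(10L, 18L))))
  cds2 <- extract_cds(rec)
  expect_setequal(names(cds2), c("dup_1", "dup_2"))
})

test_that("filter_cds applies each selection rule with the correct strictness", {
  ok <- dna_gene("AUG", rep(c("GCU", "AAA", "CUG"), 40), "UAA")   # 369 bp
  exactly300 <- dna_gene("AUG", rep("GCA", 98), "UGA")            # 300 bp exactly
  internal_stop <- dna_gene("AUG", rep("GCU", 50), "UGA", rep("AAA", 49), "UAA")
  no_start <- dna_gene("GCU", rep("AAA", 110), "UAA")
  no_stop <- dna_gene("AUG", rep("AAA", 111))
  off_frame <- paste0(ok, "A")
  raw <- c(ok = ok, ex300 = exactly300, istop = internal_stop,
           nostart = no_start, nostop = no_stop, frame = off_frame)
  fs <- filter_cds(raw)
  expect_identical(names(fs$entries), "ok")
  reasons <- setNames(fs$log$reason, fs$log$gene)
  expect_identical(unname(reasons[c("ex300", "istop", "nostart", "nostop", "frame")]),
                   c("too_short", "internal_stop", "no_start_codon",
                     "no_stop_codon", "frame_incomplete"))

  # idempotence: re-filtering the retained set keeps everything
  again <- filter_cds(fs$entries)
  expect_identical(again$entries, fs$entries)

  # retained genes are always a subset with codon-multiple lengths
  expect_true(all(names(fs$entries) %in% names(raw)))
  expect_true(all(nchar(fs$entries) %% 3L == 0L))
})

test_that("genes with many ambiguous codons are rejected, few are tolerated", {
  base <- c("AUG", rep("GCU", 200), "UAA")
  few_n <- base; few_n[5] <- "GNU"          # 1 of 202 codons ambiguous (<1%)
  many_n <- base; many_n[5:10] <- "GNU"     # ~3% ambiguous
  fs <- filter_cds(c(few = dna_gene(few_n), many = dna_gene(many_n)))
  expect_identical(names(fs$entries), "few")
  expect_identical(fs$log$reason[fs$log$gene == "many"], "excess_ambiguity")
})

test_that("gene_inventory counts occurrences by kind including IR duplicates", {
  dg <- demo_genome()
  inv <- gene_inventory(dg$record)
  # 5 planted CDS + 1 mirrored IRa copy of dupC
  expect_equal(unname(inv$counts["CDS"]), 6L)
  expect_equal(unname(inv$counts["genes"]), 6L)
  expect_equal(sum(inv$introns$n_introns), 1L)  # only twoex has an intron

  empty <- genome_record("E", "ACGT", features = list())
  expect_true(all(gene_inventory(empty)$counts == 0L))
})
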