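#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs with known ground truth.
# Produces three 50-gene CDS sets (one per codon-usage regime), a circular
# quadripartite genome with planted genes, and a 3-sequence alignment with a
# planted mutation hotspot. Everything is seeded and byte-reproducible.

suppressPackageStartupMessages(library(cpcodon))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 20260926L %% 100000L

for (rg in c("uniform", "mutation_driven", "selection_driven")) {
  sp <- synthetic_spec(seed = seed, regime = rg,
                       bias_strength = if (rg == "selection_driven") 4 else 1)
  sim <- simulate_cds_set(sp)
  write_cds_fasta(sim$cds, sprintf("results/data/cds_%s.fasta", rg))
  write.table(sim$truth, sprintf("results/data/truth_%s.tsv", rg),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-16s: %d genes, mean length %.0f bp, mean realized GC3 %.1f%%\n",
              rg, length(sim$cds), mean(nchar(sim$cds)),
              100 * mean(sim$truth$realized_gc3)))
}

# genome: LSC 20 kb | IRb 6 kb | SSC 4 kb | IRa 6 kb, with genes planted in
# the LSC, inside IRb (auto-duplicated into IRa), straddling the IRb/SSC
# junction, and on the minus strand
sp <- synthetic_spec(seed = seed, regime = "selection_driven", bias_strength = 4)
sim <- simulate_cds_set(sp)
irb_end <- sp$lsc_len + sp$ir_len
planted <- list(
  list(gene = "lscA", seq = sim$cds[[1L]], start = 500L),
  list(gene = "minB", seq = sim$cds[[2L]], start = 5000L, strand = "-"),
  list(gene = "dupC", seq = sim$cds[[3L]], start = sp$lsc_len + 900L),
  list(gene = "strD", seq = sim$cds[[4L]],
       start = irb_end - (nchar(sim$cds[[4L]]) - 120L) + 1L)  # 120 bp into SSC
)
rec <- simulate_genome(sp, planted)
write_genbank(rec, "results/data/synthetic_plastome.gb")
cat(sprintf("genome          : %d bp circular, %d features -> %s\n",
            rec$length, length(rec$features), "results/data/synthetic_plastome.gb"))

# alignment: 3 descendants of the genome sequence, one 800-bp hotspot at 10x
# the background substitution rate
al <- simulate_alignment(sp, ancestor = rec$sequence)
write_cds_fasta(al$aln, "results/data/alignment.fasta")
write.table(al$truth, "results/data/hotspot_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("alignment       : %d seqs x %d bp, hotspot %d-%d (rate %.3f)\n",
            length(al$aln), nchar(al$aln[[1L]]),
            al$truth$start[1L], al$truth$end[1L], al$truth$rate[1L]))
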