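#!/usr/bin/env Rscript

# Stage 5 (optional): full reproduction on the deposited chloroplast genome.
# The 165-kb GenBank record is not bundled; download accession PV938952 as a
# flat file (GenBank "Send to: File", format GenBank (full)) and run
#
#   Rscript analysis/05_reproduce_pv938952.R path/to/PV938952.gb
#
# The run prints the headline statistics next to the published values:
# 50 filtered genes; ENC 34.72-54.41 (mean 45.49); GC1/GC2/GC3 means
# 47.02/39.80/28.20; neutrality slope 0.2718; 14 optimal codons; PR2 counts
# 37 and 36; LSC/SSC/IR lengths 103,234/6,847/27,542 bp.

suppressPackageStartupMessages(library(cpcodon))
args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || !file.exists(args[[1L]])) {
  stop("usage: Rscript analysis/05_reproduce_pv938952.R <PV938952.gb>",
       call. = FALSE)
}

res <- run_full_analysis(genbank = args[[1L]], aln = if (length(args) > 1L) args[[2L]],
                         outdir = "results/pv938952")
s <- res$summary
cat(sprintf("genes retained  : %d (published: 50)\n", s$gene_count))
cat(sprintf("ENC             : %.2f-%.2f, mean %.2f (published: 34.72-54.41, mean 45.49)\n",
            s$enc_min, s$enc_max, s$enc_mean))
cat(sprintf("GC means        : GC1 %.2f, GC2 %.2f, GC3 %.2f (published: 47.02/39.80/28.20)\n",
            s$gc1_mean, s$gc2_mean, s$gc3_mean))
cat(sprintf("neutrality      : slope %.4f (published: 0.2718)\n", s$neutrality_slope))
cat(sprintf("optimal codons  : %d (published: 14): %s\n",
            s$n_optimal_codons, paste(s$optimal_codons, collapse = " ")))
cat(sprintf("PR2             : x>0.5: %d, y<0.5: %d (published: 37, 36)\n",
            s$pr2_x_gt_half, s$pr2_y_lt_half))
if (!is.null(s$quadripartite)) {
  cat(sprintf("structure       : LSC %d, SSC %d, IR %d bp (published: 103234/6847/27542)\n",
              s$quadripartite$lsc, s$quadripartite$ssc, s$quadripartite$irb))
}
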