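# Small fixtures built in code.

# in-frame DNA gene from RNA codons
dna_gene <- function(...) gsub("U", "T", paste(c(...), collapse = ""))

# a gene using every synonymous codon of every family `reps` times (uniform
# usage), ATG start and a stop appended
uniform_gene <- function(reps = 10L) {
  fams <- synonymous_families()
  cods <- unlist(lapply(fams, rep, times = reps), use.names = FALSE)
  dna_gene("AUG", cods, "UAA")
}

# a maximally biased gene: one codon per amino acid
one_codon_gene <- function(reps = 20L) {
  fams <- synonymous_families()
  cods <- unlist(lapply(fams, function(f) rep(f[1L], reps)), use.names = FALSE)
  dna_gene("AUG", cods, "UAA")
}

# standard synthetic genome bundle with planted genes used across tests
demo_genome <- function(seed = 7L, ...) {
  sp <- synthetic_spec(seed = seed, ...)
  sim <- simulate_cds_set(sp)
  irb_end <- sp$lsc_len + sp$ir_len
  g <- sim$cds
  planted <- list(
    list(gene = "lscA", seq = g[[1L]], start = 500L),
    list(gene = "strB", seq = g[[2L]],
         start = irb_end - (nchar(g[[2L]]) - 100L) + 1L),  # straddles JSB by 100 bp
    list(gene = "dupC", seq = g[[3L]], start = sp$lsc_len + 501L),  # inside IRb, 500 bp from JLB
    list(gene = "minD", seq = g[[4L]], start = 3000L, strand = "-"),
    list(gene = "twoex", seq = substr(g[[1L]], 1L, 150L),
         intervals = matrix(c(7000L, 7099L, 7200L, 7249L), ncol = 2L, byrow = TRUE))
  )
  list(spec = sp, sim = sim, planted = planted,
       record = simulate_genome(sp, planted))
}
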