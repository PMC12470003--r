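---
title: "Codon usage bias and plastome structure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias and plastome structure: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpcodon)
```

## Scope

`cpcodon` analyses codon usage bias and structural features of chloroplast
genomes: it filters protein-coding sequences, computes the standard per-gene
codon statistics (positional GC, RSCU, ENC, PR2 coordinates), runs the three
classical diagnostics of mutation versus selection (neutrality plot, ENC-plot,
PR2-bias plot), identifies optimal codons from expression-ranked gene groups,
detects the quadripartite LSC/IRb/SSC/IRa architecture with a junction gene
report, and scans alignments for sliding-window nucleotide diversity. A seeded
synthetic-data module generates every input with known ground truth, so the
whole pipeline is testable without external data.

## CDS selection

Candidate coding sequences are kept when they start with ATG, end with
TAA/TAG/TGA, contain no premature in-frame stop, and are strictly longer than
300 bp (`min_len`, strict inequality: a 300-bp CDS is rejected). Two further
rules make the statistics well defined: the length must be divisible by three
(`frame_incomplete` otherwise — a trailing partial codon cannot be attributed
to a codon), and at most 1% of codons may contain a non-ACGT symbol
(`excess_ambiguity`); individual ambiguous codons are skipped in all counts.
Every rejection is logged with its reason, so the route from an annotated
genome (which typically carries ~90 CDS features, many of them IR duplicates)
down to the analysis set is auditable. IR-duplicated genes with identical
sequence are collapsed to a single entry *before* filtering; same-name copies
that differ in sequence keep numeric copy tags.

## Codon statistics

All statistics exclude stop codons and treat the initiator ATG as an ordinary
Met codon (the CodonW/CUSP convention). GCk is the percentage of G+C at codon
position k over sense codons; GC12 = (GC1+GC2)/2 and
GC\_all = (GC1+GC2+GC3)/3 by definition, which the code asserts as
invariants.

**RSCU** of codon *c* in synonymous family *F* is its count divided by the
family mean count; a uniformly used family has RSCU 1 for all members, and the
family's RSCU values always sum to its degeneracy. Families with zero usage in
a gene are reported `NA` rather than 0.

**ENC** follows Wright: for each amino acid used *n* ≥ 2 times, the codon
homozygosity is F = (n·Σp²−1)/(n−1); F is averaged within degeneracy classes
and ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆, clamped to [20, 61]. Degeneracy
classes follow the standard code with Leu/Ser/Arg as 6-fold families and Ile
as the only 3-fold family. Amino acids with n ≤ 1 are excluded from their
class average (F is undefined at n = 1). When the 3-fold class is not
estimable, (F̄₂+F̄₄)/2 is substituted — Wright's own recommendation; when any
other class average is missing or non-positive the gene's ENC is `NA` and the
gene is excluded from downstream means. A rare consequence, mostly in very
short or extremely biased genes, is an undefined ENC; the test suite checks
that an independent brute-force homozygosity implementation agrees both on
the defined values (within 0.1) and on which genes are undefined.

The **expected ENC** under mutation alone is the standard null curve
ENC = 2 + X + 29/[X² + (1−X)²] with X the GC3 fraction, defined on (0, 1).
The **ENC ratio** is (ENC_exp − ENC_obs)/ENC_exp; the literature uses this
quantity without printing a formula, so it is fixed here as a documented
definition. Its histogram uses left-closed bins of width 0.05 aligned on
multiples of 0.05, so that [−0.05, 0.05] — the band conventionally read as
"compatible with mutation pressure alone" — spans exactly two bins; the
within-band count uses the closed interval. Left-closure is a choice (the
sources are silent); it is fixed and documented rather than configurable.

**PR2 coordinates** are x = G3/(G3+C3), y = A3/(A3+T3) with third-position
bases counted only over fourfold-degenerate codon boxes. "Amino acids encoded
by four codons" has two readings in the literature; the default (`extended`)
uses all eight fourfold boxes (Ala GCN, Gly GGN, Pro CCN, Thr ACN, Val GUN,
plus Leu CUN, Ser UCN, Arg CGN), and `strict` keeps only the five amino acids
with exactly four codons. Genes with a zero denominator are flagged `NA` and
excluded from quadrant counts. Points exactly on a centre line are counted as
`boundary`, not assigned to a quadrant; the threshold counts (x > 0.5,
y < 0.5) are strict.

## Gene-set analyses

**Expression groups.** Following the convention that highly expressed genes
show stronger bias and therefore *lower* ENC, the high-expression group is
the ⌈fraction·N⌉ genes with the lowest ENC (default fraction 0.10, i.e. 5 of
50) and the low-expression group the same number with the highest ENC. Some
descriptions in the literature invert this mapping; `swap_groups = TRUE`
reproduces that literal reading. Ties are broken by gene name for
determinism. The group size must satisfy 2·⌈fraction·N⌉ < N so the two
extremes never exhaust the set.

**Optimal codons.** Group RSCU values are computed on codon counts pooled
across the group's genes (not averaged per gene — pooling is what makes the
integer per-group codon counts in published tables reproducible).
ΔRSCU = RSCU_high − RSCU_low; codons with ΔRSCU ≥ 0.08 (closed bound, as in
the published star-class bins `*` [0.08, 0.30), `**` [0.30, 0.50),
`***` ≥ 0.50) are high-expression preferred. High-frequency codons have
RSCU > 1 on the full pooled gene set. Optimal codons are the intersection.

**Neutrality plot.** Unweighted OLS of GC12 on GC3 across genes, with the
Pearson correlation and its two-tailed p-value (t transformation, n−2 df).
The slope × 100 is reported as the mutation contribution and its complement
as the selection contribution; with a slightly negative slope the
decomposition exceeds 100%, which is a property of the conventional formula,
not an error.

**Correlations.** Pairwise Pearson r with two-tailed p over GC1, GC2, GC3,
GC_all, ENC and codon number, starred at 0.05/0.01. Constant columns yield
`NA` with a warning.

## Plastome structure

Inverted repeats are found by seed-and-extend: seeds spaced so that any
repeat of at least `min_ir` (default 1000 bp) contains one, matched against
the reverse complement on the doubled sequence (which makes detection
rotation-invariant on the circle), then extended greedily. The primary match
is exact (edit distance 0, uppercase); assembled plastomes normally have
identical IR copies. A fallback pass tolerates up to 0.1% mismatches during
extension — never ending a repeat on a mismatch — and is preferred only when
it yields a substantially (>1.2×) longer pair, which is the signature of a
rare SNV splitting the exact repeat in half; such results are flagged
`approximate` and may over-extend by up to the mismatch budget. The longer
inter-IR arc is the LSC, the shorter the SSC, and the four intervals must
tile the circle exactly. Junctions are named in IRscope style (JLB, JSB, JSA,
JLA); the junction report lists genes spanning each boundary with the bases
on either side, and genes whose nearest end lies within 1 kb.

## Nucleotide diversity

π is the mean over sequence pairs of per-site differences. Windows (default
800 bp, step 200 bp — the conventional DnaSP setting for plastome scans) are
taken in alignment coordinates; columns containing any gap or ambiguity are
excluded within each window (complete deletion, the DnaSP default;
`gap_mode = "pairwise"` switches to per-pair deletion). The terminal partial
window is reported with its true span rather than discarded, and a window
with no usable sites yields `NA`. Alignment coordinates are also mapped to
the ungapped coordinates of the first sequence, which is what region
labelling uses — so labels are robust to the alignment-versus-reference
coordinate ambiguity, while exact window positions are alignment-relative.
Hypervariable regions are the top-k windows by π (default 7), merged when
overlapping, labelled by the gene with the largest overlap or by the flanking
gene pair ("geneA-geneB") when intergenic. With a flat π profile the ranking
is arbitrary; the function warns and the tied windows merge into one region.

## The synthetic-data generators

All generators draw from R's Mersenne-Twister under an explicit seed stored
in the `synthetic_spec`; the caller's RNG state is left untouched, and the
same spec always reproduces byte-identical output.

**Coding sequences** are built codon by codon (ATG start, sampled canonical
stop, no internal stops possible, lengths a multiple of 3 drawn from
(300, 1602] bp), 50 genes by default with target GC3 0.282 — the study
conditions of an AT-rich plastome. Three regimes differ in what varies
between genes:

* `uniform` — every synonymous codon equiprobable: the no-bias control.
  ENC approaches 61 and realized GC3 sits near 0.5 (slightly above, because
  Met/Trp force G-endings); `target_gc3` deliberately does not apply, since
  tilting third positions would destroy the uniformity the regime exists to
  provide.
* `mutation_driven` — each gene receives one GC level, drawn uniformly
  within ±`gc_spread` (0.15) of `target_gc3`, which shapes base choice at
  *all three* codon positions (codon probabilities proportional to the
  product of per-position base probabilities over sense codons). GC12 and
  GC3 therefore co-vary across genes and the neutrality slope approaches 1.
* `selection_driven` — amino-acid composition varies between genes
  (symmetric Dirichlet, concentration `aa_conc` = 10) while third positions
  follow family codon weights shared by all genes (symmetric Dirichlet with
  concentration 1/`bias_strength`, one draw per family — a single knob that
  maps monotonically to ENC). Within each family the weights are normalized
  separately over A/U-ending and G/C-ending codons and the G/C group is
  given total mass *t*, so a family's GC3 probability is exactly *t*; *t*
  is solved per gene (1-d root finding) so the gene's expected GC3 equals
  its target. Per-gene targets get independent Gaussian wobble
  (`gc3_jitter`, sd 0.04) around `target_gc3`. The wobble is deliberate
  design: it represents gene-to-gene variation in the silent-site optimum
  that is independent of amino-acid composition, and it keeps the GC3
  variance well above the multinomial sampling floor, so the neutrality
  slope of this regime is sharply concentrated near 0 (sd ≈ 0.1 at 50
  genes) instead of being dominated by regression noise. Small
  infeasibilities of a gene's GC3 target (a Met/Trp-rich draw raises the
  attainable floor) are clamped to the nearest achievable value; gaps above
  0.05 error out as genuinely unreachable.

The generated sets satisfy the CDS filter by construction, which the tests
verify by round-tripping through it.

**Genomes** are LSC + IRb + SSC + IRa (defaults 20/6/4/6 kb — a scaled-down
plastome that keeps structure detection fast while leaving every junction
geometry representable) with IRa the exact reverse complement of IRb. Planted
genes may straddle junctions, sit on the minus strand, or have multiple
exons; genes fully inside IRb are mirrored into IRa as opposite-strand
duplicates, reproducing plastome IR duplication. Because detection reports
the *maximal* reverse-complement pair, the generator breaks chance
complementary base pairs immediately flanking the repeats (when those
positions are not covered by a planted gene), so planted lengths are
recovered exactly.

**Alignments** mutate a common ancestor independently per site and sequence
(default 3 sequences, background substitution probability 0.005, one 800-bp
hotspot at 10×background). This is a star phylogeny without a substitution
model or indel evolution — adequate ground truth for window-ranking recovery,
but not a phylogenetically realistic simulator. Optional gap blocks go into
the last sequence only, keeping the first sequence's coordinate map clean.

## What the synthetic tests do and do not show

Passing recovery tests shows the estimators are implemented correctly and
can separate the planted regimes under idealized conditions: independent
sites, no selection on amino-acid identity, identical IR copies, star-shaped
ancestry. Real plastome data violate all of these to some degree — real
genes mix mutation and selection (published neutrality slopes around 0.27
sit between the two synthetic regimes), real IRs occasionally differ by a
few SNVs, and real alignments contain indels and rate heterogeneity beyond a
single hotspot. The synthetic results therefore validate the machinery, not
any biological claim.

## Problem sizes and numerical choices

The test suite and acceptance script use 50-gene sets (25 for some
replicated checks), 20 replicate seeds for regime-separation and hotspot
recovery, 36-kb synthetic genomes and 20-36-kb alignments; a full run takes
on the order of a minute. Percentages are computed in full precision and
rounded only for display (2 decimals) and TSV output (4 decimals);
`summary.json` keeps full precision. Root finding for the GC3 tilt uses
`uniroot` on (10⁻⁶, 1−10⁻⁶) with tolerance 10⁻⁹. Ties in ENC ranking and in
window ranking are broken by name and position respectively, so every
result is deterministic for a given input.

## Known limitations

* The GenBank reader targets single-record flat files with standard
  LOCUS/FEATURES/ORIGIN layout; it keeps `join()` structure and `/gene`
  qualifiers but ignores other qualifiers (`trans_splicing` annotations such
  as rps12 are used as written, with no reconstruction).
* ENC estimators differ between published tools in their rare-amino-acid
  handling; values can shift by ~0.1-0.3 between implementations. The
  package documents its exact rules (above) rather than chasing any single
  tool.
* Approximate IR detection reports a flagged, budget-limited extension, not
  an optimal alignment of the two copies.
* π windows are alignment-relative; only region labels are mapped to
  reference coordinates.
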