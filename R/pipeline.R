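#' Run the full codon-usage and structure analysis
#'
#' Wires the stages end to end: CDS extraction and filtering, per-gene codon
#' profiles, pooled RSCU, optimal-codon identification, neutrality plot,
#' ENC-plot, PR2 analysis and the codon-parameter correlation matrix; plus,
#' when the inputs allow, quadripartite structure detection with a junction
#' report and a sliding-window nucleotide-diversity scan. All result tables
#' are written as TSV under `outdir` together with a machine-readable
#' `summary.json` holding the key numbers at full precision.
#'
#' @param genbank Path to a GenBank flat file, or a `genome_record` (optional
#'   if `cds` is given).
#' @param cds Named character vector of coding sequences, `cds_set`, or FASTA
#'   path (optional if `genbank` is given).
#' @param aln Alignment (named character vector, `DNAStringSet`, or FASTA
#'   path) for the diversity scan; optional.
#' @param outdir Output directory (created if missing); `NULL` writes nothing.
#' @param min_len CDS length filter in bp (default 300, strict).
#' @param fraction Expression-group fraction (default 0.10).
#' @param delta_threshold Optimal-codon delta-RSCU threshold (default 0.08).
#' @param pr2_families PR2 family mode, `"extended"` or `"strict"`.
#' @param swap_groups Reverse the ENC/expression convention.
#' @param min_ir Minimum inverted-repeat length (default 1000).
#' @param window,step,top_k Diversity-scan parameters (defaults 800/200/7).
#' @param gap_mode Gap handling for the diversity scan.
#' @return (Invisibly) a list with every stage result and the `summary` list.
#' @export
run_full_analysis <- function(genbank = NULL, cds = NULL, aln = NULL,
                              outdir = NULL,
                              min_len = 300L, fraction = 0.10,
                              delta_threshold = 0.08,
                              pr2_families = "extended",
                              swap_groups = FALSE,
                              min_ir = 1000L,
                              window = 800L, step = 200L, top_k = 7L,
                              gap_mode = "complete") {
  if (is.null(genbank) && is.null(cds)) {
    stop("provide a GenBank record or a CDS set", call. = FALSE)
  }
  record <- NULL
  if (!is.null(genbank)) {
    record <- if (inherits(genbank, "genome_record")) genbank else read_genbank(genbank)
  }
  raw <- if (!is.null(cds)) {
    if (inherits(cds, "cds_set")) cds$entries
    else if (is.character(cds) && length(cds) == 1L && file.exists(cds)) read_cds_fasta(cds)
    else cds
  } else {
    extract_cds(record)
  }
  filtered <- filter_cds(raw, min_len = min_len)
  if (length(filtered$entries) == 0L) stop("no CDS passed the filter", call. = FALSE)
  profiles <- codon_profiles(filtered, pr2_families = pr2_families)
  rscu_all <- compute_rscu(pooled_counts(filtered))
  optimal <- identify_optimal_codons(filtered$entries, profiles,
                                     fraction = fraction,
                                     delta_threshold = delta_threshold,
                                     swap_groups = swap_groups)
  neutrality <- neutrality_analysis(profiles)
  encplot <- enc_plot_analysis(profiles)
  pr2 <- pr2_analysis(profiles)
  correlations <- correlation_matrix(profiles)

  structure_res <- NULL; junctions <- NULL; inventory <- NULL
  if (!is.null(record)) {
    inventory <- gene_inventory(record)
    if (record$circular && record$length > 4L * min_ir) {
      structure_res <- tryCatch(detect_inverted_repeats(record, min_ir = min_ir),
                                error = function(e) NULL)
      if (!is.null(structure_res)) {
        junctions <- junction_report(structure_res, record)
      }
    }
  }
  diversity <- NULL; regions <- NULL
  if (!is.null(aln)) {
    diversity <- sliding_window_pi(aln, window = window, step = step,
                                   gap_mode = gap_mode)
    regions <- hypervariable_regions(diversity, record = record, top_k = top_k)
  }

  opt_rows <- optimal$report[optimal$report$is_optimal, ]
  summary <- list(
    gene_count = nrow(profiles),
    n_rejected = sum(filtered$log$status == "rejected"),
    enc_mean = mean(profiles$enc, na.rm = TRUE),
    enc_min = min(profiles$enc, na.rm = TRUE),
    enc_max = max(profiles$enc, na.rm = TRUE),
    gc1_mean = mean(profiles$gc1), gc2_mean = mean(profiles$gc2),
    gc3_mean = mean(profiles$gc3), gc_all_mean = mean(profiles$gc_all),
    neutrality_slope = neutrality$slope,
    neutrality_r = neutrality$r,
    neutrality_p = neutrality$p_value,
    mutation_pct = neutrality$mutation_pct,
    selection_pct = neutrality$selection_pct,
    n_high_frequency_codons = sum(optimal$report$is_high_frequency),
    n_optimal_codons = nrow(opt_rows),
    optimal_codons = opt_rows$codon,
    enc_ratio_within = encplot$n_within,
    enc_ratio_outside = encplot$n_outside,
    pr2_x_gt_half = pr2$n_x_gt_half,
    pr2_y_lt_half = pr2$n_y_lt_half,
    r_enc_gc3 = correlations$r["ENC", "GC3"]
  )
  if (!is.null(structure_res)) {
    summary$quadripartite <- as.list(structure_res$lengths)
  }
  if (!is.null(regions)) summary$hypervariable_labels <- regions$label

  res <- list(record = record, filtered = filtered, profiles = profiles,
              rscu = rscu_all, optimal = optimal, neutrality = neutrality,
              encplot = encplot, pr2 = pr2, correlations = correlations,
              inventory = inventory, structure = structure_res,
              junctions = junctions, diversity = diversity, regions = regions,
              summary = summary)
  if (!is.null(outdir)) write_result_bundle(res, outdir)
  invisible(res)
}

# write every stage table of a run_full_analysis() result as TSV + JSON
write_result_bundle <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(res$filtered$log, "filter_log.tsv")
  prof <- res$profiles
  num <- vapply(prof, is.numeric, logical(1))
  prof[num] <- lapply(prof[num], function(x) round(x, 4))
  tsv(prof, "profiles.tsv")
  tsv(data.frame(codon = names(res$rscu),
                 amino_acid = unname(.codon_table[names(res$rscu)]),
                 rscu = round(unname(res$rscu), 4)), "rscu.tsv")
  opt <- res$optimal$report
  for (cl in c("rscu_high", "rscu_low", "rscu_all", "delta_rscu")) {
    opt[[cl]] <- round(opt[[cl]], 4)
  }
  tsv(opt, "optimal_codons.tsv")
  tsv(data.frame(quantity = names(unlist(res$neutrality)),
                 value = unname(unlist(res$neutrality))), "neutrality.tsv")
  tsv(res$encplot$table, "encplot.tsv")
  tsv(res$encplot$histogram, "encplot_histogram.tsv")
  tsv(res$pr2$table, "pr2.tsv")
  cm <- res$correlations
  tsv(data.frame(parameter = rownames(cm$r),
                 round(as.data.frame(cm$r), 4)), "correlations_r.tsv")
  tsv(data.frame(parameter = rownames(cm$p),
                 signif(as.data.frame(cm$p), 4)), "correlations_p.tsv")
  if (!is.null(res$inventory)) {
    tsv(data.frame(kind = names(res$inventory$counts),
                   count = unname(res$inventory$counts)), "inventory.tsv")
    tsv(res$inventory$introns, "introns.tsv")
  }
  if (!is.null(res$structure)) {
    s <- res$structure
    tsv(data.frame(region = c("lsc", "irb", "ssc", "ira"),
                   start = c(s$lsc[1], s$irb[1], s$ssc[1], s$ira[1]),
                   end = c(s$lsc[2], s$irb[2], s$ssc[2], s$ira[2]),
                   length = unname(s$lengths)), "structure.tsv")
  }
  if (!is.null(res$junctions)) tsv(res$junctions, "junctions.tsv")
  if (!is.null(res$diversity)) tsv(res$diversity$windows, "pi_windows.tsv")
  if (!is.null(res$regions)) tsv(res$regions, "regions.tsv")
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Published optimal-codon reference table for accession PV938952
#'
#' The published high/low expression group RSCU values, codon counts and
#' delta-RSCU for the 14 optimal codons reported for the *Pothos chinensis*
#' chloroplast genome (GenBank PV938952), bundled as plain-text reference
#' data. Used to check the package's delta-RSCU and star-class arithmetic
#' against independently published values.
#'
#' @return Data frame: `amino_acid`, `codon`, `rscu_high`, `n_high`,
#'   `rscu_low`, `n_low`, `delta_rscu`, `star_class`.
#' @export
pv938952_optimal_codons <- function() {
  path <- system.file("extdata", "pv938952_optimal_codons.tsv",
                      package = "cpcodon", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
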