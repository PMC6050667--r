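# One-call orchestration of the full codon-usage analysis, and TSV/JSON
# result writing. The numbered scripts under analysis/ are thin drivers
# over these functions.

#' Run the complete codon-usage-bias analysis
#'
#' Executes every stage over a validated CDS set: composition and GC
#' histogram, dinucleotide profiles, pooled RSCU with preferred/avoided
#' classification, the per-gene index table, ENC plot layers, deviation
#' histogram, PR2 analysis, neutrality regression, the correlation suite,
#' optional expression stratification and focal gene-set comparison, and
#' the three PCA decompositions.
#'
#' @param x a `cds_set`.
#' @param expression optional expression table ([read_expression_table()]).
#' @param gene_set optional character vector of focal gene ids.
#' @param gc_breaks optional explicit GC breakpoints for stratification and
#'   PCA group labels (default: dataset quartiles).
#' @param impute RSCU imputation mode for PCA (see [rscu_matrix()]).
#' @return list of stage results plus a `summary` list of headline numbers
#'   (counts, preferred-codon tallies, neutrality slope, quadrant counts,
#'   modal deviation bin).
#' @export
analyze_cds_set <- function(x, expression = NULL, gene_set = NULL,
                            gc_breaks = NULL, impute = "one") {
  stopifnot(inherits(x, "cds_set"))
  composition <- nucleotide_content(x, pooled = TRUE)
  per_record <- nucleotide_content(x, pooled = FALSE)
  gc_hist <- gc_histogram(per_record$gc_overall)
  dinucs <- dinucleotide_profiles(x)
  counts <- count_codons(x)
  pooled_rscu <- rscu_classify(rscu(counts))
  index <- gene_index_table(x, expression = expression)
  encplot <- enc_plot_data(index)
  dev_hist <- deviation_histogram(index$deviation[!is.na(index$deviation)])
  pr2 <- pr2_analysis(x)
  neutrality <- neutrality_fit(index$gc12, index$gc3)

  rmat <- rscu_matrix(counts, impute = impute)
  pca_genes <- pca_genes_rscu(rmat, gc = index$gc, gc_breaks = gc_breaks)
  pca_codons <- pca_codons_rscu(rmat)
  prot <- protein_indices(stats::setNames(x$records$protein, x$records$id))
  pca_aa <- pca_amino_acids(prot$aa_proportion)

  index$rscu_axis1 <- pca_genes$scores[, 1]
  index$aa_axis1 <- pca_aa$scores[, 1]
  correlations <- correlation_suite(index, list(
    c("enc", "aa_axis1"), c("enc", "rscu_axis1"),
    c("enc", "length_aa"), c("enc", "gravy"), c("enc", "aromo"),
    c("rscu_axis1", "length_aa"), c("rscu_axis1", "gravy"),
    c("rscu_axis1", "aromo")
  ))

  strata <- NULL
  if (!is.null(expression)) {
    strata <- expression_stratification(index, gc_breaks = gc_breaks)
  }
  gene_set_comparison <- NULL
  if (!is.null(gene_set)) {
    gene_set_comparison <- gene_set_compare(index, gene_set)
  }

  modal <- dev_hist[which.max(dev_hist$count), ]
  summary <- list(
    n_accepted = nrow(x$records),
    n_rejected = nrow(x$rejected),
    gc_overall = composition$gc_overall,
    mean_enc = mean(index$enc, na.rm = TRUE),
    n_strong_bias = encplot$n_strong,
    preferred_count = length(pooled_rscu$preferred),
    ending_base_tally = as.list(pooled_rscu$ending_base_tally),
    neutrality_slope = neutrality$slope,
    neutrality_r_squared = neutrality$r_squared,
    quadrant_counts = as.list(pr2$quadrant_counts),
    modal_deviation_bin = c(modal$bin_lo, modal$bin_hi),
    rscu_axis_variance = pca_genes$variance_explained[1:2],
    aa_axis_variance = pca_aa$variance_explained[1:2]
  )

  list(
    composition = composition, per_record_composition = per_record,
    gc_histogram = gc_hist, dinucleotides = dinucs,
    pooled_rscu = pooled_rscu, index = index,
    enc_plot = encplot, deviation_histogram = dev_hist,
    pr2 = pr2, neutrality = neutrality, correlations = correlations,
    strata = strata, gene_set_comparison = gene_set_comparison,
    pca_genes = pca_genes, pca_codons = pca_codons, pca_aa = pca_aa,
    rejection = rejection_report(x),
    summary = summary
  )
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write analysis results as TSV and JSON files
#'
#' Every figure-bearing table is written as TSV so plots are reproducible
#' from the files alone; the headline numbers go to `summary.json`.
#'
#' @param results list from [analyze_cds_set()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- character(0)
  w <- function(df, name) {
    path <- file.path(dir, name)
    .write_tsv(df, path)
    p[[name]] <<- path
  }
  w(results$per_record_composition, "composition.tsv")
  w(results$dinucleotides, "dinucleotides.tsv")
  w(results$pooled_rscu$profile, "pooled_rscu.tsv")
  w(results$index, "gene_index.tsv")
  w(results$enc_plot$points, "enc_plot_points.tsv")
  w(results$enc_plot$curve, "enc_plot_curve.tsv")
  w(results$deviation_histogram, "deviation_histogram.tsv")
  w(results$pr2$points, "pr2.tsv")
  w(results$correlations, "correlations.tsv")
  if (!is.null(results$strata)) w(results$strata$table,
                                  "expression_strata.tsv")
  if (!is.null(results$gene_set_comparison)) {
    w(results$gene_set_comparison$table, "gene_set_comparison.tsv")
  }
  w(data.frame(id = rownames(results$pca_genes$scores),
               results$pca_genes$scores[, 1:2, drop = FALSE],
               group = results$pca_genes$group_labels %||% NA),
    "pca_genes_scores.tsv")
  w(data.frame(codon = rownames(results$pca_codons$scores),
               results$pca_codons$scores[, 1:2, drop = FALSE],
               ending_base = results$pca_codons$group_labels),
    "pca_codons_scores.tsv")
  if (nrow(results$rejection) > 0) w(results$rejection, "rejected.tsv")
  jsonlite::write_json(results$neutrality,
                       file.path(dir, "neutrality.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(results$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(p)
}
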