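# Synthetic CDS generator with explicit mutation/selection ground truth,
# and the packaged reference RSCU table.

#' Parameters for the synthetic CDS generator
#'
#' The generator draws, per gene, a protein length from a truncated
#' lognormal, an FPKM from a lognormal, a gene-level mutational GC bias
#' m_g from a Beta distribution centred on `gc_bias`, and an effective
#' selection strength s_g coupling translational selection to expression.
#' Codons are then drawn independently: under `mutation_scope = "third"`
#' the amino acid is drawn from `aa_profile` and the synonymous codon with
#' probability proportional to base(m_g) * exp(s_g * [ending base in
#' `selection_target`]), where base(m_g) places third-position G/C mass
#' m_g split evenly (A/U likewise); under `"all"` the codon is drawn from
#' all 61 sense codons with weight equal to the product of per-position
#' base probabilities under m_g times the same selection factor, so
#' compositional bias reaches all three positions. A start codon AUG is
#' prepended and a terminal stop appended, so the output always passes the
#' CDS filters.
#'
#' @param n_genes number of genes (default 2000).
#' @param length_meanlog,length_sdlog lognormal parameters of protein
#'   length in amino acids (defaults log(300) and 0.45, giving a mean near
#'   330 aa).
#' @param min_length_aa truncation floor in amino acids (default 100).
#' @param gc_bias m, the neutral probability that a third-position draw is
#'   G or C (default 0.5).
#' @param gc3_heterogeneity Beta concentration of the per-gene m_g around
#'   `gc_bias` (default 50; `Inf` makes m_g constant).
#' @param selection_strength s, the log-weight added to codons whose ending
#'   base is in `selection_target` (default 0).
#' @param selection_target `"GC"` or `"C"` (default `"GC"`).
#' @param selection_expression_coupling scales s by the gene's log10-FPKM
#'   z-score: s_g = s * max(0, 1 + coupling * z_g) (default 0).
#' @param fpkm_meanlog,fpkm_sdlog lognormal FPKM parameters (defaults 1
#'   and 2).
#' @param mutation_scope `"third"` (default) or `"all"` codon positions.
#' @param aa_profile optional named amino-acid sampling weights (default
#'   uniform over the 20 canonical residues); ignored under scope `"all"`.
#' @param seed integer seed (mandatory for reproducibility).
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(n_genes = 2000,
                              length_meanlog = log(300),
                              length_sdlog = 0.45,
                              min_length_aa = 100,
                              gc_bias = 0.5,
                              gc3_heterogeneity = 50,
                              selection_strength = 0,
                              selection_target = c("GC", "C"),
                              selection_expression_coupling = 0,
                              fpkm_meanlog = 1,
                              fpkm_sdlog = 2,
                              mutation_scope = c("third", "all"),
                              aa_profile = NULL,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  selection_target <- match.arg(selection_target)
  mutation_scope <- match.arg(mutation_scope)
  stopifnot(n_genes >= 1, min_length_aa >= 1,
            gc_bias > 0, gc_bias < 1,
            gc3_heterogeneity > 0,
            selection_strength >= 0,
            is.finite(length_meanlog), length_sdlog > 0,
            is.finite(fpkm_meanlog), fpkm_sdlog > 0)
  if (stats::plnorm(min_length_aa, length_meanlog, length_sdlog) > 0.99) {
    stop("infeasible length distribution: truncation removes >99% of mass")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    min_length_aa = as.integer(min_length_aa),
    gc_bias = gc_bias, gc3_heterogeneity = gc3_heterogeneity,
    selection_strength = selection_strength,
    selection_target = selection_target,
    selection_expression_coupling = selection_expression_coupling,
    fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
    mutation_scope = mutation_scope,
    aa_profile = aa_profile,
    seed = as.integer(seed)
  ), class = "simulation_params")
}

# per-position base probabilities under mutational GC bias m
.base_probs <- function(m) {
  c(A = (1 - m) / 2, C = m / 2, G = m / 2, T = (1 - m) / 2)
}

# codon sampling probabilities for one gene
.codon_probs <- function(m_g, s_g, target_bases, scope, aa_profile) {
  code <- .code()
  sense <- code$sense_codons
  third <- .codon_base(sense, 3)
  sel <- exp(s_g * (third %in% target_bases))
  bp <- .base_probs(m_g)
  if (scope == "all") {
    w <- bp[.codon_base(sense, 1)] * bp[.codon_base(sense, 2)] *
      bp[third] * sel
  } else {
    aa <- code$codon_to_aa[sense]
    w <- bp[third] * sel
    # normalize within each family, then weight families by the aa profile
    fam_tot <- tapply(w, aa, sum)[aa]
    w <- aa_profile[aa] * w / fam_tot
  }
  stats::setNames(w / sum(w), sense)
}

#' Simulate a CDS set with known mutation/selection structure
#'
#' @param params a `simulation_params` object.
#' @return list with `sequences` (named character vector of full CDSs,
#'   start codon and terminal stop included, DNA alphabet), `expression`
#'   (data.frame id, fpkm), and `truth` (list: `params` echo and `genes`
#'   data.frame with per-gene length_aa, fpkm, m_g, s_g and realized body
#'   gc3). Regenerating with the same seed reproduces identical output.
#' @export
simulate_cds_set <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  n <- params$n_genes
  # truncated lognormal lengths by rejection
  len <- round(rlnorm(n, params$length_meanlog, params$length_sdlog))
  for (i in 1:100) {
    short <- len < params$min_length_aa
    if (!any(short)) break
    len[short] <- round(rlnorm(sum(short), params$length_meanlog,
                               params$length_sdlog))
  }
  len[len < params$min_length_aa] <- params$min_length_aa
  fpkm <- rlnorm(n, params$fpkm_meanlog, params$fpkm_sdlog)
  z <- as.vector(scale(log10(fpkm)))
  if (n == 1L || sd(log10(fpkm)) == 0) z <- rep(0, n)
  s_g <- params$selection_strength *
    pmax(0, 1 + params$selection_expression_coupling * z)
  kappa <- params$gc3_heterogeneity
  m_g <- if (is.finite(kappa)) {
    pmin(pmax(rbeta(n, params$gc_bias * kappa,
                    (1 - params$gc_bias) * kappa), 1e-4), 1 - 1e-4)
  } else {
    rep(params$gc_bias, n)
  }
  aa_profile <- params$aa_profile
  if (is.null(aa_profile)) {
    aa_profile <- stats::setNames(rep(1 / 20, 20), .amino_acids)
  }
  aa_profile <- aa_profile / sum(aa_profile)
  target <- if (params$selection_target == "GC") c("G", "C") else "C"
  sense <- .code()$sense_codons
  stops <- .code()$stop_codons
  seqs <- character(n)
  gc3_body <- numeric(n)
  for (g in seq_len(n)) {
    pr <- .codon_probs(m_g[g], s_g[g], target, params$mutation_scope,
                       aa_profile)
    body <- sample(sense, len[g], replace = TRUE, prob = pr)
    gc3_body[g] <- mean(substr(body, 3, 3) %in% c("G", "C"))
    seqs[g] <- paste0("ATG", paste(body, collapse = ""),
                      sample(stops, 1L))
  }
  ids <- sprintf("gene%05d", seq_len(n))
  names(seqs) <- ids
  list(
    sequences = seqs,
    expression = data.frame(id = ids, fpkm = fpkm,
                            stringsAsFactors = FALSE),
    truth = list(
      params = unclass(params),
      genes = data.frame(id = ids, length_aa = len, fpkm = fpkm,
                         m_g = m_g, s_g = s_g, gc3_body = gc3_body,
                         stringsAsFactors = FALSE)
    )
  )
}

#' Validate a simulation as a CDS set
#'
#' @param sim output of [simulate_cds_set()].
#' @param ... passed to [cds_set()].
#' @return a `cds_set` (every simulated record passes the filters by
#'   construction).
#' @export
as_cds_set <- function(sim, ...) {
  cds_set(names(sim$sequences), sim$sequences, ...)
}

#' Write a simulation to disk (FASTA + expression TSV + truth JSON)
#'
#' @param sim output of [simulate_cds_set()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "cds.fasta"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.json"))
  write_fasta(sim$sequences, paths[["fasta"]])
  write.table(sim$expression, paths[["expression"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Packaged reference RSCU table
#'
#' The published genome-wide RSCU table for the buffalo leech
#' (*Hirudinaria manillensis*) transcriptome CDS set, stored exactly as
#' printed (61 sense codons, including AUG and UGG at 1). Family sums carry
#' the printed rounding residue (the Leu family sums to 6.001). Used as a
#' fixed worked example for the preferred/avoided classification.
#'
#' @return data.frame with columns amino_acid (three-letter code), codon
#'   (RNA) and rscu.
#' @export
reference_rscu <- function() {
  path <- system.file("extdata", "reference_rscu.tsv", package = "codonbias",
                      mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
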