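# Per-gene codon-usage statistics: RSCU, Wright's ENC, the GC3-expected ENC
# curve and its deviation ratio, and protein-level indices.

# coerce counts input (named vector or 1-row slice) to a named 64-vector
.as_count_vector <- function(counts) {
  if (is.matrix(counts)) {
    stopifnot(nrow(counts) == 1L)
    counts <- counts[1L, ]
  }
  stopifnot(!is.null(names(counts)))
  full <- stats::setNames(numeric(64), .codon_universe())
  full[names(counts)] <- counts
  full
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c in a synonymous family of size n is its observed count
#' divided by the equal-usage expectation (family total / n). Within each
#' observed family the values sum to the family size; a family with zero
#' occurrences yields NA (flagged absent). Stop codons are excluded; the
#' single-codon families Met (AUG) and Trp (UGG) are reported with RSCU 1
#' when observed but carry no usage information.
#'
#' @param counts named codon count vector (DNA or RNA codon names), a
#'   one-row matrix, or a full count matrix (which is summed into a pooled
#'   table first — genome-level RSCU is the RSCU of the summed counts, not
#'   the mean of per-gene RSCU).
#' @return data.frame with columns amino_acid, codon (RNA), count, rscu,
#'   ordered by amino acid then codon; 61 rows.
#' @export
rscu <- function(counts) {
  if (is.matrix(counts)) {
    counts <- if (nrow(counts) > 1L) colSums(counts) else counts[1L, ]
  }
  counts <- .as_count_vector(stats::setNames(
    as.numeric(counts), rna_to_dna(names(counts))))
  code <- .code()
  if (sum(counts[code$sense_codons]) == 0) stop("all-zero codon counts")
  rows <- lapply(names(code$families), function(aa) {
    fam <- sort(code$families[[aa]])
    fc <- counts[fam]
    total <- sum(fc)
    vals <- if (total > 0) fc / (total / length(fam)) else rep(NA_real_,
                                                              length(fam))
    data.frame(amino_acid = aa, codon = dna_to_rna(fam),
               count = as.numeric(fc), rscu = as.numeric(vals),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$amino_acid, out$codon), ]
  rownames(out) <- NULL
  out
}

#' Classify preferred and avoided codons from an RSCU profile
#'
#' Thresholds are strict: preferred means RSCU > 1, highly preferred
#' RSCU > 1.25, avoided RSCU < 0.75. The ending-base tally counts the third
#' (RNA) base among preferred codons.
#'
#' @param profile data.frame with columns codon (RNA) and rscu, as returned
#'   by [rscu()] or [reference_rscu()].
#' @param preferred,highly_preferred,avoided classification thresholds.
#' @return list with character vectors `preferred`, `highly_preferred`,
#'   `avoided`, the integer `ending_base_tally` (named A, U, G, C, over the
#'   preferred set) and the input profile with a `class` column
#'   (`highly_preferred` / `preferred` / `avoided` / `typical` / `absent`).
#' @export
rscu_classify <- function(profile, preferred = 1, highly_preferred = 1.25,
                          avoided = 0.75) {
  stopifnot(all(c("codon", "rscu") %in% names(profile)))
  v <- profile$rscu
  cl <- ifelse(is.na(v), "absent",
        ifelse(v > highly_preferred, "highly_preferred",
        ifelse(v > preferred, "preferred",
        ifelse(v < avoided, "avoided", "typical"))))
  pref <- profile$codon[!is.na(v) & v > preferred]
  tally <- vapply(c("A", "U", "G", "C"), function(b) {
    sum(substr(pref, 3, 3) == b)
  }, integer(1))
  profile$class <- cl
  list(
    preferred = pref,
    highly_preferred = profile$codon[!is.na(v) & v > highly_preferred],
    avoided = profile$codon[!is.na(v) & v < avoided],
    ending_base_tally = tally,
    profile = profile
  )
}

#' RSCU matrix over the 59 informative codons
#'
#' Per-gene RSCU for multivariate analysis. Codons of families unobserved in
#' a gene have no defined RSCU; they are imputed with 1 (the no-information
#' value that preserves family mass) by default, with 0 or dropping the gene
#' available as sensitivity switches.
#'
#' @param counts genes x 64 codon count matrix from [count_codons()].
#' @param impute `"one"` (default), `"zero"`, or `"drop"` (drop genes with
#'   any unobserved family).
#' @return numeric matrix genes x 59 (RNA codon names) with attribute
#'   `imputed` (logical matrix of the cells that were imputed).
#' @export
rscu_matrix <- function(counts, impute = c("one", "zero", "drop")) {
  impute <- match.arg(impute)
  code <- .code()
  info <- code$informative_codons
  out <- matrix(NA_real_, nrow(counts), length(info),
                dimnames = list(rownames(counts), dna_to_rna(info)))
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    fam_i <- intersect(fam, info)
    if (length(fam_i) == 0L) next
    sub <- counts[, fam, drop = FALSE]
    tot <- rowSums(sub)
    vals <- sub[, fam_i, drop = FALSE] / (tot / length(fam))
    vals[tot == 0, ] <- NA_real_
    out[, dna_to_rna(fam_i)] <- vals
  }
  imputed <- is.na(out)
  if (impute == "drop") {
    keep <- rowSums(imputed) == 0L
    out <- out[keep, , drop = FALSE]
    imputed <- imputed[keep, , drop = FALSE]
  } else {
    out[imputed] <- if (impute == "one") 1 else 0
  }
  attr(out, "imputed") <- imputed
  out
}

# Wright's homozygosity F for one family's count sub-matrix (genes x codons)
# rows with family total < 2 get NA (F undefined at m < 2)
.family_F <- function(sub) {
  m <- rowSums(sub)
  p2 <- rowSums((sub / ifelse(m > 0, m, 1))^2)
  f <- (m * p2 - 1) / (m - 1)
  f[m < 2] <- NA_real_
  f
}

#' Wright's effective number of codons (ENC)
#'
#' Per amino acid with family total m >= 2, the codon homozygosity is
#' F = (m * sum(p_i^2) - 1) / (m - 1) with p_i the within-family codon
#' proportions. F is averaged over the observed amino acids of each
#' degeneracy class (2-, 3-, 4- and 6-fold; Leu, Ser, Arg are single 6-fold
#' families) and ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, clamped to at most 61.
#' If the 3-fold class (Ile) cannot be estimated it falls back to the mean
#' of the 2- and 4-fold class averages; if any other class average is
#' missing or non-positive, ENC is NA with a machine-readable reason.
#'
#' @param counts genes x 64 codon count matrix, or a single named count
#'   vector.
#' @return data.frame with columns enc, clamped (logical), reason (NA when
#'   defined; `insufficient_families` or `nonpositive_fbar` otherwise) and
#'   f_bar_2, f_bar_3, f_bar_4, f_bar_6; one row per gene.
#' @export
enc <- function(counts) {
  if (!is.matrix(counts)) {
    counts <- matrix(.as_count_vector(stats::setNames(
      as.numeric(counts), rna_to_dna(names(counts)))), nrow = 1,
      dimnames = list(NULL, .codon_universe()))
  } else {
    colnames(counts) <- rna_to_dna(colnames(counts))
  }
  code <- .code()
  n <- nrow(counts)
  classes <- c(2L, 3L, 4L, 6L)
  f_sum <- matrix(0, n, 4, dimnames = list(NULL, classes))
  f_n <- matrix(0L, n, 4, dimnames = list(NULL, classes))
  for (aa in names(code$families)) {
    k <- code$degeneracy[[aa]]
    if (k == 1L) next
    f <- .family_F(counts[, code$families[[aa]], drop = FALSE])
    ok <- !is.na(f)
    kc <- as.character(k)
    f_sum[ok, kc] <- f_sum[ok, kc] + f[ok]
    f_n[ok, kc] <- f_n[ok, kc] + 1L
  }
  f_bar <- f_sum / ifelse(f_n > 0, f_n, NA)
  # Ile fallback: mean of the 2- and 4-fold class averages
  miss3 <- is.na(f_bar[, "3"]) & !is.na(f_bar[, "2"]) & !is.na(f_bar[, "4"])
  f_bar[miss3, "3"] <- (f_bar[miss3, "2"] + f_bar[miss3, "4"]) / 2
  weights <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  missing_any <- rowSums(is.na(f_bar)) > 0
  nonpos <- !missing_any & rowSums(f_bar <= 0, na.rm = TRUE) > 0
  value <- 2 + as.vector((1 / f_bar) %*% weights)
  value[missing_any | nonpos] <- NA_real_
  clamped <- !is.na(value) & value > 61
  value[clamped] <- 61
  data.frame(
    enc = value,
    clamped = clamped,
    reason = ifelse(missing_any, "insufficient_families",
                    ifelse(nonpos, "nonpositive_fbar", NA_character_)),
    f_bar_2 = f_bar[, "2"], f_bar_3 = f_bar[, "3"],
    f_bar_4 = f_bar[, "4"], f_bar_6 = f_bar[, "6"],
    row.names = rownames(counts),
    stringsAsFactors = FALSE
  )
}

#' Expected ENC under pure compositional (GC3) bias
#'
#' The null curve relating ENC to third-position GC content when only
#' mutational composition acts: ENC_exp = 2 + s + 29 / (s^2 + (1 - s)^2),
#' with s the GC3 proportion.
#'
#' @param gc3 numeric vector of GC3 proportions in (0, 1].
#' @return numeric vector of expected ENC values.
#' @export
expected_enc <- function(gc3) {
  if (any(is.na(gc3)) || any(gc3 <= 0 | gc3 > 1)) {
    stop("gc3 must lie in (0, 1]")
  }
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' ENC deviation ratio
#'
#' The relative shortfall of the observed ENC from its GC3 expectation:
#' (ENC_exp - ENC_obs) / ENC_exp. Positive values mean fewer codons are used
#' than composition alone predicts; the value may be negative.
#'
#' @param enc_obs observed ENC values (NA propagates).
#' @param enc_exp expected ENC values (must be positive).
#' @return numeric vector of deviation ratios.
#' @export
enc_deviation <- function(enc_obs, enc_exp) {
  stopifnot(all(enc_exp > 0, na.rm = TRUE))
  (enc_exp - enc_obs) / enc_exp
}

#' Protein-level indices: length, GRAVY, aromaticity, composition
#'
#' GRAVY is the mean Kyte-Doolittle hydropathy over residues; aromaticity
#' (AROMO) is the fraction of Phe, Tyr and Trp.
#'
#' @param proteins character vector of amino-acid sequences (canonical
#'   one-letter codes, no stop symbol).
#' @return list with `indices` (data.frame: length_aa, gravy, aromo) and
#'   `aa_proportion` (matrix, proteins x 20, rows on the simplex).
#' @export
protein_indices <- function(proteins) {
  stopifnot(length(proteins) > 0L, all(nchar(proteins) > 0L))
  chars <- strsplit(proteins, "")
  bad <- lapply(chars, function(v) which(!(v %in% .amino_acids)))
  ibad <- which(lengths(bad) > 0L)
  if (length(ibad) > 0L) {
    stop("non-canonical residue at position ", bad[[ibad[1]]][1],
         " of protein ", ibad[1])
  }
  counts <- t(vapply(chars, function(v) {
    tabulate(match(v, .amino_acids), nbins = length(.amino_acids))
  }, numeric(length(.amino_acids))))
  colnames(counts) <- .amino_acids
  len <- rowSums(counts)
  prop <- counts / len
  data_idx <- data.frame(
    length_aa = as.integer(len),
    gravy = as.vector(prop %*% .kyte_doolittle[.amino_acids]),
    aromo = rowSums(prop[, .aromatic, drop = FALSE])
  )
  if (!is.null(names(proteins))) {
    rownames(prop) <- names(proteins)
    data_idx <- cbind(data.frame(id = names(proteins),
                                 stringsAsFactors = FALSE), data_idx)
  }
  list(indices = data_idx, aa_proportion = prop)
}

#' Per-gene index table
#'
#' Assembles the full per-gene scalar index table: codon totals, positional
#' GC, ENC with its GC3 expectation and deviation ratio, PR2 coordinates,
#' protein length, GRAVY, aromaticity, and (when an expression table is
#' supplied) FPKM.
#'
#' @param x a `cds_set`.
#' @param expression optional data.frame from [read_expression_table()].
#' @return data.frame with one row per CDS: id, n_codons, gc, gc1, gc2, gc3,
#'   gc12, gc3s, enc, enc_expected, deviation, pr2_x, pr2_y, length_aa,
#'   gravy, aromo, fpkm, log10_fpkm.
#' @export
gene_index_table <- function(x, expression = NULL) {
  stopifnot(inherits(x, "cds_set"))
  comp <- nucleotide_content(x, pooled = FALSE)
  counts <- count_codons(x)
  enc_res <- enc(counts)
  pr2 <- pr2_analysis(x)$points
  prot <- protein_indices(stats::setNames(x$records$protein, x$records$id))
  out <- data.frame(
    id = x$records$id,
    n_codons = x$records$n_codons,
    gc = comp$gc_overall,
    gc1 = comp$gc1, gc2 = comp$gc2, gc3 = comp$gc3,
    gc12 = comp$gc12, gc3s = comp$gc3s,
    enc = enc_res$enc,
    enc_expected = ifelse(comp$gc3 > 0, expected_enc(pmax(comp$gc3, 1e-12)),
                          NA_real_),
    length_aa = prot$indices$length_aa,
    gravy = prot$indices$gravy,
    aromo = prot$indices$aromo,
    stringsAsFactors = FALSE
  )
  out$deviation <- enc_deviation(out$enc, out$enc_expected)
  out$pr2_x <- pr2$x[match(out$id, pr2$id)]
  out$pr2_y <- pr2$y[match(out$id, pr2$id)]
  if (!is.null(expression)) {
    j <- match(out$id, expression$id)
    out$fpkm <- expression$fpkm[j]
    out$log10_fpkm <- expression$log10_fpkm[j]
  } else {
    out$fpkm <- NA_real_
    out$log10_fpkm <- NA_real_
  }
  out
}
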