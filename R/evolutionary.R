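# Inference layer: ENC plot, deviation histogram, PR2 bias, neutrality
# regression, correlation suite, expression stratification, gene-set
# comparison.

#' ENC-plot layers: observed scatter and the expected curve
#'
#' Assembles the observed (GC3, ENC) scatter, each gene's position relative
#' to the compositional-null curve, and the expected curve sampled at the
#' conventional grid of 1000 strictly increasing GC3 values from 0.001 to
#' 1.000. ENC = 35 is carried as the conventional reference separating
#' strong from weak codon usage bias.
#'
#' @param index per-gene index table from [gene_index_table()].
#' @param strong_cutoff ENC value delimiting strong bias (default 35).
#' @return list with `points` (id, gc3, enc, enc_expected, status
#'   above/below/on), `curve` (gc3, enc_expected at the 1000-point grid),
#'   `strong_cutoff` and `n_strong` (genes with ENC below the cutoff).
#' @export
enc_plot_data <- function(index, strong_cutoff = 35) {
  ok <- !is.na(index$enc)
  if (sum(ok) < 2L) stop("need at least 2 genes with defined ENC")
  pts <- index[ok, c("id", "gc3", "enc", "enc_expected")]
  pts$status <- ifelse(pts$enc < pts$enc_expected, "below",
                       ifelse(pts$enc > pts$enc_expected, "above", "on"))
  grid <- seq(0.001, 1, by = 0.001)
  list(
    points = pts,
    curve = data.frame(gc3 = grid, enc_expected = expected_enc(grid)),
    strong_cutoff = strong_cutoff,
    n_strong = sum(pts$enc < strong_cutoff)
  )
}

#' Histogram of ENC deviation ratios
#'
#' Bins (ENC_exp - ENC_obs)/ENC_exp values into half-open bins of fixed
#' width aligned to zero, so one bin edge always falls at 0.
#'
#' @param deviations numeric vector (NAs dropped with a warning).
#' @param bin_width bin width (default 0.01).
#' @return data.frame with bin_lo, bin_hi, count and frequency (summing
#'   to 1), restricted to the occupied range.
#' @export
deviation_histogram <- function(deviations, bin_width = 0.01) {
  if (anyNA(deviations)) {
    warning(sum(is.na(deviations)), " undefined deviation(s) dropped")
    deviations <- deviations[!is.na(deviations)]
  }
  if (length(deviations) == 0L) stop("no deviation values")
  stopifnot(all(is.finite(deviations)), bin_width > 0)
  idx <- floor(deviations / bin_width)
  rng <- seq(min(idx), max(idx))
  counts <- tabulate(idx - min(idx) + 1L, nbins = length(rng))
  data.frame(
    bin_lo = rng * bin_width,
    bin_hi = (rng + 1) * bin_width,
    count = counts,
    frequency = counts / sum(counts)
  )
}

# third-position base counts per gene over a choice of codon columns
.third_base_counts <- function(counts, codons) {
  out <- vapply(c("A", "T", "G", "C"), function(b) {
    cols <- codons[.codon_base(codons, 3) == b]
    as.vector(counts[, cols, drop = FALSE] %*% rep(1, length(cols)))
  }, numeric(nrow(counts)))
  if (!is.matrix(out)) out <- matrix(out, nrow = 1,
                                     dimnames = list(NULL,
                                                     c("A", "T", "G", "C")))
  out
}

#' Parity Rule 2 bias coordinates and quadrant tallies
#'
#' For each gene, y = A3/(A3 + U3) and x = G3/(G3 + C3) over third codon
#' positions. Under PR2 (no strand-specific mutation/selection) both are
#' 0.5. Quadrants around (0.5, 0.5): Q1 both > 0.5; Q2 y > 0.5, x < 0.5;
#' Q3 both < 0.5; Q4 y < 0.5, x > 0.5. Points exactly on 0.5 on either axis
#' are counted as boundary; zero denominators flag the point undefined.
#' Both are excluded from quadrant tallies.
#'
#' @param x a `cds_set` or a genes x 64 codon count matrix.
#' @param fourfold_only use only codons of fourfold-degenerate codon boxes
#'   (the classical PR2 convention) instead of all sense codons.
#' @return list with `points` (id, x, y, quadrant as "1".."4", "boundary" or
#'   "undefined") and `quadrant_counts` (named integer vector Q1..Q4,
#'   boundary, undefined).
#' @export
pr2_analysis <- function(x, fourfold_only = FALSE) {
  counts <- if (inherits(x, "cds_set")) .codon_counts(x) else x
  code <- .code()
  codons <- code$sense_codons
  if (fourfold_only) {
    boxes <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
    codons <- codons[substr(codons, 1, 2) %in% boxes]
  }
  tb <- .third_base_counts(counts, codons)
  au <- tb[, "A"] + tb[, "T"]
  gc <- tb[, "G"] + tb[, "C"]
  y <- ifelse(au > 0, tb[, "A"] / au, NA_real_)
  xx <- ifelse(gc > 0, tb[, "G"] / gc, NA_real_)
  quadrant <- ifelse(is.na(y) | is.na(xx), "undefined",
               ifelse(y == 0.5 | xx == 0.5, "boundary",
               ifelse(y > 0.5 & xx > 0.5, "1",
               ifelse(y > 0.5 & xx < 0.5, "2",
               ifelse(y < 0.5 & xx < 0.5, "3", "4")))))
  ids <- rownames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  pts <- data.frame(id = ids, x = xx, y = y, quadrant = quadrant,
                    stringsAsFactors = FALSE)
  qc <- vapply(c("1", "2", "3", "4", "boundary", "undefined"), function(q) {
    sum(quadrant == q)
  }, integer(1))
  names(qc) <- c("Q1", "Q2", "Q3", "Q4", "boundary", "undefined")
  list(points = pts, quadrant_counts = qc)
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 (response) on GC3 (predictor) across
#' genes. A slope of 1 indicates codon usage driven solely by mutational
#' (compositional) pressure; the shortfall from 1 is attributed to
#' selection constraints on first and second codon positions. The slope is
#' reported both directly and as mutation% = 100 * slope with selection% =
#' 100 * (1 - slope).
#'
#' @param gc12,gc3 numeric vectors of per-gene GC12 and GC3 proportions, or
#'   a data.frame with columns `gc12` and `gc3` as the first argument.
#' @return list with slope, intercept, r_squared, mutation_pct,
#'   selection_pct and n.
#' @export
neutrality_fit <- function(gc12, gc3 = NULL) {
  if (is.data.frame(gc12)) {
    gc3 <- gc12$gc3
    gc12 <- gc12$gc12
  }
  ok <- !is.na(gc12) & !is.na(gc3)
  gc12 <- gc12[ok]
  gc3 <- gc3[ok]
  if (length(gc3) < 3L) stop("need at least 3 genes for the neutrality fit")
  if (stats::sd(gc3) == 0) stop("zero GC3 variance")
  fit <- lm(gc12 ~ gc3)
  slope <- unname(coef(fit)[2])
  list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    mutation_pct = 100 * slope,
    selection_pct = 100 * (1 - slope),
    n = length(gc3)
  )
}

#' Pearson correlations between index-table columns
#'
#' @param index per-gene table (e.g. [gene_index_table()] possibly extended
#'   with PCA axis scores).
#' @param pairs list of length-2 character vectors naming column pairs.
#' @return data.frame with var1, var2, pearson_r, p_value, n and note
#'   (`"constant"` flags an undefined correlation).
#' @export
correlation_suite <- function(index, pairs) {
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L, all(pr %in% names(index)))
    a <- index[[pr[1]]]
    b <- index[[pr[2]]]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]
    b <- b[ok]
    if (length(a) < 3L) stop("fewer than 3 complete cases for ",
                             pr[1], " vs ", pr[2])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(data.frame(var1 = pr[1], var2 = pr[2], pearson_r = NA_real_,
                        p_value = NA_real_, n = length(a),
                        note = "constant", stringsAsFactors = FALSE))
    }
    ct <- cor.test(a, b, method = "pearson")
    data.frame(var1 = pr[1], var2 = pr[2],
               pearson_r = unname(ct$estimate), p_value = ct$p.value,
               n = length(a), note = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratify expressed genes by GC content for the expression plot
#'
#' Keeps genes with FPKM strictly above 1 and assigns each to one of three
#' GC groups split at the lower and upper quartiles of the full dataset's
#' overall GC content (data-derived by default; explicit breakpoints may be
#' supplied).
#'
#' @param index per-gene index table with fpkm and log10_fpkm columns (from
#'   [gene_index_table()] with an expression table).
#' @param gc_breaks optional numeric length-2 vector (low, high) of GC
#'   breakpoints; default the 25% and 75% quantiles of `index$gc`.
#' @param fpkm_threshold strict FPKM threshold (default 1).
#' @return list with `table` (id, log10_fpkm, enc, gc, gc_group with levels
#'   low/mid/high), `breaks`, and `group_summary` (n, mean_enc, mean_gc per
#'   group).
#' @export
expression_stratification <- function(index, gc_breaks = NULL,
                                      fpkm_threshold = 1) {
  if (is.null(gc_breaks)) {
    gc_breaks <- unname(quantile(index$gc, c(0.25, 0.75), na.rm = TRUE))
  }
  stopifnot(length(gc_breaks) == 2L, gc_breaks[1] < gc_breaks[2])
  keep <- !is.na(index$fpkm) & index$fpkm > fpkm_threshold
  if (!any(keep)) stop("no rows above threshold")
  tab <- index[keep, c("id", "log10_fpkm", "enc", "gc")]
  tab$gc_group <- factor(
    ifelse(tab$gc < gc_breaks[1], "low",
           ifelse(tab$gc > gc_breaks[2], "high", "mid")),
    levels = c("low", "mid", "high")
  )
  rownames(tab) <- NULL
  gs <- do.call(rbind, lapply(levels(tab$gc_group), function(g) {
    sub <- tab[tab$gc_group == g, ]
    data.frame(gc_group = g, n = nrow(sub),
               mean_enc = mean(sub$enc, na.rm = TRUE),
               mean_gc = mean(sub$gc),
               stringsAsFactors = FALSE)
  }))
  list(table = tab, breaks = gc_breaks, group_summary = gs)
}

#' Compare a focal gene set against dataset-average codon usage
#'
#' For each focal gene, the GC12/GC3 ratio and ENC are flagged against the
#' dataset means (strict comparison), the convention used to ask whether a
#' functional gene set is more or less codon-adapted than the background.
#'
#' @param index per-gene index table.
#' @param gene_ids character vector of focal ids.
#' @return list with `table` (id, enc, gc12_gc3_ratio, enc_below_average,
#'   ratio_below_average), `reference` (mean_enc, mean_gc12_gc3_ratio over
#'   the whole dataset), `missing_ids`, and `summary` counts.
#' @export
gene_set_compare <- function(index, gene_ids) {
  gene_ids <- unique(gene_ids)
  missing_ids <- setdiff(gene_ids, index$id)
  found <- intersect(gene_ids, index$id)
  if (length(found) == 0L) stop("no focal gene ids found in the index table")
  if (length(missing_ids) > 0L) {
    warning(length(missing_ids), " focal id(s) not in index table")
  }
  ratio_all <- index$gc12 / index$gc3
  ref <- list(mean_enc = mean(index$enc, na.rm = TRUE),
              mean_gc12_gc3_ratio = mean(ratio_all[is.finite(ratio_all)]))
  sub <- index[match(found, index$id), ]
  tab <- data.frame(
    id = sub$id,
    enc = sub$enc,
    gc12_gc3_ratio = sub$gc12 / sub$gc3,
    stringsAsFactors = FALSE
  )
  tab$enc_below_average <- tab$enc < ref$mean_enc
  tab$ratio_below_average <- tab$gc12_gc3_ratio < ref$mean_gc12_gc3_ratio
  rownames(tab) <- NULL
  list(
    table = tab,
    reference = ref,
    missing_ids = missing_ids,
    summary = c(
      n = nrow(tab),
      enc_below = sum(tab$enc_below_average, na.rm = TRUE),
      ratio_below = sum(tab$ratio_below_average, na.rm = TRUE)
    )
  )
}
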