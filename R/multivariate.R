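# Principal component decompositions of RSCU and amino-acid matrices.

# fix axis signs: largest-|loading| entry of each rotation column positive
.fix_signs <- function(p) {
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  p$rotation[, flip] <- -p$rotation[, flip]
  p$x[, flip] <- -p$x[, flip]
  p
}

.pca_result <- function(mat, scale. = FALSE, n_axes = NULL,
                        item_labels = NULL, group_labels = NULL) {
  if (nrow(mat) < 3L) stop("need at least 3 items for PCA")
  sds <- apply(mat, 2, stats::sd)
  if (scale. && any(sds == 0)) {
    mat <- mat[, sds > 0, drop = FALSE]
  }
  if (all(apply(mat, 2, stats::sd) == 0)) {
    # degenerate: no variation at all
    k <- if (is.null(n_axes)) min(nrow(mat) - 1L, ncol(mat)) else n_axes
    scores <- matrix(0, nrow(mat), k,
                     dimnames = list(rownames(mat), paste0("PC", seq_len(k))))
    return(structure(list(scores = scores,
                          loadings = matrix(0, ncol(mat), k),
                          variance_explained = rep(0, k),
                          item_labels = item_labels %||% rownames(mat),
                          group_labels = group_labels),
                     class = "cub_pca"))
  }
  p <- .fix_signs(prcomp(mat, center = TRUE, scale. = scale.))
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  k <- min(if (is.null(n_axes)) ncol(p$x) else n_axes, ncol(p$x))
  structure(list(
    scores = p$x[, seq_len(k), drop = FALSE],
    loadings = p$rotation[, seq_len(k), drop = FALSE],
    variance_explained = ve[seq_len(k)],
    item_labels = item_labels %||% rownames(mat),
    group_labels = group_labels
  ), class = "cub_pca")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cub_pca <- function(x, ...) {
  k <- min(4L, length(x$variance_explained))
  cat("PCA:", nrow(x$scores), "items,",
      length(x$variance_explained), "axes\n")
  cat("  variance explained (%):",
      paste(sprintf("%.2f", x$variance_explained[seq_len(k)]),
            collapse = ", "),
      if (length(x$variance_explained) > k) "..." else "", "\n")
  invisible(x)
}

#' PCA of the gene-wise RSCU matrix
#'
#' Column-centered, unscaled decomposition of the genes x 59 RSCU matrix
#' (RSCU values already share a scale). Genes are labelled by GC-content
#' interval when GC values are supplied, mirroring the conventional overlay
#' of composition groups on the first axes.
#'
#' @param rscu_mat genes x 59 matrix from [rscu_matrix()].
#' @param gc optional per-gene overall GC for group labels.
#' @param gc_breaks length-2 breakpoints for the GC groups; default the
#'   quartiles of `gc`.
#' @param scale. scale columns to unit variance (default FALSE).
#' @return A `cub_pca`: scores, loadings, variance_explained (%),
#'   item_labels, group_labels.
#' @export
pca_genes_rscu <- function(rscu_mat, gc = NULL, gc_breaks = NULL,
                           scale. = FALSE) {
  groups <- NULL
  if (!is.null(gc)) {
    stopifnot(length(gc) == nrow(rscu_mat))
    if (is.null(gc_breaks)) {
      gc_breaks <- unname(quantile(gc, c(0.25, 0.75)))
    }
    groups <- ifelse(gc < gc_breaks[1], "low",
                     ifelse(gc > gc_breaks[2], "high", "mid"))
  }
  .pca_result(rscu_mat, scale. = scale., group_labels = groups)
}

#' PCA of the codon-wise RSCU matrix
#'
#' Decomposes the transposed matrix (59 codons as items, genes as
#' variables); codons are labelled by their third (ending) base, and a
#' per-group dispersion summary (mean distance to the group centroid on the
#' first two axes) is attached, the statistic used to compare how tightly
#' AU- versus GC-ending codons cluster.
#'
#' @param rscu_mat genes x 59 matrix from [rscu_matrix()].
#' @param scale. scale columns (genes) to unit variance (default FALSE).
#' @return A `cub_pca` with `group_labels` = ending base (A/U/G/C) and an
#'   extra `group_dispersion` data.frame.
#' @export
pca_codons_rscu <- function(rscu_mat, scale. = FALSE) {
  m <- t(rscu_mat)
  res <- .pca_result(m, scale. = scale.)
  ending <- substr(rownames(m), 3, 3)
  res$group_labels <- ending
  sc <- res$scores[, seq_len(min(2L, ncol(res$scores))), drop = FALSE]
  res$group_dispersion <- do.call(rbind, lapply(c("A", "U", "G", "C"),
    function(b) {
      sub <- sc[ending == b, , drop = FALSE]
      cen <- colMeans(sub)
      data.frame(ending_base = b, n = nrow(sub),
                 dispersion = mean(sqrt(rowSums(
                   sweep(sub, 2, cen)^2))),
                 stringsAsFactors = FALSE)
    }))
  res
}

#' PCA of gene-wise amino-acid proportions
#'
#' Decomposes the genes x 20 amino-acid composition matrix (rows on the
#' simplex), reporting up to 20 axes with cumulative variance over the
#' first six, the summary used to judge how concentrated amino-acid usage
#' variation is.
#'
#' @param aa_mat genes x 20 proportion matrix from [protein_indices()].
#' @param n_axes number of axes to keep (default 20).
#' @return A `cub_pca` with an extra `cumulative_variance` vector (%).
#' @export
pca_amino_acids <- function(aa_mat, n_axes = 20) {
  stopifnot(ncol(aa_mat) == 20L,
            all(abs(rowSums(aa_mat) - 1) < 1e-8))
  res <- .pca_result(aa_mat, n_axes = n_axes)
  res$cumulative_variance <- cumsum(res$variance_explained)
  res
}
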