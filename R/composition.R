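# Nucleotide content, positional GC, GC histogram and dinucleotide profiles.

# genes x 64 frame-0 codon count matrix over sense codons
.codon_counts <- function(x) {
  stopifnot(inherits(x, "cds_set"))
  if (nrow(x$records) == 0L) stop("empty CDS set")
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(x$records$sense), width = 3, step = 3)
  rownames(m) <- x$records$id
  m
}

#' Frame-0 codon counts for every CDS
#'
#' Counts non-overlapping frame-0 triplets over the sense codons of each
#' record (terminal stop already excluded). Stop-codon columns are
#' necessarily zero for a validated set; terminal stop occurrences are kept
#' in the `terminal_stops` attribute and never enter RSCU or ENC.
#'
#' @param x a `cds_set`.
#' @return integer matrix, genes in rows, the 64 codons (DNA alphabet,
#'   alphabetical) in columns, with attribute `terminal_stops`.
#' @export
count_codons <- function(x) {
  m <- .codon_counts(x)
  attr(m, "terminal_stops") <- sum(x$records$has_terminal_stop)
  m
}

# positional GC proportions from a codon count matrix (rows = genes).
# exclude_mw drops ATG and TGG columns (gc3s variant).
.positional_gc <- function(counts, pos, exclude_mw = FALSE) {
  codons <- colnames(counts)
  use <- codons %in% .code()$sense_codons
  if (exclude_mw) use <- use & !(codons %in% c("ATG", "TGG"))
  gcc <- use & .codon_base(codons, pos) %in% c("G", "C")
  total <- as.vector(counts[, use, drop = FALSE] %*% rep(1, sum(use)))
  as.vector(counts[, gcc, drop = FALSE] %*% rep(1, sum(gcc))) / total
}

#' Nucleotide composition and positional GC content
#'
#' Base proportions and GC content by codon position, computed over sense
#' codons only (the terminal stop codon never contributes). GC12 is the
#' arithmetic mean of GC1 and GC2. `gc3s` is the GC3 variant excluding the
#' third positions of Met (AUG) and Trp (UGG) codons, provided for
#' cross-checks; all headline analyses use `gc3` over all sense codons.
#'
#' @param x a `cds_set`.
#' @param pooled if TRUE (default) counts are summed over all records before
#'   normalizing; if FALSE a per-record data.frame is returned.
#' @return One-row (pooled) or per-record data.frame with columns p_A, p_C,
#'   p_G, p_U, gc_overall, gc1, gc2, gc3, gc12, gc3s (and id when
#'   per-record).
#' @export
nucleotide_content <- function(x, pooled = TRUE) {
  counts <- .codon_counts(x)
  if (pooled) counts <- matrix(colSums(counts), nrow = 1,
                               dimnames = list(NULL, colnames(counts)))
  codons <- colnames(counts)
  base_mat <- sapply(c("A", "C", "G", "T"), function(b) {
    vapply(codons, function(cd) {
      sum(strsplit(cd, "")[[1]] == b)
    }, numeric(1))
  })
  base_counts <- counts %*% base_mat
  totals <- rowSums(base_counts)
  p <- base_counts / totals
  out <- data.frame(
    p_A = p[, "A"], p_C = p[, "C"], p_G = p[, "G"], p_U = p[, "T"],
    gc_overall = p[, "G"] + p[, "C"],
    gc1 = .positional_gc(counts, 1),
    gc2 = .positional_gc(counts, 2),
    gc3 = .positional_gc(counts, 3),
    gc3s = .positional_gc(counts, 3, exclude_mw = TRUE)
  )
  out$gc12 <- (out$gc1 + out$gc2) / 2
  out <- out[, c("p_A", "p_C", "p_G", "p_U", "gc_overall",
                 "gc1", "gc2", "gc3", "gc12", "gc3s")]
  if (!pooled) out <- cbind(data.frame(id = x$records$id,
                                       stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' GC-content histogram over fixed intervals
#'
#' Bins per-CDS overall GC into the five conventional intervals below 30%,
#' 30-42%, 42-50%, 50-60% and 60% or more, with half-open `[lo, hi)`
#' closure.
#'
#' @param gc numeric vector of per-CDS GC proportions in `[0, 1]`.
#' @param edges interior breakpoints (default `c(0.30, 0.42, 0.50, 0.60)`).
#' @return named integer vector of counts, one per interval, summing to
#'   `length(gc)`.
#' @export
gc_histogram <- function(gc, edges = c(0.30, 0.42, 0.50, 0.60)) {
  stopifnot(all(gc >= 0 & gc <= 1), !is.unsorted(edges))
  breaks <- c(-Inf, edges, Inf)
  counts <- as.integer(table(cut(gc, breaks = breaks, right = FALSE)))
  pct <- function(v) sub("\\.?0+$", "", formatC(100 * v, format = "f",
                                                digits = 2))
  names(counts) <- c(paste0("<", pct(edges[1]), "%"),
                     paste0(pct(edges[-length(edges)]), "-",
                            pct(edges[-1]), "%"),
                     paste0(">=", pct(edges[length(edges)]), "%"))
  counts
}

# drop the initial codon when it is ATG (start codons are removed from
# dinucleotide analysis; terminal stops are already gone from sense)
.strip_start_codon <- function(sense) {
  ifelse(substr(sense, 1L, 3L) == "ATG", substr(sense, 4L, nchar(sense)),
         sense)
}

.dinucs <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(t(outer(b, b, paste0)))  # AA AC AG AT CA ... TT
}

# pooled dinucleotide counts at codon-frame offsets: offset 1 = positions
# 1-2 within each codon, 2 = positions 2-3, 3 = position 3 bridging to the
# next codon's position 1; step 1 with offset 1 = all overlapping pairs.
.dinuc_counts <- function(seqs, offset, step) {
  ss <- Biostrings::DNAStringSet(substring(seqs, offset))
  colSums(Biostrings::oligonucleotideFrequency(ss, width = 2, step = step))
}

# pooled base frequencies at one codon position (1, 2 or 3), or overall (0)
.pos_base_freq <- function(seqs, pos) {
  ss <- Biostrings::DNAStringSet(seqs)
  if (pos == 0L) {
    counts <- colSums(Biostrings::alphabetFrequency(ss, baseOnly = TRUE))
    counts <- counts[c("A", "C", "G", "T")]
  } else {
    m <- Biostrings::oligonucleotideFrequency(ss, width = 3, step = 3)
    counts <- vapply(c("A", "C", "G", "T"), function(b) {
      sum(m[, .codon_base(colnames(m), pos) == b, drop = FALSE])
    }, numeric(1))
  }
  counts / sum(counts)
}

#' Positional dinucleotide frequency and ratio profiles
#'
#' Builds the four dinucleotide datasets used in codon-position composition
#' analysis: `1st&2nd` (within-codon positions 1-2), `2nd&3rd` (within-codon
#' positions 2-3), `3rd&1st` (position 3 of a codon with position 1 of the
#' next codon, within a record), and `all` (every overlapping dinucleotide).
#' An initial ATG codon and the terminal stop are excluded from every
#' dataset. Ratios divide the observed frequency by the product of the two
#' positional marginal base contents of that dataset (`global` marginals use
#' overall base content instead); under no association every ratio tends to
#' 1 and every frequency to 1/16 = 0.0625.
#'
#' @param x a `cds_set`.
#' @param marginals `"positional"` (default) or `"global"` reference
#'   marginals for the ratio denominator.
#' @return data.frame in long format: dataset, dinucleotide (RNA alphabet),
#'   freq, ratio; 64 rows (4 datasets x 16 dinucleotides).
#' @export
dinucleotide_profiles <- function(x, marginals = c("positional", "global")) {
  marginals <- match.arg(marginals)
  stopifnot(inherits(x, "cds_set"))
  seqs <- .strip_start_codon(x$records$sense)
  ok <- nchar(seqs) >= 9L
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with fewer than 3 codons after ",
            "start/stop exclusion skipped")
    seqs <- seqs[ok]
  }
  if (length(seqs) == 0L) stop("no records usable for dinucleotide analysis")
  spec <- list(
    `1st&2nd` = list(offset = 1L, step = 3L, pos = c(1L, 2L)),
    `2nd&3rd` = list(offset = 2L, step = 3L, pos = c(2L, 3L)),
    `3rd&1st` = list(offset = 3L, step = 3L, pos = c(3L, 1L)),
    all       = list(offset = 1L, step = 1L, pos = c(0L, 0L))
  )
  res <- lapply(names(spec), function(nm) {
    sp <- spec[[nm]]
    counts <- .dinuc_counts(seqs, sp$offset, sp$step)
    counts <- counts[.dinucs()]
    freq <- counts / sum(counts)
    if (marginals == "global") {
      m1 <- m2 <- .pos_base_freq(seqs, 0L)
    } else {
      m1 <- .pos_base_freq(seqs, sp$pos[1])
      m2 <- .pos_base_freq(seqs, sp$pos[2])
    }
    expected <- as.vector(outer(m1, m2))[match(
      .dinucs(), as.vector(outer(names(m1), names(m2), paste0)))]
    data.frame(
      dataset = nm,
      dinucleotide = dna_to_rna(.dinucs()),
      freq = as.numeric(freq),
      ratio = as.numeric(freq / expected),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
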