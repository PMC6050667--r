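# Independent brute-force oracles, coded literally from the defining
# formulas and kept separate from the package implementation paths.

.oracle_code <- Biostrings::GENETIC_CODE

# frame-0 codon tally by explicit index walking
oracle_codon_count <- function(seq) {
  counts <- stats::setNames(rep(0L, 64L), names(.oracle_code))
  i <- 1L
  while (i + 2L <= nchar(seq)) {
    cd <- substr(seq, i, i + 2L)
    counts[cd] <- counts[cd] + 1L
    i <- i + 3L
  }
  counts
}

# literal RSCU: loop over amino acids and their codons
oracle_rscu <- function(counts) {
  sense <- names(.oracle_code)[.oracle_code != "*"]
  out <- stats::setNames(rep(NA_real_, length(sense)), sense)
  for (aa in unique(.oracle_code[sense])) {
    fam <- sense[.oracle_code[sense] == aa]
    total <- sum(counts[fam])
    if (total > 0) {
      for (cd in fam) {
        out[cd] <- counts[cd] / (total / length(fam))
      }
    }
  }
  out
}

# literal Wright ENC with the same conventions as the package: families
# need total >= 2; Leu/Ser/Arg are 6-fold; Ile fallback (F2+F4)/2; clamp 61
oracle_enc <- function(counts) {
  sense <- names(.oracle_code)[.oracle_code != "*"]
  fams <- split(sense, .oracle_code[sense])
  f_by_class <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (aa in names(fams)) {
    fam <- fams[[aa]]
    k <- as.character(length(fam))
    if (k == "1") next
    m <- sum(counts[fam])
    if (m < 2) next
    p <- counts[fam] / m
    f <- (m * sum(p^2) - 1) / (m - 1)
    f_by_class[[k]] <- c(f_by_class[[k]], f)
  }
  fbar <- vapply(f_by_class, function(v) {
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  if (is.na(fbar[["3"]]) && !is.na(fbar[["2"]]) && !is.na(fbar[["4"]])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  }
  if (any(is.na(fbar)) || any(fbar <= 0)) return(NA_real_)
  val <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] +
    3 / fbar[["6"]]
  min(val, 61)
}

# random codon count table over the 61 sense codons (zeros allowed)
random_count_table <- function(max_count = 30) {
  sense <- names(.oracle_code)[.oracle_code != "*"]
  counts <- stats::setNames(rep(0, 64), names(.oracle_code))
  counts[sense] <- rpois(length(sense), runif(length(sense), 0, max_count))
  counts
}

# random valid CDS: n_codons sense codons (uniform), optional start/stop
random_cds_seq <- function(n_codons, start = TRUE, stop = TRUE) {
  sense <- names(.oracle_code)[.oracle_code != "*"]
  body <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  paste0(if (start) "ATG" else "", body, if (stop) "TAA" else "")
}

# build a cds_set from explicit codon vectors (relaxed min length)
cds_from_codons <- function(..., min_length = 3) {
  seqs <- vapply(list(...), paste, character(1), collapse = "")
  cds_set(paste0("s", seq_along(seqs)), seqs, min_length = min_length)
}

write_temp_fasta <- function(seqs, ids = paste0("seq", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
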