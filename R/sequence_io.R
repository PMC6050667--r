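# Reading, validating and translating candidate coding sequences.

.reject_rules <- c("too_short", "not_multiple_of_3", "ambiguity", "internal_stop")

# classify one normalized (uppercase, T-alphabet) sequence; NA_character_ if
# it passes. Rules are checked in a fixed order and the first failure wins.
.first_failed_rule <- function(seq, min_length, max_internal_stops) {
  n <- nchar(seq)
  if (n < min_length) return("too_short")
  if (n %% 3L != 0L) return("not_multiple_of_3")
  if (grepl("[^ACGT]", seq)) return("ambiguity")
  codons <- substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  internal <- codons[-length(codons)]
  if (sum(internal %in% .code()$stop_codons) > max_internal_stops) {
    return("internal_stop")
  }
  NA_character_
}

# strip a single terminal stop codon, if present
.strip_terminal_stop <- function(seq) {
  n <- nchar(seq)
  last <- substr(seq, n - 2L, n)
  has_stop <- last %in% .code()$stop_codons
  list(sense = ifelse(has_stop, substr(seq, 1L, n - 3L), seq),
       has_terminal_stop = has_stop)
}

#' Construct a validated CDS set from id and sequence vectors
#'
#' Applies the same filtering rules as [read_cds_fasta()] to in-memory
#' sequences. Sequences are upper-cased and U is normalized to T before
#' validation; a single terminal stop codon is allowed and stripped from the
#' stored sense sequence.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param sequences character vector of nucleotide sequences (T or U,
#'   any case).
#' @param min_length minimum full CDS length in nucleotides (default 300).
#' @param max_internal_stops maximum tolerated in-frame internal stop codons
#'   (default 0: any internal stop rejects the sequence).
#' @return An object of class `cds_set`: a list with `records` (data.frame
#'   with columns id, sense, length_nt, has_terminal_stop, n_codons, protein)
#'   and `rejected` (data.frame with columns id, rule). `sense` holds the
#'   stop-trimmed coding sequence actually used by every downstream
#'   statistic.
#' @export
cds_set <- function(ids, sequences, min_length = 300,
                    max_internal_stops = 0) {
  stopifnot(length(ids) == length(sequences))
  if (length(ids) == 0L) stop("no sequences")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id: ", dup[[1L]])
  }
  seqs <- rna_to_dna(toupper(sequences))
  rules <- vapply(seqs, .first_failed_rule, character(1),
                  min_length = min_length,
                  max_internal_stops = max_internal_stops,
                  USE.NAMES = FALSE)
  keep <- is.na(rules)
  rejected <- data.frame(id = ids[!keep], rule = rules[!keep],
                         stringsAsFactors = FALSE)
  ids <- ids[keep]
  seqs <- seqs[keep]
  if (length(seqs) > 0L) {
    st <- .strip_terminal_stop(seqs)
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(st$sense)))
    records <- data.frame(
      id = ids,
      sense = st$sense,
      length_nt = nchar(seqs),
      has_terminal_stop = st$has_terminal_stop,
      n_codons = nchar(st$sense) %/% 3L,
      protein = prot,
      stringsAsFactors = FALSE
    )
  } else {
    records <- data.frame(id = character(), sense = character(),
                          length_nt = integer(),
                          has_terminal_stop = logical(),
                          n_codons = integer(), protein = character(),
                          stringsAsFactors = FALSE)
  }
  structure(list(records = records, rejected = rejected,
                 min_length = min_length),
            class = "cds_set")
}

#' @export
print.cds_set <- function(x, ...) {
  cat("cds_set:", nrow(x$records), "accepted,",
      nrow(x$rejected), "rejected\n")
  if (nrow(x$records) > 0L) {
    cat("  codons per CDS:", min(x$records$n_codons), "-",
        max(x$records$n_codons), "\n")
  }
  invisible(x)
}

#' @export
length.cds_set <- function(x) nrow(x$records)

#' Read and filter coding sequences from a multi-FASTA file
#'
#' Sequences shorter than `min_length`, with a length not divisible by 3,
#' containing ambiguity characters (N or other IUPAC codes), or containing an
#' in-frame internal stop codon are rejected; each rejected id is reported
#' with the first rule it failed. A single terminal stop codon is permitted
#' and excluded from all downstream counting. Ids are taken as the FASTA
#' header token before the first whitespace; parsing is case-insensitive and
#' accepts RNA (U) as well as DNA (T).
#'
#' @inheritParams cds_set
#' @param path path to a readable FASTA file.
#' @return A `cds_set`; see [cds_set()].
#' @export
read_cds_fasta <- function(path, min_length = 300, max_internal_stops = 0) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no sequences")
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
  cds_set(ids, as.character(raw), min_length = min_length,
          max_internal_stops = max_internal_stops)
}

#' Translate CDS records under the standard genetic code
#'
#' @param x a `cds_set`.
#' @return Named character vector of amino-acid sequences, one letter per
#'   sense codon (terminal stop excluded).
#' @export
translate_cds <- function(x) {
  stopifnot(inherits(x, "cds_set"))
  stats::setNames(x$records$protein, x$records$id)
}

#' Rejection report of a CDS set
#'
#' @param x a `cds_set`.
#' @return data.frame with columns `id` and `rule` (one of too_short,
#'   not_multiple_of_3, ambiguity, internal_stop).
#' @export
rejection_report <- function(x) {
  stopifnot(inherits(x, "cds_set"))
  x$rejected
}

#' Write the rejection report as TSV
#'
#' @param x a `cds_set`.
#' @param path output path.
#' @export
write_rejection_report <- function(x, path) {
  write.table(rejection_report(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an expression table (id, FPKM)
#'
#' Two-column delimited text with an optional header. Rows with FPKM at or
#' below the plot threshold are retained but flagged, so the strict
#' "FPKM above 1" filter can be applied downstream.
#'
#' @param path path to a tab- or whitespace-delimited two-column file.
#' @param plot_threshold FPKM threshold for the expression plots (strict;
#'   default 1).
#' @return data.frame with columns id, fpkm, log10_fpkm (NA when fpkm is 0)
#'   and above_threshold (fpkm strictly greater than `plot_threshold`).
#' @export
read_expression_table <- function(path, plot_threshold = 1) {
  if (!file.exists(path)) stop("cannot read expression table: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty expression table")
  fields <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) stop("malformed expression row ", bad[[1L]])
  first_val <- fields[[1L]][[2L]]
  has_header <- is.na(suppressWarnings(as.numeric(first_val)))
  if (has_header) fields <- fields[-1L]
  if (length(fields) == 0L) stop("empty expression table")
  ids <- vapply(fields, `[`, character(1), 1L)
  vals <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  if (anyNA(vals)) {
    stop("non-numeric FPKM in row ", which(is.na(vals))[[1L]] + has_header)
  }
  if (any(vals < 0)) stop("negative FPKM in row ",
                          which(vals < 0)[[1L]] + has_header)
  data.frame(
    id = ids,
    fpkm = vals,
    log10_fpkm = ifelse(vals > 0, log10(vals), NA_real_),
    above_threshold = vals > plot_threshold,
    stringsAsFactors = FALSE
  )
}

#' Read a gene-set id list (one id per line)
#'
#' @param path path to a plain-text file.
#' @return character vector of ids.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("cannot read gene set: ", path)
  ids <- trimws(readLines(path))
  ids[nzchar(ids)]
}

#' Write a CDS set (or named sequences) as multi-FASTA
#'
#' @param sequences named character vector of nucleotide sequences.
#' @param path output path.
#' @param rna write in RNA (U) alphabet; default FALSE.
#' @export
write_fasta <- function(sequences, path, rna = FALSE) {
  if (rna) sequences <- dna_to_rna(sequences)
  out <- character(2L * length(sequences))
  out[c(TRUE, FALSE)] <- paste0(">", names(sequences))
  out[c(FALSE, TRUE)] <- unname(sequences)
  writeLines(out, path)
  invisible(path)
}
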