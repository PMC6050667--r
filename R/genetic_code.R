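#' @importFrom stats cor.test lm coef prcomp quantile rlnorm rbeta runif sd
#' @importFrom utils read.table write.table
NULL

# Standard genetic code (translation table 1) and derived lookups.
# Codons are kept internally in DNA alphabet (T); all user-facing output uses
# the RNA alphabet (U), the convention for transcriptome codon-usage tables.

.codon_universe <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))  # AAA, CAA, ..., TTT
}

#' The standard genetic code and its synonymous-family structure
#'
#' Returns the standard code (translation table 1) together with the lookups
#' the codon-usage statistics need: the synonymous family of each amino acid
#' and its degeneracy class. Leu, Ser and Arg are kept as single six-fold
#' families; Ile is the only three-fold family; Met and Trp are singletons.
#'
#' @return A list with elements `codon_to_aa` (named character, 64 DNA
#'   codons), `stop_codons`, `sense_codons` (61), `informative_codons` (59,
#'   sense minus ATG and TGG), `families` (list: amino acid -> codon set),
#'   `degeneracy` (named integer: amino acid -> family size).
#' @export
genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  stops <- codons[code == "*"]
  sense <- codons[code != "*"]
  fam <- split(sense, code[sense])
  deg <- vapply(fam, length, integer(1))
  list(
    codon_to_aa = code,
    stop_codons = stops,
    sense_codons = sense,
    informative_codons = setdiff(sense, c("ATG", "TGG")),
    families = fam,
    degeneracy = deg
  )
}

# cached at load time; the code never changes
.gc_env <- new.env(parent = emptyenv())

.code <- function() {
  if (is.null(.gc_env$code)) .gc_env$code <- genetic_code()
  .gc_env$code
}

#' Convert codons between DNA (T) and RNA (U) alphabets
#'
#' @param x character vector of codons or sequences.
#' @return `x` with T replaced by U (`dna_to_rna`) or U by T (`rna_to_dna`).
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# base at a given codon position, for the 64-codon universe
.codon_base <- function(codons, pos) substr(codons, pos, pos)

# Kyte-Doolittle hydropathy scale
.kyte_doolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

.aromatic <- c("F", "Y", "W")

.amino_acids <- sort(names(.kyte_doolittle))
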