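#!/usr/bin/env Rscript
# Nucleotide composition of the selected dataset: base proportions,
# positional GC, the GC-content histogram and the four positional
# dinucleotide profiles. Writes results/composition/*.

suppressPackageStartupMessages(library(codonbias))

x <- read_cds_fasta("results/data/selected/cds.fasta")
dir.create("results/composition", recursive = TRUE, showWarnings = FALSE)

pooled <- nucleotide_content(x)
per_rec <- nucleotide_content(x, pooled = FALSE)
write.table(per_rec, "results/composition/per_record.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("pooled base content: A %.1f%%  C %.1f%%  G %.1f%%  U %.1f%%  (GC %.1f%%)\n",
            100 * pooled$p_A, 100 * pooled$p_C, 100 * pooled$p_G,
            100 * pooled$p_U, 100 * pooled$gc_overall))
cat(sprintf("positional GC: GC1 %.1f%%  GC2 %.1f%%  GC3 %.1f%%\n",
            100 * pooled$gc1, 100 * pooled$gc2, 100 * pooled$gc3))

h <- gc_histogram(per_rec$gc_overall)
write.table(data.frame(interval = names(h), count = as.integer(h)),
            "results/composition/gc_histogram.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("GC-content histogram (half-open intervals):\n")
print(h)
cat(sprintf("modal interval: %s\n", names(h)[which.max(h)]))

dn <- dinucleotide_profiles(x)
write.table(dn, "results/composition/dinucleotides.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
extreme <- dn[order(-abs(dn$ratio - 1)), ][1:5, ]
cat("dinucleotides deviating most from the 0.0625 unbiased expectation:\n")
print(extreme, row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)
  ggsave("results/figures/gc_histogram.png",
         ggplot(per_rec, aes(gc_overall)) +
           geom_histogram(binwidth = 0.02, fill = "steelblue") +
           labs(x = "overall GC content", y = "CDS count"),
         width = 5, height = 4, dpi = 120)
  ggsave("results/figures/dinucleotide_ratios.png",
         ggplot(dn, aes(dinucleotide, ratio, group = dataset,
                        colour = dataset)) +
           geom_line() + geom_hline(yintercept = 1, linetype = 2) +
           labs(y = "observed / expected frequency"),
         width = 7, height = 4, dpi = 120)
}
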