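---
title: "Measuring codon usage bias and its evolutionary drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring codon usage bias and its evolutionary drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Synonymous codons are not used interchangeably. In most genomes the choice
among synonyms reflects a balance of mutational composition bias (which
shifts whole-genome base content, most visibly at third codon positions,
where most changes are synonymous), translational selection (which favours
codons matching the tRNA pool, most strongly in highly expressed genes), and
drift. `codonbias` implements the standard index suite used to measure this
balance on a set of transcriptome-derived coding sequences (CDSs), together
with a generative simulator in which the mutational and selective forces are
explicit parameters, so every inference step can be checked against known
ground truth.

# Input filtering

`read_cds_fasta()` accepts a nucleotide multi-FASTA (DNA or RNA alphabet,
any case) and keeps a sequence only if it is at least 300 bp (the
conventional floor for trusting a predicted ORF), a multiple of 3, free of
ambiguity characters, and free of in-frame internal stop codons. Each
rejected id is reported with the first rule it failed. A single terminal
stop codon is allowed and stripped; every downstream statistic operates on
sense codons only. Internal-stop tolerance is configurable
(`max_internal_stops`), but the default of zero is deliberate: RSCU and ENC
arithmetic assume a clean reading frame, and a sequence with an internal
stop is either mis-framed or pseudogenised. We do not require a start
codon — upstream ORF callers already decide that, and a fragment CDS is
still informative about codon usage.

# The statistics

**RSCU.** For codon $c$ in a synonymous family of size $n$ with family
total $N$, $\mathrm{RSCU}_c = c_\text{obs} / (N/n)$: 1 means no bias, and
values sum to $n$ within each observed family. Codons are classified with
strict thresholds — preferred $>1$, highly preferred $>1.25$, avoided
$<0.75$ — and the ending-base tally of the preferred set summarises which
third base selection favours. Genome-level RSCU is computed from the summed
codon counts, not by averaging per-gene profiles; the two differ whenever
gene lengths vary, and the pooled form is what a genome-wide codon table
means.

**ENC.** Wright's effective number of codons estimates, per gene, how many
codons are effectively in use (61 = unbiased, 20 = one codon per amino
acid). Per amino acid with family total $m \ge 2$ the codon homozygosity is
$F = (m\sum p_i^2 - 1)/(m-1)$; $F$ is averaged within each degeneracy class
(Leu, Ser and Arg kept as single six-fold families) and
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
clamped at 61. Ile (the only three-fold family) falls back to
$(\bar F_2 + \bar F_4)/2$ when unobserved; any other missing or
non-positive class average leaves ENC undefined with a machine-readable
reason rather than a silent number. Families observed exactly once are
excluded ($F$ is undefined at $m = 1$).

**The expected-ENC curve.** Under pure compositional bias, ENC is a
function of third-position GC content $s$ alone:
$\mathrm{ENC}_{exp} = 2 + s + 29/(s^2 + (1-s)^2)$. Genes below the curve
use fewer codons than their composition explains — the signature of
selection. The per-gene deviation ratio
$(\mathrm{ENC}_{exp} - \mathrm{ENC}_{obs})/\mathrm{ENC}_{exp}$ is
histogrammed in zero-aligned 0.01-wide bins. GC3 here includes the third
positions of all sense codons (AUG and UGG included); a `gc3s` variant
excluding them is carried in the index table for sensitivity checks.

**PR2.** Parity Rule 2 states that without strand-specific forces,
$A \approx U$ and $G \approx C$ at third positions. Each gene is placed at
$x = G_3/(G_3+C_3)$, $y = A_3/(A_3+U_3)$; quadrant tallies around
$(0.5, 0.5)$ summarise the direction of violation. Points exactly on an
axis are counted as boundary, and zero denominators flag the point
undefined; neither enters the quadrant tallies. By default all sense codons
contribute; `fourfold_only = TRUE` restricts to fourfold-degenerate codon
boxes, the stricter classical convention.

**Neutrality regression.** GC12 (mean of GC1 and GC2) is regressed on GC3
by ordinary least squares across genes. If mutational composition drove all
positions equally, the slope would be 1; selection on first and second
positions flattens it. The slope is reported directly and as
mutation% $= 100\beta$ / selection% $= 100(1-\beta)$. We treat GC12 as the
response because third positions absorb mutational bias most freely, making
GC3 the natural predictor.

**Protein indices and PCA.** GRAVY (mean Kyte–Doolittle hydropathy),
aromaticity (fraction of F/Y/W) and length are computed per translated
gene. Three decompositions use `stats::prcomp` on column-centred, unscaled
matrices: gene-wise RSCU (59 informative codons: 61 sense minus AUG/UGG),
codon-wise RSCU (the transpose), and gene-wise amino-acid proportions.
RSCU values already share a scale, so scaling is off by default (a
`scale.` switch exists). Axis signs are fixed by forcing the
largest-magnitude loading positive, making scores row-order invariant. For
genes in which a family is entirely unobserved, the missing RSCU entries
are imputed at 1 — the no-information value that preserves family mass —
rather than 0, which would encode strong avoidance that a short gene
cannot support; `impute = "zero"` and `"drop"` are available for
sensitivity analysis.

# The synthetic generator

`simulate_cds_set()` draws, per gene: a protein length from a lognormal
(meanlog $\log 300$, sdlog 0.45, truncated at 100 aa — matching a
transcriptome whose mean CDS is just under 1 kb), an FPKM from a lognormal
(meanlog 1, sdlog 2, a typical RNA-seq spread of several orders of
magnitude), a mutational GC bias $m_g \sim
\mathrm{Beta}(m\kappa, (1-m)\kappa)$ with concentration $\kappa = 50$
(per-gene GC3 s.d. ≈ 0.07, the kind of spread real transcriptomes show),
and an effective selection strength $s_g = s\,\max(0,\, 1 + c\, z_g)$ with
$z_g$ the gene's log10-FPKM z-score and $c$ the expression coupling. Codons
are then drawn independently with weight
$\mathrm{base}(m_g) \times e^{s_g \cdot [\text{ending} \in T]}$, where
$T$ is the selected ending set (G+C, or C only) and $\mathrm{base}(m)$
splits third-position mass $m$ evenly over G/C and $1-m$ over A/U. Under
`mutation_scope = "all"` the same base weights apply to all three codon
positions (amino-acid composition then co-varies with $m_g$); under the
default `"third"` scope the amino acid is drawn from a uniform profile
first, so amino-acid composition is null by construction and any coupling
detected between amino-acid usage and codon bias is a bug signal. A start
AUG is prepended and a random stop appended, so output always passes the
input filters.

These defaults are the package's study conditions and are not adjusted per
analysis; scenario parameters (e.g. $s = 2$ on C-ending codons with
coupling 0.5 for the selection regime, or a generating slope of 0.32 with
noise s.d. 0.01 at $n = 2000$ for regression recovery) are stated where
used in `analysis/` and `scripts/acceptance.R`.

Two properties of the model are worth knowing before interpreting results.
First, symmetric GC-ending selection without expression coupling is
mathematically indistinguishable from raising $m$ — both apply the same
exponential tilt to third-base probabilities — so such genes stay *on* the
expected-ENC curve. Only asymmetric selection (e.g. C-only), or coupling
that varies $s_g$ across genes, produces the below-curve pattern. Second,
under the all-positions mutation scope the realized neutrality slope is
high but below 1 (≈ 0.8 at default conditions) because the genetic code
constrains first and second positions more than third; the contrast with
the near-zero slope of the third-only scope is the meaningful signal.

What the generator does **not** emulate: amino-acid composition that
co-varies with expression or function, length–bias correlations, isochore
structure, dinucleotide-level mutational effects (e.g. CpG suppression),
or any evolutionary time dynamics. Passing tests on simulated data
therefore validate the arithmetic and the inference logic, not the
biological completeness of the model.

# Numerical choices and degenerate inputs

* ENC values above 61 after summation are clamped to 61 and flagged —
  the estimator overshoots slightly for near-uniform usage at finite
  counts.
* Wright's $F$ is exactly unbiased for $\sum p_i^2$, but ENC (a sum of
  reciprocals of averaged $F$) is not scale-invariant at finite counts and
  carries small finite-length effects; together with the curve itself
  being an approximation (true neutral ENC at $s = 0.5$ is 61, the curve
  gives 60.5), mean deviations of up to ±2% arise for unbiased genes of
  realistic length. Tests bound the neutral mean deviation by 0.02 rather
  than asserting exact zero.
* The expected-ENC curve peaks at $s \approx 0.502$, not exactly 0.5 —
  the linear $+s$ term shifts the maximum of the symmetric term.
* Half-open binning `[lo, hi)` is used for the GC histogram and deviation
  histogram; deviation bins are aligned so an edge falls at 0.
* GC-group breakpoints for stratification and PCA overlays default to the
  dataset's own GC quartiles rather than fixed values — published interval
  bounds of this kind are quartiles of the dataset they came from.
* Expression filtering for stratification is strictly FPKM > 1; rows at
  or below the threshold are retained in the parsed table but flagged.
* Dinucleotide ratios divide observed frequencies by the product of the
  positional marginals of the dataset in question (e.g. the 1st&2nd
  dataset uses position-1 and position-2 marginals), which makes the ratio
  a pure association measure; `marginals = "global"` switches to
  whole-sequence marginals. The initial ATG (when present) and terminal
  stop are excluded from all four dinucleotide datasets.
* The deviation histogram is deterministic; no resampling is involved in
  any headline statistic, and the only randomness anywhere is the seeded
  generator.

# Problem sizes

The packaged analyses and checks use 2,000 simulated genes (mean ≈ 330
codons) for distribution-level claims, 500 random count tables for
dual-route formula agreement, and 150–1,000 genes for scenario contrasts —
sizes at which sampling error is well below every asserted effect while a
full run stays comfortably interactive.

# Known limitations

ENC is undefined (with a reason code) for very short or compositionally
extreme genes; correlation and PCA stages drop such genes from affected
rows rather than imputing. CAI, CBI, Fop and tRNA-adaptation indices are
out of scope — with expression measured directly (FPKM), ranking genes by
a proxy for expression is unnecessary. Correspondence analysis, the
classical alternative to PCA for codon counts, is a possible extension;
PCA on RSCU is used here because RSCU already removes amino-acid
composition effects, which is also why the 59-codon convention (excluding
the uninformative AUG and UGG) is applied throughout the multivariate
stage.
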