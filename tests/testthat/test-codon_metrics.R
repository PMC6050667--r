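test_that("codon counting equals a brute-force triplet tally", {
  set.seed(31)
  seqs <- replicate(10, random_cds_seq(sample(100:500, 1)))
  x <- cds_set(paste0("g", 1:10), seqs)
  counts <- count_codons(x)
  for (i in 1:10) {
    want <- oracle_codon_count(x$records$sense[i])
    expect_equal(counts[i, names(want)], want, ignore_attr = TRUE)
  }
  expect_equal(rowSums(counts), x$records$n_codons, ignore_attr = TRUE)
  # stop columns are empty for validated sets
  expect_true(all(counts[, c("TAA", "TAG", "TGA")] == 0))
})

test_that("RSCU matches hand computations and classifies strictly", {
  counts <- stats::setNames(rep(0, 64), names(Biostrings::GENETIC_CODE))
  counts["TTT"] <- 50
  counts["TTC"] <- 50
  prof <- rscu(counts)
  phe <- prof[prof$codon %in% c("UUU", "UUC"), ]
  expect_equal(phe$rscu, c(1, 1))
  cl <- rscu_classify(prof)
  expect_false(any(c("UUU", "UUC") %in% cl$preferred))
  expect_false(any(c("UUU", "UUC") %in% cl$avoided))

  # Leu family worked example: counts 1,4,4,3,2,4 -> mean 3
  leu <- c(CTA = 1, CTC = 4, CTG = 4, CTT = 3, TTA = 2, TTG = 4)
  counts2 <- stats::setNames(rep(0, 64), names(Biostrings::GENETIC_CODE))
  counts2[names(leu)] <- leu
  counts2["ATG"] <- 5  # keep the table non-trivial elsewhere
  prof2 <- rscu(counts2)
  got <- prof2$rscu[match(c("CUA", "CUC", "CUG", "CUU", "UUA", "UUG"),
                          prof2$codon)]
  expect_equal(got, c(1, 4, 4, 3, 2, 4) / 3, tolerance = 1e-12)
  expect_equal(sum(got), 6, tolerance = 1e-12)

  expect_error(rscu(stats::setNames(rep(0, 64),
                                    names(Biostrings::GENETIC_CODE))),
               "all-zero")
})

test_that("RSCU family sums equal family sizes on simulated genes", {
  sim <- simulate_cds_set(simulation_params(n_genes = 200, seed = 32))
  counts <- count_codons(as_cds_set(sim))
  code <- genetic_code()
  for (g in sample(nrow(counts), 25)) {
    prof <- rscu(counts[g, , drop = FALSE])
    for (aa in names(code$families)) {
      fam <- chartr("T", "U", code$families[[aa]])
      vals <- prof$rscu[prof$codon %in% fam]
      if (!anyNA(vals)) {
        expect_equal(sum(vals), length(fam), tolerance = 1e-9)
      }
    }
  }
})

test_that("ENC reaches its closed-form extremes", {
  code <- genetic_code()
  # one codon per amino acid, each seen twice: maximal bias, ENC = 20
  counts <- stats::setNames(rep(0, 64), names(Biostrings::GENETIC_CODE))
  for (aa in names(code$families)) {
    counts[code$families[[aa]][1]] <- 2
  }
  res <- enc(counts)
  expect_equal(res$enc, 20, tolerance = 1e-12)

  # uniform usage at large counts: estimator exceeds 61 and is clamped
  uniform <- stats::setNames(rep(0, 64), names(Biostrings::GENETIC_CODE))
  uniform[code$sense_codons] <- 1000
  res2 <- enc(uniform)
  expect_equal(res2$enc, 61)
  expect_true(res2$clamped)
})

test_that("ENC and RSCU agree with independent oracles on random tables", {
  set.seed(33)
  for (i in 1:500) {
    counts <- random_count_table()
    if (sum(counts) == 0) next
    got <- enc(counts)$enc
    want <- oracle_enc(counts)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, want, tolerance = 1e-9)
    }
    prof <- rscu(counts)
    want_rscu <- oracle_rscu(counts)
    expect_equal(prof$rscu[match(chartr("T", "U", names(want_rscu)),
                                 prof$codon)],
                 unname(want_rscu), tolerance = 1e-9)
  }
})

test_that("ENC stabilises under count scaling and decreases under concentration", {
  set.seed(34)
  counts <- random_count_table()
  counts <- counts * 3
  # RSCU is exactly scale-invariant; Wright's F depends on the family total
  # m, so ENC is only asymptotically scale-invariant and converges as counts
  # grow
  expect_equal(rscu(counts)$rscu, rscu(counts * 7)$rscu, tolerance = 1e-12)
  expect_equal(enc(counts * 100)$enc, enc(counts * 10000)$enc,
               tolerance = 1e-3)

  # one-parameter sweep: concentrate mass within every family
  code <- genetic_code()
  enc_at <- vapply(c(0, 0.5, 1, 2, 4), function(t) {
    counts <- stats::setNames(rep(0, 64), names(Biostrings::GENETIC_CODE))
    for (aa in names(code$families)) {
      fam <- code$families[[aa]]
      w <- exp(t * (seq_along(fam) == 1))
      counts[fam] <- round(1000 * w / sum(w))
    }
    enc(counts)$enc
  }, numeric(1))
  expect_true(all(diff(enc_at) < 0))
})

test_that("the expected-ENC curve matches its closed form on the full grid", {
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(1.0), 32.0)
  grid <- seq(0.001, 1, by = 0.001)
  vals <- expected_enc(grid)
  expect_equal(vals, 2 + grid + 29 / (grid^2 + (1 - grid)^2),
               tolerance = 1e-15)
  expect_true(all(vals <= 61 + 1e-12))
  # unimodal with the maximum near s = 0.5 (the linear "+ s" term shifts
  # the peak slightly above the symmetry point of the quadratic term)
  s_max <- grid[which.max(vals)]
  expect_gt(s_max, 0.49)
  expect_lt(s_max, 0.52)
  expect_true(all(diff(vals[grid <= 0.49]) > 0))
  expect_true(all(diff(vals[grid >= 0.52]) < 0))
  expect_error(expected_enc(0), "gc3")
  expect_error(expected_enc(1.2), "gc3")
})

test_that("ENC deviation is the relative shortfall from expectation", {
  expect_equal(enc_deviation(54.45, 60.5), 0.1, tolerance = 1e-12)
  expect_equal(enc_deviation(45, 45), 0)
  expect_true(enc_deviation(62, 60) < 0)
})

test_that("protein indices reproduce scale values and simplex structure", {
  res <- protein_indices(c(a = strrep("I", 50)))
  expect_equal(res$indices$gravy, 4.5)
  expect_equal(protein_indices("FYW")$indices$aromo, 1.0)
  uni <- protein_indices("ACDEFGHIKLMNPQRSTVWY")
  expect_equal(unname(uni$aa_proportion[1, ]), rep(0.05, 20))
  expect_equal(uni$indices$aromo, 0.15)
  expect_equal(rowSums(uni$aa_proportion), 1, ignore_attr = TRUE)
  expect_error(protein_indices("ACDX"), "position 4 of protein 1")
})

test_that("the per-gene index table is internally consistent", {
  sim <- simulate_cds_set(simulation_params(n_genes = 40, seed = 35))
  x <- as_cds_set(sim)
  idx <- gene_index_table(x, expression = transform(
    sim$expression, log10_fpkm = log10(fpkm), above_threshold = fpkm > 1))
  expect_equal(nrow(idx), 40L)
  expect_equal(idx$gc12, (idx$gc1 + idx$gc2) / 2, tolerance = 1e-12)
  expect_equal(idx$deviation,
               (idx$enc_expected - idx$enc) / idx$enc_expected,
               tolerance = 1e-12)
  expect_equal(idx$enc_expected, expected_enc(idx$gc3), tolerance = 1e-12)
  expect_equal(idx$fpkm, sim$expression$fpkm[match(idx$id,
                                                   sim$expression$id)])
  expect_true(all(idx$enc >= 20 - 1e-9 & idx$enc <= 61 + 1e-9,
                  na.rm = TRUE))
})
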