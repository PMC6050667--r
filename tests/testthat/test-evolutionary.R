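.mk_index <- function(gc3, enc) {
  data.frame(id = paste0("g", seq_along(gc3)), gc3 = gc3, enc = enc,
             enc_expected = expected_enc(gc3))
}

test_that("ENC plot layers carry curve, status and the strong-bias count", {
  idx <- .mk_index(gc3 = c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
                   enc = c(30, 33, 34, 50, 55, 61))
  ep <- enc_plot_data(idx)
  expect_equal(nrow(ep$curve), 1000L)
  expect_equal(ep$curve$gc3[1], 0.001)
  expect_equal(ep$curve$gc3[1000], 1.000)
  expect_equal(ep$n_strong, 3L)  # exactly three genes below ENC 35
  expect_true(all(ep$points$status[ep$points$enc <
                                     ep$points$enc_expected] == "below"))
  expect_error(enc_plot_data(.mk_index(0.5, NA)[0, ]), "at least 2")
})

test_that("unbiased simulated genes hug the curve, selected genes fall below", {
  neutral <- simulate_cds_set(simulation_params(n_genes = 150, seed = 41))
  idx_n <- gene_index_table(as_cds_set(neutral))
  # uniform synonymous choice: mean deviation near 0
  expect_lt(abs(mean(idx_n$deviation, na.rm = TRUE)), 0.02)

  # symmetric GC-ending selection is indistinguishable from compositional
  # bias and stays on the curve; asymmetric (C-only) selection distorts
  # usage beyond what GC3 explains and drops points below it
  sel <- simulate_cds_set(simulation_params(n_genes = 150,
                                            selection_strength = 1.5,
                                            selection_target = "C",
                                            seed = 41))
  idx_s <- gene_index_table(as_cds_set(sel))
  below <- mean(idx_s$enc < idx_s$enc_expected, na.rm = TRUE)
  expect_gt(below, 0.9)
})

test_that("deviation histogram bins are zero-aligned and complete", {
  h <- deviation_histogram(rep(0.005, 10))
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$bin_lo, h$bin_hi), c(0, 0.01))
  expect_equal(h$frequency, 1)

  h2 <- deviation_histogram(c(-0.005, 0.005))
  expect_equal(h2$bin_lo, c(-0.01, 0))
  expect_equal(h2$frequency, c(0.5, 0.5))

  set.seed(42)
  dev <- rnorm(500, 0.08, 0.04)
  h3 <- deviation_histogram(dev)
  expect_equal(sum(h3$frequency), 1, tolerance = 1e-12)
  expect_equal(sum(h3$count), 500L)
  brute <- table(floor(dev / 0.01))
  expect_equal(h3$bin_lo[which.max(h3$count)],
               as.numeric(names(brute)[which.max(brute)]) * 0.01)
  expect_error(deviation_histogram(numeric(0)), "no deviation")
})

test_that("PR2 coordinates, quadrants and degenerate denominators behave", {
  counts <- matrix(0, 2, 64,
                   dimnames = list(c("allc", "mix"),
                                   names(Biostrings::GENETIC_CODE)))
  counts["allc", "GCC"] <- 50             # all third positions C
  counts["mix", c("GCA", "GCT", "GCG", "GCC")] <- c(10, 30, 10, 30)
  res <- pr2_analysis(counts)
  expect_equal(res$points$quadrant[1], "undefined")  # A3+U3 = 0
  expect_equal(res$points$x[2], 0.25)
  expect_equal(res$points$y[2], 0.25)
  expect_equal(res$points$quadrant[2], "3")
  expect_equal(sum(res$quadrant_counts), 2L)

  # boundary points are excluded from quadrant tallies
  b <- matrix(0, 1, 64, dimnames = list("b", names(Biostrings::GENETIC_CODE)))
  b[1, c("GCA", "GCT", "GCG", "GCC")] <- c(5, 5, 3, 7)
  expect_equal(pr2_analysis(b)$points$quadrant, "boundary")
})

test_that("quadrant counts partition the gene set", {
  set.seed(43)
  sim <- simulate_cds_set(simulation_params(n_genes = 120, seed = 43))
  res <- pr2_analysis(as_cds_set(sim))
  expect_equal(sum(res$quadrant_counts), 120L)
  expect_equal(unname(res$quadrant_counts),
               unname(table(factor(res$points$quadrant,
                                   c("1", "2", "3", "4", "boundary",
                                     "undefined")))),
               ignore_attr = TRUE)
})

test_that("U/C-favouring third-position bias concentrates points in Q3", {
  # sample codons with pyrimidine-favouring third-base weights
  # (A .2, U .3, G .2, C .3): both PR2 coordinates sit below 0.5
  set.seed(44)
  code <- genetic_code()
  third <- substr(code$sense_codons, 3, 3)
  w <- c(A = 0.2, T = 0.3, G = 0.2, C = 0.3)[third]
  counts <- t(vapply(1:200, function(i) {
    tab <- table(factor(sample(code$sense_codons, 200, replace = TRUE,
                               prob = w), levels = names(Biostrings::GENETIC_CODE)))
    as.numeric(tab)
  }, numeric(64)))
  colnames(counts) <- names(Biostrings::GENETIC_CODE)
  res <- pr2_analysis(counts)
  expect_equal(names(which.max(res$quadrant_counts[1:4])), "Q3")
  expect_gt(res$quadrant_counts[["Q3"]], 150)
})

test_that("neutrality fit recovers degenerate and noisy generating slopes", {
  gc3 <- seq(0.2, 0.8, length.out = 50)
  # exact generating relationships; lm warns about the perfect fit
  fit1 <- suppressWarnings(neutrality_fit(gc12 = gc3, gc3 = gc3))
  expect_equal(fit1$slope, 1, tolerance = 1e-12)
  expect_equal(fit1$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit1$mutation_pct, 100, tolerance = 1e-9)

  fit0 <- suppressWarnings(neutrality_fit(gc12 = rep(0.40, 50), gc3 = gc3))
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
  expect_equal(fit0$selection_pct, 100, tolerance = 1e-9)
  expect_equal(fit0$mutation_pct + fit0$selection_pct, 100)

  set.seed(45)
  gc3 <- runif(2000, 0.2, 0.8)
  gc12 <- 0.2 + 0.32 * gc3 + rnorm(2000, 0, 0.01)
  fit <- neutrality_fit(gc12, gc3)
  expect_equal(fit$slope, 0.32, tolerance = 0.02 / 0.32)
  expect_equal(fit$n, 2000L)

  expect_error(neutrality_fit(c(0.4, 0.5), c(0.3, 0.4)), "at least 3")
  expect_error(neutrality_fit(runif(10), rep(0.5, 10)), "variance")
})

test_that("generating slopes are recovered within 3 standard errors across seeds", {
  for (seed in 1:20) {
    set.seed(seed)
    beta <- runif(1, 0.1, 0.9)
    gc3 <- runif(300, 0.25, 0.75)
    gc12 <- 0.25 + beta * gc3 + rnorm(300, 0, 0.02)
    fit <- neutrality_fit(gc12, gc3)
    se <- 0.02 / (sd(gc3) * sqrt(300))
    expect_lt(abs(fit$slope - beta), 3 * se + 0.01)
  }
})

test_that("correlation suite reports exact, null and near-deterministic cases", {
  x <- seq_len(100)
  df <- data.frame(a = x, b = x, c = -2 * x + rnorm(100, 0, 1e-8),
                   k = rep(1, 100))
  res <- correlation_suite(df, list(c("a", "b"), c("a", "c"), c("a", "k")))
  expect_equal(res$pearson_r[1], 1, tolerance = 1e-12)
  expect_lt(res$pearson_r[2], -0.99)
  expect_true(is.na(res$pearson_r[3]))
  expect_equal(res$note[3], "constant")

  set.seed(46)
  ok <- vapply(1:100, function(i) {
    d <- data.frame(x = rnorm(1000), y = rnorm(1000))
    r <- correlation_suite(d, list(c("x", "y")))
    abs(r$pearson_r) < 0.08 && r$p_value > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("expression stratification splits at quartiles and demands expressed rows", {
  # constructed GC with known quartiles 0.418 / 0.508
  gc <- c(rep(0.40, 25), rep(0.45, 50), rep(0.55, 25))
  idx <- data.frame(id = paste0("g", 1:100), gc = gc,
                    enc = rnorm(100, 50, 2),
                    fpkm = rep(10, 100), log10_fpkm = 1)
  st <- expression_stratification(idx, gc_breaks = c(0.418, 0.508))
  expect_equal(unname(table(st$table$gc_group)), c(25L, 50L, 25L),
               ignore_attr = TRUE)

  idx$fpkm <- 0.5
  expect_error(expression_stratification(idx), "no rows above threshold")
})

test_that("expression-coupled selection lowers ENC in the high-GC group", {
  sim <- simulate_cds_set(simulation_params(
    n_genes = 400, selection_strength = 1.5, selection_target = "GC",
    selection_expression_coupling = 0.8, seed = 47))
  idx <- gene_index_table(as_cds_set(sim), expression = transform(
    sim$expression, log10_fpkm = log10(fpkm), above_threshold = fpkm > 1))
  st <- expression_stratification(idx)
  gs <- st$group_summary
  expect_lt(gs$mean_enc[gs$gc_group == "high"],
            gs$mean_enc[gs$gc_group == "low"])
})

test_that("gene-set comparison flags against dataset means", {
  idx <- data.frame(id = paste0("g", 1:10),
                    enc = c(50, rep(52.45, 9)),
                    gc12 = c(0.45, rep(0.44, 9)),
                    gc3 = c(0.45, rep(0.50, 9)))
  res <- gene_set_compare(idx, c("g1"))
  expect_equal(res$table$gc12_gc3_ratio, 1.0)
  expect_true(res$table$enc_below_average)  # 50 < mean (~52.2)
  expect_false(res$table$ratio_below_average)

  expect_error(gene_set_compare(idx, c("zz")), "no focal gene ids")
  expect_warning(res2 <- gene_set_compare(idx, c("g1", "zz")), "not in index")
  expect_equal(res2$missing_ids, "zz")
})

test_that("a focal set drawn from the background flags about half below average", {
  set.seed(48)
  idx <- data.frame(id = paste0("g", 1:2000),
                    enc = rnorm(2000, 52, 4),
                    gc12 = runif(2000, 0.35, 0.55),
                    gc3 = runif(2000, 0.35, 0.65))
  focal <- sample(idx$id, 200)
  res <- gene_set_compare(idx, focal)
  # binomial(200, 0.5) 99.9% bounds
  expect_gt(res$summary[["enc_below"]], 200 * 0.5 - 3.3 * sqrt(200 * 0.25))
  expect_lt(res$summary[["enc_below"]], 200 * 0.5 + 3.3 * sqrt(200 * 0.25))
})
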