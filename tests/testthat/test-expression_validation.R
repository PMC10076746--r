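test_that("median-of-ratios size factors recover an exact library-size shift", {
  base <- matrix(rep(c(10, 100, 1000, 50), 3), ncol = 3)
  base[, 2] <- base[, 2] * 2  # sample 2 sequenced twice as deep
  m <- make_expr(base, normalized = FALSE)
  norm <- normalize_counts(m)
  sf <- attr(norm, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(sf[2] / sf[3]), 2)
  # identical profiles -> normalized columns equal
  expect_equal(unclass(norm)[, 1], unclass(norm)[, 2])
})

test_that("normalization rejects degenerate inputs", {
  expect_error(normalize_counts(make_expr(matrix(1:3, ncol = 1),
                                          normalized = FALSE)),
               "2 samples")
  allzero <- make_expr(matrix(c(0, 1, 1, 0), 2), normalized = FALSE)
  expect_error(normalize_counts(allzero), "size factors")
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(401)
  counts <- matrix(rpois(200 * 6, lambda = rlnorm(200, 4, 1)), ncol = 6)
  counts <- round(sweep(counts, 2, c(1, 2, 0.5, 1.5, 1, 0.8), "*"))
  m <- make_expr(counts, normalized = FALSE)
  sf <- attr(normalize_counts(m), "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("blood expression calls use the cohort mean threshold", {
  m <- make_expr(rbind(c(0, 0, 0), c(1, 2, 3), c(0.4, 0.3, 0.2)),
                 genes = c("silent", "on", "dim"))
  expect_false(expressed_in_blood(m, "silent"))
  expect_true(expressed_in_blood(m, "on"))
  expect_false(expressed_in_blood(m, "dim"))         # mean 0.3 < 1
  expect_false(expressed_in_blood(m, "absent_gene")) # absent -> FALSE
})

test_that("gene z-score uses the population sd and handles sd = 0", {
  m <- make_expr(rbind(c(1, 2, 3), c(5, 5, 5)), genes = c("g", "flat"))
  # hand computation: mean 2, population sd sqrt(2/3) = 0.8165
  expect_equal(gene_zscore(m, "g", "s3"), (3 - 2) / sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(round(gene_zscore(m, "g", "s3"), 4), 1.2247)
  expect_equal(gene_zscore(m, "g", "s2"), 0)      # at the cohort mean
  expect_equal(gene_zscore(m, "flat", "s1"), 0)   # constant gene
})

test_that("log2 fold change is pseudocount-guarded", {
  m <- make_expr(rbind(c(1000, 1000, 4000)), genes = "g")
  # cohort mean 2000; patient 4000 -> about log2(2)
  expect_equal(gene_log2fc(m, "g", "s3"), log2(4001 / 2001))
  expect_equal(gene_log2fc(m, "g", "s3"), 1, tolerance = 0.001)
  z <- make_expr(rbind(c(0, 0)), genes = "g")
  expect_equal(gene_log2fc(z, "g", "s1"), 0)  # 0/0 guarded to log2(1)
})

test_that("per-gene z-scores have cohort mean 0 and population variance 1", {
  cfg <- sim_config(seed = 9, n_trios = 30, n_chromosomes = 1,
                    genes_per_chromosome = 60)
  m <- normalize_counts(generate_cohort(cfg)$expression)
  genes <- rownames(m)[expressed_in_blood(m, rownames(m))]
  for (g in genes[1:10]) {
    zs <- vapply(colnames(m), function(s) gene_zscore(m, g, s), 0)
    expect_equal(mean(zs), 0, tolerance = 1e-10)
    expect_equal(mean(zs^2), 1, tolerance = 1e-10)
  }
})

test_that("a CNV whose genes are blood-silent is not evaluable", {
  genes <- gene_models(c("a", "b"), "chr1", c(100L, 5000L), c(200L, 6000L))
  m <- make_expr(rbind(c(0, 0, 0), c(10, 10, 10)), genes = c("a", "b"))
  cnv <- cnv_calls("s1", "chr1", 50L, 300L, "deletion")
  r <- cnv_dosage_validation(m, cnv, genes)
  expect_equal(r$gene_in_cnv, 1L)
  expect_equal(r$rna_in_cnv, 0L)
  expect_equal(r$status, "not_expressed")
  expect_error(direction_consistent(r), "not evaluable")
})

test_that("noise-free duplication recovers the planted copy ratio", {
  cfg <- sim_config(seed = 21, n_trios = 100, n_chromosomes = 1,
                    genes_per_chromosome = 40, noise_sd = 0,
                    blood_expressed_fraction = 1, round_counts = FALSE,
                    cnvs = list(plant_cnv(1, 1, first_gene = 5,
                                          n_genes = 10, copy_ratio = 1.5)))
  co <- generate_cohort(cfg)
  m <- normalize_counts(co$expression)
  r <- cnv_dosage_validation(m, co$cnvs[1, ], co$genes, seed = 3)
  expect_equal(r$gene_in_cnv, 10L)
  expect_equal(r$rna_in_cnv, 10L)
  # cohort mean includes the carrier: closed-form expectation with n = 100
  expect_equal(r$log2fc_cnv, log2(1.5 / (1 + 0.5 / 100)), tolerance = 0.01)
  expect_equal(r$log2fc_cnv, log2(1.5), tolerance = 0.05)
  expect_gt(r$zscore_cnv, 0)
  # out-CNV genes are identical across the cohort -> controls exactly 0
  expect_equal(r$zscore_random, rep(0, 3))
  expect_equal(r$log2fc_random, rep(0, 3))
  expect_true(direction_consistent(r))
})

test_that("a patient sitting at the cohort profile scores 0 everywhere", {
  vals <- matrix(rep(c(10, 20, 30, 40), 3), ncol = 3)
  genes <- gene_models(paste0("g", 1:4), "chr1",
                       c(100L, 1000L, 2000L, 3000L),
                       c(500L, 1500L, 2500L, 3500L))
  m <- make_expr(vals, genes = genes$gene_id)
  cnv <- cnv_calls("s2", "chr1", 50L, 1600L, "duplication")
  r <- cnv_dosage_validation(m, cnv, genes, seed = 1)
  expect_equal(r$zscore_cnv, 0)
  expect_equal(r$zscore_chr, 0)
  expect_equal(r$log2fc_cnv, 0)
})

test_that("dosage statistics match a brute-force oracle on a 5-gene chromosome", {
  genes <- gene_models(paste0("g", 1:5), "chr1",
                       c(100L, 1000L, 2000L, 3000L, 4000L),
                       c(500L, 1500L, 2500L, 3500L, 4500L))
  set.seed(77)
  vals <- matrix(rlnorm(5 * 6, 4, 0.3), nrow = 5)
  m <- make_expr(vals, genes = genes$gene_id)
  cnv <- cnv_calls("s4", "chr1", 50L, 1600L, "duplication")  # genes g1, g2
  r <- cnv_dosage_validation(m, cnv, genes, seed = 99)

  # oracle: plain-loop recomputation from first principles
  zfc <- function(gs) {
    z <- fc <- numeric(length(gs))
    for (i in seq_along(gs)) {
      x <- vals[match(gs[i], genes$gene_id), ]
      mu <- sum(x) / length(x)
      sdp <- sqrt(sum((x - mu)^2) / length(x))
      z[i] <- (x[4] - mu) / sdp
      fc[i] <- log2((x[4] + 1) / (mu + 1))
    }
    c(mean(z), mean(fc))
  }
  expect_equal(c(r$zscore_cnv, r$log2fc_cnv), zfc(c("g1", "g2")))
  expect_equal(c(r$zscore_chr, r$log2fc_chr), zfc(paste0("g", 1:5)))
  # every control-set mean must equal the mean of one of the C(3,2)
  # possible out-CNV subsets
  subsets <- combn(c("g3", "g4", "g5"), 2)
  possible <- apply(subsets, 2, zfc)
  for (i in 1:3) {
    expect_true(any(abs(possible[1, ] - r$zscore_random[i]) < 1e-12))
    expect_true(any(abs(possible[2, ] - r$log2fc_random[i]) < 1e-12))
  }
})

test_that("control-set draws are deterministic under the seed", {
  cfg <- sim_config(seed = 31, n_trios = 20, n_chromosomes = 1,
                    genes_per_chromosome = 80,
                    cnvs = list(plant_cnv(2, 1, 10, 10, 1.5)))
  co <- generate_cohort(cfg)
  m <- normalize_counts(co$expression)
  r1 <- cnv_dosage_validation(m, co$cnvs[1, ], co$genes, seed = 17)
  r2 <- cnv_dosage_validation(m, co$cnvs[1, ], co$genes, seed = 17)
  r3 <- cnv_dosage_validation(m, co$cnvs[1, ], co$genes, seed = 18)
  expect_identical(r1, r2)
  expect_false(identical(r1$zscore_random, r3$zscore_random))
})

test_that("too small an out-CNV gene pool is a sampling error", {
  genes <- gene_models(paste0("g", 1:3), "chr1",
                       c(100L, 1000L, 2000L), c(500L, 1500L, 2500L))
  m <- make_expr(matrix(10 + seq_len(9), nrow = 3), genes = genes$gene_id)
  cnv <- cnv_calls("s1", "chr1", 50L, 1600L, "duplication")
  expect_error(cnv_dosage_validation(m, cnv, genes), "gene universe")
})

test_that("direction consistency compares against extremes of the control sets", {
  mk <- function(type, z, fc, zr, fcr) {
    structure(list(sample_id = "s", chrom = "chr1", start = 1L, end = 2L,
                   cnv_type = type, gene_in_cnv = 5L, rna_in_cnv = 5L,
                   status = "evaluable", zscore_chr = 0, zscore_cnv = z,
                   zscore_random = zr, log2fc_chr = 0, log2fc_cnv = fc,
                   log2fc_random = fcr), class = "dosage_result")
  }
  expect_true(direction_consistent(
    mk("duplication", 3.745, 0.48, c(0.345, 0.245, -0.155),
       c(0.03, 0.02, -0.01))))
  expect_true(direction_consistent(
    mk("deletion", -5.025, -0.775, c(0.205, -0.23, 0.01),
       c(0.01, -0.04, -0.005))))
  expect_false(direction_consistent(
    mk("duplication", -1, -0.2, c(0.1, -0.05, 0), c(0.01, 0, -0.01))))
  # z consistent but fold change not -> overall inconsistent
  expect_false(direction_consistent(
    mk("duplication", 2, 0.01, c(0.1, -0.05, 0), c(0.2, 0, -0.01))))
})

test_that("truncating-gene expression check uses the strict cohort-mean rule", {
  m <- make_expr(rbind(c(3095.66, 4000, 4749.69)), genes = "PTENlike")
  r <- snv_expression_check(m, "PTENlike", "s1")
  expect_true(r$expressed_in_blood)
  expect_equal(r$patient_level, 3095.66)
  expect_equal(r$cohort_mean_level, mean(c(3095.66, 4000, 4749.69)))
  expect_true(r$reduced)
  # patient exactly at the mean -> not reduced (strict inequality)
  m2 <- make_expr(rbind(c(10, 10, 10)), genes = "g")
  expect_false(snv_expression_check(m2, "g", "s1")$reduced)
  # blood-silent gene -> no levels
  m3 <- make_expr(rbind(c(0, 0, 0)), genes = "g")
  r3 <- snv_expression_check(m3, "g", "s1")
  expect_false(r3$expressed_in_blood)
  expect_true(is.na(r3$patient_level))
  # excluding the index patient is available as a flag
  r4 <- snv_expression_check(m, "PTENlike", "s1", include_patient = FALSE)
  expect_equal(r4$cohort_mean_level, mean(c(4000, 4749.69)))
})

test_that("dosage result tables mirror the per-CNV column layout", {
  genes <- gene_models(paste0("g", 1:5), "chr1",
                       c(100L, 1000L, 2000L, 3000L, 4000L),
                       c(500L, 1500L, 2500L, 3500L, 4500L))
  set.seed(5)
  m <- make_expr(matrix(rlnorm(30, 4, 0.3), nrow = 5),
                 genes = genes$gene_id)
  r <- cnv_dosage_validation(m, cnv_calls("s1", "chr1", 50L, 1600L,
                                          "duplication"), genes, seed = 2)
  tab <- dosage_result_table(list(r))
  expect_equal(tab$zscore_random2, r$zscore_random[2])
  expect_equal(tab$log2fc_random3, r$log2fc_random[3])
  expect_equal(tab$status, "evaluable")
})
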