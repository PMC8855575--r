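test_that("ld_prune removes one of each correlated pair and never both", {
  set.seed(10)
  h <- matrix(rbinom(60 * 30, 1, 0.5), nrow = 60)
  h2 <- matrix(rbinom(60 * 30, 1, 0.5), nrow = 60)
  co <- toy_cohort(h, h2, groups = rep("g", 60))
  # duplicate a column: r2 = 1
  co$dosage[, 5] <- co$dosage[, 4]
  kept <- ld_prune(co, window_snps = 30, step_snps = 30, r2_threshold = 0.2)
  expect_true("snp4" %in% kept)
  expect_false("snp5" %in% kept)
  # no retained within-block pair with r2 >= threshold
  idx <- match(kept[kept %in% paste0("snp", 1:30)], colnames(co$dosage))
  r2 <- cor(co$dosage[, idx])^2
  expect_true(all(r2[upper.tri(r2)] < 0.2))
  # low-correlation pairs survive
  co2 <- toy_cohort(h[, 1:2], h2[, 1:2], groups = rep("g", 60))
  r2_12 <- cor(co2$dosage)[1, 2]^2
  kept2 <- ld_prune(co2, r2_threshold = max(r2_12 + 0.01, 0.2))
  expect_equal(length(kept2), 2L)
})

test_that("bonferroni threshold reproduces the printed cutoff", {
  expect_equal(signif(bonferroni_threshold(165202), 3), 6.05e-6)
  expect_equal(bonferroni_threshold(1), 1)
  expect_equal(bonferroni_threshold(100), 0.01)
  expect_error(bonferroni_threshold(0), "count")
})

test_that("kinship is PSD, standardized, and doubles for duplicated samples", {
  co <- sim_two_pop_cohort(f = 0.1, n_per_pop = 40, n_snps = 3000, seed = 19)
  K <- kinship(co)
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # HWE outbred samples: mean diagonal ~ 1
  teo <- which(co$samples$group %in% c("parviglumis", "mexicana"))
  expect_lt(abs(mean(diag(K)[teo]) - 1), 0.05)
  # duplicated sample: off-diagonal equals the diagonal
  co$hap1[2, ] <- co$hap1[1, ]; co$hap2[2, ] <- co$hap2[1, ]
  co$dosage <- co$hap1 + co$hap2
  K2 <- kinship(co)
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-8)
})

test_that("with identity kinship and no PCs the MLM equals the OLS oracle", {
  set.seed(20)
  n <- 80
  h1 <- matrix(rbinom(n * 40, 1, 0.4), nrow = n)
  h2 <- matrix(rbinom(n * 40, 1, 0.4), nrow = n)
  co <- toy_cohort(h1, h2, groups = rep("g", n))
  y <- rnorm(n) + 0.5 * co$dosage[, 7]
  ph <- tibble::tibble(sample = co$samples$sample, value = y)
  K <- diag(n); dimnames(K) <- list(co$samples$sample, co$samples$sample)
  scan <- mlm_scan(co, ph, K = K, n_pcs = 0, min_maf = 0)
  res <- tidy(scan)
  for (j in c(1, 7, 20)) {
    p_ols <- ols_pval(y, co$dosage[, j])
    expect_equal(res$p_value[res$snp_id == paste0("snp", j)], p_ols,
                 tolerance = 1e-6)
  }
  # effect direction and magnitude match lm
  fit <- lm(y ~ co$dosage[, 7])
  expect_equal(res$effect[res$snp_id == "snp7"],
               unname(coef(fit)[2]), tolerance = 1e-6)
})

test_that("a large planted effect is the top association under the full MLM", {
  co <- simulate_cohort(n_snps = 1500, n_chrom = 3, chrom_length_bp = 5e6,
                        missing_rate = 0.02, seed = 23)
  snp <- co$variants$snp_id[700]
  ph <- simulate_phenotype(co, causal_snps = snp, effects = 1.5,
                           h2_polygenic = 0.3, noise_sd = 1, seed = 2)
  scan <- mlm_scan(co, ph)
  res <- tidy(scan)
  expect_equal(res$snp_id[which.min(res$p_value)], snp)
  expect_true(all(res$maf >= 0.05))
  g <- glance(scan)
  expect_equal(g$n_samples, n_samples(co))
  expect_gt(g$h2, 0)
})

test_that("null phenotypes give calibrated type-I error", {
  co <- sim_two_pop_cohort(f = 0.1, n_per_pop = 50, n_snps = 5000, seed = 29,
                           missing_rate = 0)
  set.seed(30)
  ph <- tibble::tibble(
    sample = co$samples$sample, value = rnorm(n_samples(co))
  )
  scan <- mlm_scan(co, ph, min_maf = 0.05)
  frac <- mean(tidy(scan)$p_value <= 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("locus resolution merges nearby significant SNPs and picks lead SNPs", {
  res <- tibble::tibble(
    snp_id = paste0("s", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr3"),
    pos = c(1e6, 1.5e6, 9e6, 1e6, 1.2e6, 5e6),
    maf = 0.2, effect = 1, se = 0.1, statistic = 5,
    p_value = c(1e-8, 1e-10, 1e-7, 1e-9, 0.5, 1e-7)
  )
  loci <- resolve_loci(res, cutoff = 1e-6)
  expect_equal(nrow(loci), 4L) # chr1: 2 loci; chr2: 1; chr3: 1
  l1 <- loci[loci$chrom == "chr1" & loci$start == 1e6, ]
  expect_equal(l1$lead_snp, "s2")
  expect_equal(l1$n_snps, 2L)
  # number of loci <= number of significant SNPs
  expect_lte(nrow(loci), sum(res$p_value <= 1e-6))
  # no significant SNPs -> empty tibble, not an error
  expect_equal(nrow(resolve_loci(res, cutoff = 1e-20)), 0L)
  # SNPs on different chromosomes never merge
  expect_equal(sum(loci$chrom == "chr2"), 1L)
})

test_that("group frequency contrasts recover planted frequency shifts", {
  specs <- dplyr::bind_rows(
    population_spec("parviglumis", 5, "outbred_HWE", 0.05),
    population_spec("mexicana", 5, "outbred_HWE", 0.05),
    population_spec("tropical", 100, "fully_inbred", 0.1),
    population_spec("temperate", 100, "fully_inbred", 0.1)
  )
  co <- simulate_cohort(specs, n_snps = 300, n_chrom = 1,
                        chrom_length_bp = 1e6, missing_rate = 0, seed = 33)
  # overwrite one SNP with known group frequencies 0.7 / 0.95
  snp <- co$variants$snp_id[5]
  set.seed(34)
  for (gr in c("tropical", "temperate")) {
    rows <- which(co$samples$group == gr)
    p <- if (gr == "tropical") 0.7 else 0.95
    hap <- rbinom(length(rows), 1, p)
    co$hap1[rows, 5] <- hap; co$hap2[rows, 5] <- hap
  }
  co$dosage <- co$hap1 + co$hap2
  got <- group_freq_contrast(co, snp, allele = "alt",
                             groups = c("tropical", "temperate"))
  expect_lt(abs(got$freq[got$group == "tropical"] - 0.7), 0.05 + 0.09)
  expect_lt(abs(got$freq[got$group == "temperate"] - 0.95), 0.05)
  # ref allele is the complement
  ref <- group_freq_contrast(co, snp, allele = "ref",
                             groups = c("tropical", "temperate"))
  expect_equal(ref$freq + got$freq, c(1, 1))
  expect_error(group_freq_contrast(co, snp, allele = "T"), "not present")
  expect_error(group_freq_contrast(co, "nope"), "not found")
})
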