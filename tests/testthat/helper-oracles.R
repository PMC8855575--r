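# Independent oracles and tiny fixture builders used across the suite.

# Weir & Cockerham (1984) two-population estimator, transcribed directly
# from the published equations (r = 2), scalar arithmetic only. Kept
# deliberately separate from the package's vectorized implementation.
wc_oracle <- function(d1, d2) {
  d1 <- d1[!is.na(d1)]
  d2 <- d2[!is.na(d2)]
  r <- 2
  n_i <- c(length(d1), length(d2))
  p_i <- c(sum(d1) / (2 * n_i[1]), sum(d2) / (2 * n_i[2]))
  h_i <- c(mean(d1 == 1), mean(d2 == 1))
  n_bar <- mean(n_i)
  C2 <- sum((n_i - n_bar)^2) / ((r - 1) * n_bar^2)  # squared CV of sizes
  n_c <- n_bar * (1 - C2 / r)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# OLS oracle: p-value of the slope in y ~ x (+ optional covariates)
ols_pval <- function(y, x, covars = NULL) {
  df <- data.frame(y = y, x = x)
  form <- y ~ x
  if (!is.null(covars)) {
    df <- cbind(df, covars)
    form <- stats::as.formula(paste("y ~ x +", paste(colnames(covars), collapse = "+")))
  }
  fit <- stats::lm(form, data = df)
  summary(fit)$coefficients["x", 4]
}

# Build a zea_cohort directly from explicit haplotype matrices.
toy_cohort <- function(h1, h2, groups, chrom = "chr1",
                       pos = NULL, phased = TRUE) {
  m <- ncol(h1)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  variants <- tibble::tibble(
    snp_id = paste0("snp", seq_len(m)),
    chrom = chrom, pos = pos, ref = "A", alt = "C"
  )
  samples <- tibble::tibble(
    sample = paste0("s", seq_along(groups)), group = groups
  )
  new_cohort(h1, h2, variants, samples, phased = phased)
}

# Minimal hap_catalog for functions that only consume counts + samples.
make_catalog <- function(counts, samples) {
  structure(
    list(
      loci = tibble::tibble(locus_id = unique(counts$locus_id)),
      samples = samples, codes = NULL, alleles = NULL,
      counts = tibble::as_tibble(counts)
    ),
    class = "hap_catalog"
  )
}

# Two-population Balding-Nichols cohort via the package generator: the two
# teosinte groups carry the F of interest, the maize groups are minimal.
sim_two_pop_cohort <- function(f, n_per_pop, n_snps, seed,
                               missing_rate = 0) {
  specs <- dplyr::bind_rows(
    population_spec("parviglumis", n_per_pop, "outbred_HWE", f),
    population_spec("mexicana", n_per_pop, "outbred_HWE", f),
    population_spec("tropical", 2, "fully_inbred", 0.05),
    population_spec("temperate", 2, "fully_inbred", 0.05)
  )
  simulate_cohort(
    pop_specs = specs, n_chrom = 5, chrom_length_bp = 2e6,
    n_snps = n_snps, missing_rate = missing_rate, seed = seed
  )
}

write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t100\trs1\tA\tC\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0",
    "chr1\t200\trs2\tG\tT\t.\tPASS\t.\tGT\t.|.\t0|1\t1|0",
    "chr1\t300\trs3\tA\tC,G\t.\tPASS\t.\tGT\t0|1\t0|2\t0|0",
    "chr1\t400\trs4\tAT\tA\t.\tPASS\t.\tGT\t0|0\t0|1\t1|1",
    "chr1\t500\t.\tC\tG\t.\tPASS\t.\tGT\t1|1\t0|0\t0|1"
  ), path)
}
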