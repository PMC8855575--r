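test_that("per-SNP Weir-Cockerham components match the transcribed oracle", {
  # pop1: 12/20 alt alleles in 10 diploids (6 het), pop2: 4/20 (4 het)
  d1 <- c(rep(2, 3), rep(1, 6), 0)
  d2 <- c(rep(1, 4), rep(0, 6))
  got <- wc_fst_snp(d1, d2)
  ora <- wc_oracle(d1, d2)
  expect_equal(got$a, ora$a, tolerance = 1e-10)
  expect_equal(got$b, ora$b, tolerance = 1e-10)
  expect_equal(got$c, ora$c, tolerance = 1e-10)
  expect_equal(got$theta, ora$theta, tolerance = 1e-10)

  # randomized cases, including unequal and odd sample sizes with missing data
  set.seed(99)
  for (i in 1:25) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    d1 <- sample(0:2, n1, replace = TRUE)
    d2 <- sample(0:2, n2, replace = TRUE)
    d1[sample(n1, 1)] <- NA
    got <- wc_fst_snp(d1, d2)
    ora <- wc_oracle(d1, d2)
    expect_equal(got$a + got$b + got$c, ora$a + ora$b + ora$c,
                 tolerance = 1e-10)
    expect_equal(got$theta, ora$theta, tolerance = 1e-10)
  }
})

test_that("theta hits the boundary cases: fixed difference ~1, no differentiation ~0", {
  n <- 500
  fixed <- wc_fst_snp(rep(2, n), rep(0, n))
  expect_gt(fixed$theta, 0.99)
  same <- wc_fst_snp(
    c(rep(2, 125), rep(1, 250), rep(0, 125)), # HWE at p = 0.5
    c(rep(2, 125), rep(1, 250), rep(0, 125))
  )
  expect_lt(abs(same$theta), 0.05)
})

test_that("windowed FST is the weighted ratio of sums, not a mean of ratios", {
  comp <- tibble::tibble(
    snp_id = c("x", "y"), chrom = "chr1", pos = c(1000, 2000),
    a = c(0.1, 0), b = c(0.05, 0.4), c = c(0.05, 0.4),
    theta = c(0.5, 0)
  )
  tr <- windowed_fst(comp, window_bp = 1e5, step_bp = 1e5, min_snps = 2)
  expect_equal(tr$score, 0.1 / 1.0) # vs mean of ratios 0.25
  # all-zero-theta window scores 0
  comp0 <- dplyr::mutate(comp, a = 0)
  expect_equal(
    windowed_fst(comp0, window_bp = 1e5, step_bp = 1e5, min_snps = 2)$score, 0
  )
  # min_snps drops sparse windows
  expect_equal(nrow(windowed_fst(comp, min_snps = 5)), 0)
})

test_that("windowed FST equals oracle sums over member SNPs on simulated data", {
  co <- sim_two_pop_cohort(f = 0.1, n_per_pop = 20, n_snps = 800, seed = 12,
                           missing_rate = 0.05)
  comp <- wc_fst_components(co, "parviglumis", "mexicana")
  track <- windowed_fst(comp, window_bp = 5e5, step_bp = 5e5, min_snps = 5)
  i1 <- which(co$samples$group == "parviglumis")
  i2 <- which(co$samples$group == "mexicana")
  w <- track[3, ]
  members <- which(co$variants$chrom == w$chrom &
                     co$variants$pos - 1 >= w$start &
                     co$variants$pos - 1 < w$end)
  parts <- lapply(members, function(j) {
    wc_oracle(co$dosage[i1, j], co$dosage[i2, j])
  })
  num <- sum(vapply(parts, `[[`, numeric(1), "a"))
  den <- sum(vapply(parts, function(p) p$a + p$b + p$c, numeric(1)))
  expect_equal(w$score, num / den, tolerance = 1e-10)
  expect_equal(w$n_snps, length(members))
})

test_that("pairwise global FST is symmetric with near-zero diagonal blocks", {
  co <- sim_two_pop_cohort(f = 0.15, n_per_pop = 30, n_snps = 2000, seed = 14)
  # duplicated group: relabel half of parviglumis
  co$samples$group[1:15] <- "parv_copy"
  fst <- pairwise_global_fst(co, c("parv_copy", "parviglumis", "mexicana"))
  expect_equal(fst, t(fst))
  expect_equal(unname(diag(fst)), rep(0, 3))
  expect_lt(abs(fst["parv_copy", "parviglumis"]), 0.01)
  expect_gt(fst["parviglumis", "mexicana"], 0.1)
  expect_error(pairwise_global_fst(co, c("parviglumis", "nope")),
               "unknown group")
})

test_that("omega recovers the drift scale and is invariant to allele flips", {
  p <- runif(2000, 0.1, 0.9)
  expect_equal(estimate_omega(p, p), 0)
  set.seed(2)
  f <- 0.1
  q <- rbeta(2000, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  om <- estimate_omega(p, q)
  expect_lt(abs(om - f), 0.02)
  expect_equal(estimate_omega(1 - p, 1 - q), om)
  expect_error(estimate_omega(p[1:50], q[1:50]), "too few")
})

test_that("the composite likelihood is zero when the sweep model reduces to the null", {
  p_ref <- c(0.3, 0.5, 0.7)
  p_test <- c(0.4, 0.5, 0.6)
  pos <- c(10000, 50000, 90000)
  # s grid ~ 0: escape probability c -> 1 at any distance, alt == null
  clr <- xpclr_window(p_ref, p_test, pos, center = 50000, omega = 0.1,
                      s_grid = 1e-9)
  expect_equal(clr, 0, tolerance = 1e-6)
  expect_gte(
    xpclr_window(p_ref, p_test, pos, center = 50000, omega = 0.1), 0
  )
  expect_error(
    xpclr_window(p_ref, p_test, pos, 50000, omega = -1), "omega"
  )
  expect_error(
    xpclr_window(c(0, 0.5, 1), p_test, pos, 50000, omega = 0.1),
    "degenerate"
  )
})

test_that("swept regions score highest along the chromosome and CLR grows with sweep strength", {
  hits <- 0L
  n_rep <- 5
  clr_by_s <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(n_snps = 3000, n_chrom = 1, chrom_length_bp = 1.5e7,
                          missing_rate = 0, seed = 100 + r)
    co <- plant_sweep(co, "tropical", "chr1", center = 7.5e6,
                      half_width = 2.5e5, s_tilde = 0.05, seed = 100 + r)
    xp <- xpclr_scan(co, "parviglumis", "tropical", seed = 1)
    top <- xp[which.max(xp$score), ]
    mid <- (top$start + top$end) / 2
    if (abs(mid - 7.5e6) <= 5e5) hits <- hits + 1L
    # CLR vs planted strength (weak / medium / strong), same seed base
    for (k in seq_along(c(0.005, 0.02, 0.05))) {
      s <- c(0.005, 0.02, 0.05)[k]
      cs <- simulate_cohort(n_snps = 1500, n_chrom = 1, chrom_length_bp = 5e6,
                            missing_rate = 0, seed = 200 + r)
      cs <- plant_sweep(cs, "tropical", "chr1", center = 2.5e6,
                        half_width = 2.5e5, s_tilde = s, seed = 300 + r)
      xs <- xpclr_scan(cs, "parviglumis", "tropical", seed = 1)
      near <- xs$start >= 2.2e6 & xs$end <= 2.8e6
      clr_by_s[r, k] <- max(xs$score[near])
    }
  }
  expect_gte(hits, 4L)
  # monotone in expectation across strengths (rank of replicate means)
  m <- colMeans(clr_by_s)
  expect_true(m[1] < m[2] && m[2] < m[3])
  expect_true(all(is.finite(clr_by_s)))
})

test_that("LD down-weighting halves the weight of duplicated SNPs", {
  set.seed(5)
  ref <- matrix(rbinom(200, 2, 0.5), ncol = 4)
  ref[, 2] <- ref[, 1] # perfect LD pair
  w <- zeascan:::ld_cluster_weights(ref, cap = 0.95)
  expect_equal(w[1:2], c(0.5, 0.5))
  expect_equal(w[3:4], c(1, 1))
})
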