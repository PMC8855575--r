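test_that("build_loci tiles 50-kb windows and subsamples SNP-rich windows reproducibly", {
  pos <- c(1000, 2000, 3000, # window [0, 50k): 3 SNPs
           sort(sample(50001:100000, 12)), # window [50k, 100k): 12 SNPs
           200001) # window [200k, 250k): 1 SNP
  variants <- tibble::tibble(
    snp_id = paste0("s", seq_along(pos)), chrom = "chr1", pos = pos
  )
  loci <- build_loci(variants, seed = 4)
  expect_equal(nrow(loci), 3) # empty windows dropped
  expect_equal(loci$n_snps, c(3L, 5L, 1L))
  expect_equal(loci$start, c(0, 50000, 200000))
  expect_equal(loci$end - loci$start, rep(50000, 3))
  # subset ascending in position and reproducible under the same seed
  sub <- loci$snp_id[[2]]
  expect_equal(sub, sub[order(match(sub, variants$snp_id))])
  loci2 <- build_loci(variants, seed = 4)
  expect_identical(loci$snp_id, loci2$snp_id)
  expect_false(identical(loci$snp_id, build_loci(variants, seed = 5)$snp_id))
})

test_that("call_haplotypes forms alleles from phase, drops missing, counts by group", {
  # 3 samples, 2 SNPs in one locus; haplotypes (0,1) (1,0) (0,0) (0,0) ...
  h1 <- rbind(c(0L, 1L), c(0L, 0L), c(1L, NA))
  h2 <- rbind(c(1L, 0L), c(0L, 0L), c(0L, 0L))
  co <- toy_cohort(h1, h2, groups = c("a", "a", "b"), pos = c(100L, 200L))
  loci <- build_loci(co$variants)
  cat <- call_haplotypes(co, loci)
  expect_equal(attr(cat, "n_dropped"), 1L) # s3 hap1 has a missing allele
  cnt <- cat$counts
  expect_setequal(cnt$allele, c("01", "10", "00"))
  expect_equal(sum(cnt$count), 5L)
  expect_equal(sum(cnt$count[cnt$group == "b"]), 1L)
  # unphased cohort refused
  co_u <- toy_cohort(h1, h2, groups = c("a", "a", "b"), phased = FALSE)
  expect_error(call_haplotypes(co_u, loci), "not phased")
  # inbred sample: two identical haplotypes
  co_i <- toy_cohort(h1, h1, groups = rep("a", 3), pos = c(100L, 200L))
  cat_i <- call_haplotypes(co_i, build_loci(co_i$variants))
  expect_true(all(cat_i$codes[, 1:3] == cat_i$codes[, 4:6], na.rm = TRUE))
})

test_that("rarefied richness matches the closed form and its identities", {
  samples <- tibble::tibble(sample = c("s1", "s2"), group = "a")
  cnt <- tibble::tibble(
    locus_id = "L1", allele = c("0", "1"), group = "a", count = c(3L, 1L)
  )
  cat <- make_catalog(cnt, samples)
  expect_equal(richness(cat, 2)$richness, 1.5) # 2 - C(1,2)/C(4,2) - C(3,2)/C(4,2)
  expect_equal(richness(cat, 4)$richness, 2)   # g = N -> observed count
  expect_equal(richness(cat, 1)$richness, 1)
  # all identical haplotypes -> 1 for any g
  cat1 <- make_catalog(
    tibble::tibble(locus_id = "L1", allele = "0", group = "a", count = 4L),
    samples
  )
  expect_equal(richness(cat1, 3)$richness, 1)
  expect_error(richness(cat, 5), "exceeds")
  # monotone non-decreasing in g
  r <- vapply(1:4, function(g) richness(cat, g)$richness, numeric(1))
  expect_true(all(diff(r) >= 0))
})

test_that("group-specific haplotypes follow the exclusive-presence rule", {
  samples <- tibble::tibble(
    sample = paste0("s", 1:4), group = c("a", "a", "b", "b")
  )
  cnt <- tibble::tibble(
    locus_id = "L1",
    allele = c("00", "00", "01", "11"),
    group = c("a", "b", "a", "b"),
    count = c(2L, 1L, 2L, 1L)
  )
  got <- group_specific(make_catalog(cnt, samples), c("a", "b"))
  expect_equal(got$n_specific[got$group == "a"], 1L) # "01"
  expect_equal(got$n_specific[got$group == "b"], 1L) # "11"
  expect_equal(got$n_specific_per_line, c(0.5, 0.5))
  # sum of specific alleles <= total distinct alleles
  expect_lte(sum(got$n_specific), dplyr::n_distinct(cnt$allele))
})

test_that("shared-ancestry categories partition maize haplotypes", {
  samples <- tibble::tibble(
    sample = paste0("s", 1:4),
    group = c("tropical", "temperate", "mexicana", "parviglumis")
  )
  cnt <- tibble::tibble(
    locus_id = "L1",
    allele = c("A", "A", "A", "B", "B", "C", "C", "D", "E"),
    group = c("tropical", "mexicana", "parviglumis",
              "temperate", "mexicana",
              "tropical", "parviglumis",
              "tropical",
              "parviglumis"),
    count = 1L
  )
  got <- shared_categories(make_catalog(cnt, samples), "all")
  expect_equal(got$n[got$category == "MPM"], 1L) # A
  expect_equal(got$n[got$category == "MM"], 1L)  # B
  expect_equal(got$n[got$category == "PM"], 1L)  # C
  expect_equal(got$n[got$category == "M"], 1L)   # D; E is not in maize
  expect_equal(sum(got$pct), 100, tolerance = 1e-9)
  # subset selection changes the maize universe
  trop <- shared_categories(make_catalog(cnt, samples), "tropical")
  expect_equal(sum(trop$n), 3L) # A, C, D only
  expect_error(
    shared_categories(make_catalog(cnt[cnt$group != "mexicana", ], samples)),
    "lacks required"
  )
})

test_that("per-allele counts sum across groups to the allele total", {
  co <- simulate_cohort(n_snps = 600, n_chrom = 2, chrom_length_bp = 2e6,
                        missing_rate = 0.05, seed = 31)
  cat <- call_haplotypes(co, build_loci(co$variants, seed = 1))
  totals <- cat$counts |>
    dplyr::group_by(locus_id, allele) |>
    dplyr::summarise(total = sum(count), .groups = "drop")
  # recount from raw codes for a sample of loci
  for (i in c(1, 5, 10)) {
    cd <- cat$codes[i, ]
    tab <- table(cat$alleles[[i]][cd[!is.na(cd)]])
    sub <- totals[totals$locus_id == cat$loci$locus_id[i], ]
    expect_equal(
      sub$total[match(names(tab), sub$allele)], as.integer(unname(tab))
    )
  }
})

test_that("bootstrap equalization is seeded, stable in group order, and degenerate for exact-size groups", {
  co <- simulate_cohort(
    pop_specs = dplyr::bind_rows(
      population_spec("parviglumis", 20, "outbred_HWE", 0.08),
      population_spec("mexicana", 30, "outbred_HWE", 0.12),
      population_spec("tropical", 30, "fully_inbred", 0.18),
      population_spec("temperate", 25, "fully_inbred", 0.12)
    ),
    n_snps = 400, n_chrom = 1, chrom_length_bp = 2e6,
    missing_rate = 0, seed = 17
  )
  cat <- call_haplotypes(co, build_loci(co$variants, seed = 1))
  bs <- bootstrap_equalize(cat, n = 20, reps = 10, seed = 3)
  expect_equal(nrow(bs), 40)
  expect_equal(unique(bs$group), unique(co$samples$group))
  bs2 <- bootstrap_equalize(cat, n = 20, reps = 10, seed = 3)
  expect_identical(bs, bs2)
  expect_equal(unique(bs$group), unique(bs2$group))
  # parviglumis has exactly n samples: all reps identical
  par_means <- bs$mean_haplotypes[bs$group == "parviglumis"]
  expect_equal(length(unique(par_means)), 1L)
  # smaller group than n: used whole, with a message
  expect_message(
    bootstrap_equalize(cat, n = 25, reps = 2, seed = 1),
    "used whole"
  )
})
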