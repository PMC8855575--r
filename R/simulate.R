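#' Population specifications for the cohort simulator
#'
#' Describes one population: its label, sample size, mating model and the
#' Balding-Nichols drift parameter F of the tree edge leading to it. The
#' simulator's population tree is fixed to the inferred *Zea* lineage:
#' parviglumis and mexicana split from a common teosinte ancestor, maize
#' descends from the parviglumis branch, and temperate maize derives from
#' tropical maize. Teosinte populations are outbred (Hardy-Weinberg
#' genotypes); maize populations are fully inbred lines (one haplotype drawn
#' and duplicated, heterozygosity exactly zero before missingness masking).
#'
#' @param name population label.
#' @param n_samples number of individuals (>= 2).
#' @param ploidy_model `"outbred_HWE"` or `"fully_inbred"`.
#' @param drift_F Balding-Nichols F in (0, 1) for the edge leading to this
#'   population.
#' @return tibble with one row per population.
#' @export
#' @examples
#' default_populations()
population_spec <- function(name, n_samples, ploidy_model, drift_F) {
  ploidy_model <- match.arg(ploidy_model, c("outbred_HWE", "fully_inbred"))
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (!(drift_F > 0 && drift_F < 1)) stop("drift_F must lie in (0, 1)")
  tibble::tibble(
    name = name, n_samples = as.integer(n_samples),
    ploidy_model = ploidy_model, drift_F = drift_F
  )
}

#' @rdname population_spec
#' @details `default_populations()` returns the four-population study design
#'   used throughout: 75 parviglumis and 96 mexicana outbred accessions
#'   (matching the study's teosinte subgroup sizes) and 150 tropical and 100
#'   temperate fully inbred maize lines (desk-scale stand-ins for the 669 and
#'   157 of the real panel). Edge Fs (0.08, 0.12, 0.18, 0.12) are chosen so
#'   pairwise differentiation lands in the reported 0.10-0.21 band and
#'   expected heterozygosity declines parviglumis > mexicana > tropical >
#'   temperate.
#' @export
default_populations <- function() {
  dplyr::bind_rows(
    population_spec("parviglumis", 75, "outbred_HWE", 0.08),
    population_spec("mexicana", 96, "outbred_HWE", 0.12),
    population_spec("tropical", 150, "fully_inbred", 0.18),
    population_spec("temperate", 100, "fully_inbred", 0.12)
  )
}

bn_drift <- function(p, f) {
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a structured four-population cohort
#'
#' Draws ancestral allele frequencies from a Beta(0.8, 0.8) truncated to
#' \[0.05, 0.95\], applies Balding-Nichols drift
#' `p_child ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` along each edge of the fixed
#' population tree (parviglumis and mexicana from the ancestor; tropical
#' maize from the realized parviglumis frequencies; temperate from tropical),
#' then samples phased haplotypes: outbred populations draw two haplotypes
#' independently per SNP, fully inbred populations draw one and duplicate it.
#' SNPs are placed uniformly at random along each chromosome (independent
#' sites; linkage disequilibrium arises only through structure and planted
#' sweeps). Genotypes are masked missing uniformly at random at
#' `missing_rate` (both haplotypes of a masked call).
#'
#' @param pop_specs tibble from [population_spec()]; defaults to
#'   [default_populations()].
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param n_snps total number of biallelic SNPs (>= 1), split evenly across
#'   chromosomes.
#' @param missing_rate fraction of genotype calls masked missing, in
#'   \[0, 0.2\].
#' @param seed integer seed; all randomness is derived from it.
#' @param beta_shape shape of the symmetric Beta ancestral-frequency
#'   distribution.
#' @param freq_bounds truncation bounds for ancestral frequencies.
#' @return a [new_cohort()] object. Population allele frequencies used by
#'   the generator are kept in `attr(, "truth")` for downstream checks.
#' @export
#' @examples
#' cohort <- simulate_cohort(n_snps = 200, n_chrom = 2, seed = 1)
#' cohort
simulate_cohort <- function(pop_specs = default_populations(),
                            n_chrom = 10,
                            chrom_length_bp = 2e7,
                            n_snps = 4e4,
                            missing_rate = 0.05,
                            seed = 1,
                            beta_shape = 0.8,
                            freq_bounds = c(0.05, 0.95)) {
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (missing_rate < 0 || missing_rate > 0.2) {
    stop("missing_rate must lie in [0, 0.2]")
  }
  required <- c("parviglumis", "mexicana", "tropical", "temperate")
  if (!setequal(pop_specs$name, required)) {
    stop(
      "pop_specs must describe exactly the populations: ",
      paste(required, collapse = ", ")
    )
  }
  if (any(pop_specs$n_samples < 2) ||
      any(pop_specs$drift_F <= 0) || any(pop_specs$drift_F >= 1)) {
    stop("invalid population specification (n_samples >= 2, 0 < drift_F < 1)")
  }
  specs <- split(pop_specs, pop_specs$name)

  set.seed(seed)
  ## ancestral frequencies: truncated Beta via inverse-CDF
  lo <- stats::pbeta(freq_bounds[1], beta_shape, beta_shape)
  hi <- stats::pbeta(freq_bounds[2], beta_shape, beta_shape)
  p_anc <- stats::qbeta(runif(n_snps, lo, hi), beta_shape, beta_shape)

  freqs <- list()
  freqs$parviglumis <- bn_drift(p_anc, specs$parviglumis$drift_F)
  freqs$mexicana <- bn_drift(p_anc, specs$mexicana$drift_F)
  freqs$tropical <- bn_drift(freqs$parviglumis, specs$tropical$drift_F)
  freqs$temperate <- bn_drift(freqs$tropical, specs$temperate$drift_F)

  ## variant coordinates: uniform positions, sorted, deduplicated per chrom
  chrom_of <- sort(rep_len(seq_len(n_chrom), n_snps))
  pos <- unlist(lapply(split(chrom_of, chrom_of), function(idx) {
    n <- length(idx)
    p <- sort(sample.int(chrom_length_bp, n))
    p
  }), use.names = FALSE)
  variants <- tibble::tibble(
    snp_id = sprintf("S%d_%d", chrom_of, pos),
    chrom = paste0("chr", chrom_of),
    pos = pos,
    ref = "A", alt = "C"
  )

  ## haplotype draws, in the fixed population order of pop_specs rows
  order_pops <- c("parviglumis", "mexicana", "tropical", "temperate")
  hap_blocks <- lapply(order_pops, function(pop) {
    n <- specs[[pop]]$n_samples
    p <- freqs[[pop]]
    draw_haplotypes(n, p, specs[[pop]]$ploidy_model)
  })
  hap1 <- do.call(rbind, lapply(hap_blocks, `[[`, 1))
  hap2 <- do.call(rbind, lapply(hap_blocks, `[[`, 2))

  samples <- tibble::tibble(
    sample = sprintf(
      "%s_%03d",
      rep(order_pops, vapply(order_pops, function(p) specs[[p]]$n_samples, 1L)),
      unlist(lapply(order_pops, function(p) seq_len(specs[[p]]$n_samples)))
    ),
    group = rep(
      order_pops,
      vapply(order_pops, function(p) specs[[p]]$n_samples, 1L)
    )
  )

  if (missing_rate > 0) {
    mask <- matrix(
      runif(length(hap1)) < missing_rate,
      nrow = nrow(hap1)
    )
    hap1[mask] <- NA_integer_
    hap2[mask] <- NA_integer_
  }

  cohort <- new_cohort(hap1, hap2, variants, samples, phased = TRUE)
  attr(cohort, "truth") <- list(
    freqs = freqs, pop_specs = pop_specs, seed = seed,
    n_chrom = n_chrom, chrom_length_bp = chrom_length_bp
  )
  cohort
}

draw_haplotypes <- function(n, p, ploidy_model) {
  m <- length(p)
  if (ploidy_model == "outbred_HWE") {
    h1 <- matrix(rbinom(n * m, 1L, rep(p, each = n)), nrow = n)
    h2 <- matrix(rbinom(n * m, 1L, rep(p, each = n)), nrow = n)
  } else {
    h1 <- matrix(rbinom(n * m, 1L, rep(p, each = n)), nrow = n)
    h2 <- h1
  }
  list(h1, h2)
}

#' Plant a selective sweep into a simulated cohort
#'
#' Applies the same star-like hitchhiking model used by the composite
#' likelihood scan: a SNP at distance d from the sweep center escapes the
#' sweep with probability `c = 1 - exp(-r d / s_tilde)` (r = per-bp
#' recombination rate, `s_tilde` the unitless sweep-strength parameter). The
#' target population's allele frequency is moved to `c p + (1 - c) B`, where
#' B is a single per-sweep draw of the hitchhiking background allele (B = 1
#' with probability equal to the pre-sweep frequency at the SNP nearest the
#' center), and target-population haplotypes are re-drawn from the new
#' frequencies. Only SNPs within `center +/- half_width` are transformed.
#' The missingness pattern of the affected entries is preserved.
#'
#' @param cohort a [simulate_cohort()] cohort.
#' @param target_population group label whose frequencies are swept.
#' @param chrom chromosome id (e.g. `"chr3"`).
#' @param center,half_width sweep center and half-width in bp; the interval
#'   must lie inside the simulated chromosome.
#' @param s_tilde selection-strength parameter (> 0); larger values drag more
#'   flanking SNPs to the background allele.
#' @param recomb_rate_per_bp recombination rate per bp (default 1e-8,
#'   i.e. 1 cM/Mb).
#' @param seed integer seed.
#' @return the modified cohort; planted sweep intervals accumulate in
#'   `attr(, "truth")$sweeps`.
#' @export
plant_sweep <- function(cohort, target_population, chrom, center, half_width,
                        s_tilde, recomb_rate_per_bp = 1e-8, seed = 1) {
  stopifnot(is_cohort(cohort))
  if (s_tilde <= 0) stop("s_tilde must be > 0")
  truth <- attr(cohort, "truth")
  if (!chrom %in% cohort$variants$chrom) {
    stop("sweep chromosome not in cohort: ", chrom)
  }
  len <- if (!is.null(truth)) truth$chrom_length_bp else
    max(cohort$variants$pos[cohort$variants$chrom == chrom])
  if (center - half_width < 0 || center + half_width > len) {
    stop("sweep interval outside simulated coordinates")
  }
  rows <- group_idx(cohort, target_population)
  inbred <- all(
    cohort$hap1[rows, ] == cohort$hap2[rows, ],
    na.rm = TRUE
  )

  snp_sel <- which(
    cohort$variants$chrom == chrom &
      abs(cohort$variants$pos - center) <= half_width
  )
  if (length(snp_sel) == 0) return(cohort)
  d <- abs(cohort$variants$pos[snp_sel] - center)

  set.seed(seed)
  h1 <- cohort$hap1[rows, snp_sel, drop = FALSE]
  h2 <- cohort$hap2[rows, snp_sel, drop = FALSE]
  p_old <- colMeans(rbind(h1, h2), na.rm = TRUE)
  p_center <- p_old[which.min(d)]
  B <- rbinom(1L, 1L, p_center)
  cc <- 1 - exp(-recomb_rate_per_bp * d / s_tilde)
  p_new <- cc * p_old + (1 - cc) * B

  n <- length(rows)
  m <- length(snp_sel)
  new1 <- matrix(rbinom(n * m, 1L, rep(p_new, each = n)), nrow = n)
  new2 <- if (inbred) new1 else
    matrix(rbinom(n * m, 1L, rep(p_new, each = n)), nrow = n)
  new1[is.na(h1)] <- NA_integer_
  new2[is.na(h2)] <- NA_integer_
  cohort$hap1[rows, snp_sel] <- new1
  cohort$hap2[rows, snp_sel] <- new2
  cohort$dosage[rows, snp_sel] <- new1 + new2

  if (!is.null(truth)) {
    truth$sweeps <- dplyr::bind_rows(
      truth$sweeps,
      tibble::tibble(
        chrom = chrom, start = center - half_width, end = center + half_width,
        target_population = target_population,
        s_tilde = s_tilde, background_allele = B
      )
    )
    attr(cohort, "truth") <- truth
  }
  cohort
}

#' Simulate a quantitative phenotype on a cohort
#'
#' Generates `y = sum_k effect_k * dosage_k + g + e`: an additive
#' contribution from the named causal SNPs, a polygenic term `g` with
#' covariance proportional to the realized kinship matrix, and i.i.d.
#' Gaussian noise. The polygenic variance is scaled so that
#' `h2_polygenic = var_g / (var_g + noise_sd^2)` relative to the noise;
#' `h2_polygenic = 0` drops the term. Missing causal dosages are mean-imputed
#' for the additive term. This emulates a BLUP-like flowering-time phenotype
#' with known causal loci.
#'
#' @param cohort a cohort.
#' @param causal_snps character SNP ids (or integer indices) of causal loci.
#' @param effects additive effect per alternate-allele copy, one per causal
#'   SNP.
#' @param h2_polygenic polygenic heritability relative to noise, in \[0, 1).
#' @param noise_sd residual standard deviation (trait units).
#' @param seed integer seed.
#' @param trait trait label.
#' @return tibble `sample`, `trait`, `value`.
#' @export
simulate_phenotype <- function(cohort, causal_snps = character(), effects = numeric(),
                               h2_polygenic = 0.3, noise_sd = 1, seed = 1,
                               trait = "DTA") {
  stopifnot(is_cohort(cohort))
  if (length(causal_snps) != length(effects)) {
    stop("causal_snps and effects must have the same length")
  }
  if (h2_polygenic < 0 || h2_polygenic >= 1) {
    stop("h2_polygenic must lie in [0, 1)")
  }
  if (is.numeric(causal_snps)) {
    if (any(causal_snps < 1 | causal_snps > n_snps(cohort))) {
      stop("causal SNP index out of range")
    }
    causal_snps <- colnames(cohort$dosage)[causal_snps]
  }
  if (!all(causal_snps %in% colnames(cohort$dosage))) {
    stop("causal SNP not present in cohort")
  }

  set.seed(seed)
  n <- n_samples(cohort)
  y <- numeric(n)
  if (length(causal_snps) > 0) {
    X <- cohort$dosage[, causal_snps, drop = FALSE]
    X <- apply(X, 2, function(v) {
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      v
    })
    y <- y + drop(X %*% effects)
  }
  if (h2_polygenic > 0) {
    K <- kinship(cohort)
    eg <- eigen(K, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    var_g <- noise_sd^2 * h2_polygenic / (1 - h2_polygenic)
    ## scale so mean genetic variance across samples is var_g
    lam <- lam * var_g / mean(diag(K))
    g <- drop(eg$vectors %*% (sqrt(lam) * rnorm(n)))
    y <- y + g
  }
  if (noise_sd > 0) y <- y + rnorm(n, sd = noise_sd)

  tibble::tibble(sample = cohort$samples$sample, trait = trait, value = unname(y))
}
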