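#' Filter SNPs on missingness, polymorphism and MAF
#'
#' Retains SNPs whose missing fraction is strictly below `max_missing`
#' (default 20%, the chip QC rule), that show at least two observed alleles
#' when `require_polymorphic`, and whose minor allele frequency is at least
#' `min_maf`. SNP order is preserved and the counts removed by each
#' criterion are attached as `attr(, "removed")`.
#'
#' @param cohort a cohort.
#' @param max_missing maximum tolerated missing fraction (exclusive bound).
#' @param require_polymorphic drop monomorphic SNPs?
#' @param min_maf minimum minor allele frequency (inclusive).
#' @return the filtered cohort.
#' @export
filter_snps <- function(cohort, max_missing = 0.20,
                        require_polymorphic = TRUE, min_maf = 0) {
  stopifnot(is_cohort(cohort))
  d <- cohort$dosage
  miss <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0

  keep_miss <- miss < max_missing
  poly <- !is.nan(p) & p > 0 & p < 1
  keep_poly <- if (require_polymorphic) poly else rep(TRUE, ncol(d))
  keep_maf <- maf >= min_maf
  keep <- keep_miss & keep_poly & keep_maf

  if (!any(keep)) warning("all SNPs removed by filters; empty cohort returned")
  out <- subset_snps(cohort, which(keep))
  attr(out, "removed") <- c(
    missingness = sum(!keep_miss),
    monomorphic = sum(keep_miss & !keep_poly),
    maf = sum(keep_miss & keep_poly & !keep_maf)
  )
  out
}

subset_snps <- function(cohort, idx) {
  out <- cohort
  out$dosage <- cohort$dosage[, idx, drop = FALSE]
  out$hap1 <- cohort$hap1[, idx, drop = FALSE]
  out$hap2 <- cohort$hap2[, idx, drop = FALSE]
  out$variants <- cohort$variants[idx, , drop = FALSE]
  tr <- attr(cohort, "truth")
  if (!is.null(tr)) {
    tr$freqs <- lapply(tr$freqs, `[`, idx)
    attr(out, "truth") <- tr
  }
  out
}

#' Per-group alternate-allele frequencies
#'
#' Frequency of the alternate allele among non-missing alleles of the given
#' group. For fully inbred lines the denominator is still 2n alleles, but
#' only n independent draws are present (the two haplotypes of an inbred
#' line are copies); frequencies are unbiased either way. SNPs with no
#' non-missing call in the group get `NA`.
#'
#' @param cohort a cohort.
#' @param group group label from `cohort$samples$group`; `NULL` uses all
#'   samples.
#' @return tibble `snp_id`, `chrom`, `pos`, `freq`, `n_called` (number of
#'   non-missing diploid calls).
#' @export
allele_freq <- function(cohort, group = NULL) {
  stopifnot(is_cohort(cohort))
  rows <- if (is.null(group)) seq_len(n_samples(cohort)) else
    group_idx(cohort, group)
  d <- cohort$dosage[rows, , drop = FALSE]
  n_called <- colSums(!is.na(d))
  freq <- colSums(d, na.rm = TRUE) / (2 * n_called)
  freq[n_called == 0] <- NA_real_
  tibble::tibble(
    snp_id = cohort$variants$snp_id,
    chrom = cohort$variants$chrom,
    pos = cohort$variants$pos,
    freq = unname(freq),
    n_called = unname(n_called)
  )
}

#' Polymorphic information content
#'
#' PIC of a biallelic marker with allele frequencies p and q = 1 - p:
#' `PIC = 1 - p^2 - q^2 - 2 p^2 q^2` (the PowerMarker definition,
#' specialised from `1 - sum_i p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`).
#'
#' @param p numeric vector of alternate-allele frequencies in \[0, 1\].
#' @return numeric vector of PIC values.
#' @export
#' @examples
#' pic(c(0, 0.5, 0.9))
pic <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("frequencies must lie in [0, 1]")
  q <- 1 - p
  1 - p^2 - q^2 - 2 * p^2 * q^2
}

#' Per-SNP summary statistics
#'
#' @param cohort a cohort.
#' @return tibble `snp_id`, `chrom`, `pos`, `maf`, `pic`, `missing`.
#' @export
snp_stats <- function(cohort) {
  af <- allele_freq(cohort)
  af |>
    dplyr::mutate(
      maf = pmin(.data$freq, 1 - .data$freq),
      pic = pic(.data$freq),
      missing = 1 - .data$n_called / n_samples(cohort)
    ) |>
    dplyr::select("snp_id", "chrom", "pos", "maf", "pic", "missing")
}
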