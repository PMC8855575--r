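#' Cohort container
#'
#' A `zea_cohort` bundles a phased diploid genotype matrix with its variant
#' table and sample metadata. Haplotypes are stored as two integer matrices
#' (`hap1`, `hap2`, samples x SNPs, entries 0/1/NA for the reference /
#' alternate allele / missing); `dosage` is always `hap1 + hap2`. Analysis
#' functions take the cohort first and return tibbles, so pipelines chain
#' with the pipe.
#'
#' @param hap1,hap2 integer matrices (samples x SNPs) of phased alleles in
#'   \{0, 1, NA\}; dimnames give sample IDs and SNP IDs.
#' @param variants tibble with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; positions strictly increasing within chromosome.
#' @param samples tibble with columns `sample`, `group`.
#' @param phased logical; whether `hap1`/`hap2` carry real phase information.
#'
#' @return An object of class `zea_cohort` with elements `dosage`, `hap1`,
#'   `hap2`, `variants`, `samples`, `phased`.
#' @export
new_cohort <- function(hap1, hap2, variants, samples, phased = TRUE) {
  stopifnot(
    is.matrix(hap1), is.matrix(hap2),
    all(dim(hap1) == dim(hap2)),
    nrow(hap1) == nrow(samples),
    ncol(hap1) == nrow(variants)
  )
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  bad <- variants |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(bad$ok)) {
    stop("variant positions must be strictly increasing within chromosome")
  }
  dimnames(hap1) <- dimnames(hap2) <- list(samples$sample, variants$snp_id)
  structure(
    list(
      dosage = hap1 + hap2,
      hap1 = hap1, hap2 = hap2,
      variants = variants, samples = samples,
      phased = isTRUE(phased)
    ),
    class = "zea_cohort"
  )
}

#' @exportS3Method print zea_cohort
print.zea_cohort <- function(x, ...) {
  cat(sprintf(
    "<zea_cohort> %d samples x %d SNPs on %d chromosome(s)%s\n",
    nrow(x$dosage), ncol(x$dosage),
    dplyr::n_distinct(x$variants$chrom),
    if (x$phased) ", phased" else ""
  ))
  grp <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  cat(sprintf(
    "  missingness: %.1f%%\n", 100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @rdname new_cohort
#' @param x object to test.
#' @export
is_cohort <- function(x) inherits(x, "zea_cohort")

#' Number of samples / SNPs in a cohort
#' @param cohort a [new_cohort()] object.
#' @return integer count.
#' @export
n_samples <- function(cohort) nrow(cohort$dosage)

#' @rdname n_samples
#' @export
n_snps <- function(cohort) ncol(cohort$dosage)

#' Sample indices of one group
#' @keywords internal
group_idx <- function(cohort, group) {
  if (!group %in% cohort$samples$group) {
    stop("unknown group: ", group)
  }
  which(cohort$samples$group == group)
}
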