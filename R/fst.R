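#' Weir-Cockerham variance components for one SNP
#'
#' Two-population Weir & Cockerham (1984) estimator from diploid dosage
#' vectors: computes the among-population (a), among-individual (b) and
#' within-individual (c) variance components from the sample sizes, allele
#' frequencies and observed heterozygosities. The per-SNP estimate
#' `theta = a / (a + b + c)` may be negative.
#'
#' @param d1,d2 dosage vectors (0/1/2, `NA` missing) for the two
#'   populations at one SNP; each needs at least one non-missing call.
#' @return one-row tibble `a`, `b`, `c`, `theta`, `n1`, `n2`.
#' @export
#' @examples
#' wc_fst_snp(c(2, 2, 1, 1, 0), c(0, 0, 0, 1, 0))
wc_fst_snp <- function(d1, d2) {
  d1 <- d1[!is.na(d1)]; d2 <- d2[!is.na(d2)]
  if (length(d1) == 0 || length(d2) == 0) {
    stop("both populations need at least one non-missing call")
  }
  comp <- wc_components(
    n1 = length(d1), p1 = mean(d1) / 2, h1 = mean(d1 == 1),
    n2 = length(d2), p2 = mean(d2) / 2, h2 = mean(d2 == 1)
  )
  tibble::tibble(
    a = comp$a, b = comp$b, c = comp$c,
    theta = comp$a / (comp$a + comp$b + comp$c),
    n1 = length(d1), n2 = length(d2)
  )
}

## vectorized W&C (1984) two-population components from summary stats
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (
    s2 - 1 / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4)
  )
  b <- nbar / (nbar - 1) * (
    pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar
  )
  c_ <- hbar / 2
  list(a = a, b = b, c = c_)
}

#' Genome-wide Weir-Cockerham components for a population pair
#'
#' Computes the per-SNP a, b, c components for all SNPs typed in both
#' groups. SNPs with no non-missing call in either group are excluded (the
#' count is in `attr(, "n_excluded")`).
#'
#' @param cohort a cohort.
#' @param group1,group2 group labels.
#' @return tibble `snp_id`, `chrom`, `pos`, `a`, `b`, `c`, `theta`.
#' @export
wc_fst_components <- function(cohort, group1, group2) {
  stopifnot(is_cohort(cohort))
  s1 <- pop_summary(cohort$dosage[group_idx(cohort, group1), , drop = FALSE])
  s2 <- pop_summary(cohort$dosage[group_idx(cohort, group2), , drop = FALSE])
  ok <- s1$n > 0 & s2$n > 0
  comp <- wc_components(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
  out <- tibble::tibble(
    snp_id = cohort$variants$snp_id,
    chrom = cohort$variants$chrom,
    pos = cohort$variants$pos,
    a = unname(comp$a), b = unname(comp$b), c = unname(comp$c),
    theta = unname(comp$a / (comp$a + comp$b + comp$c))
  )[ok, ]
  attr(out, "n_excluded") <- sum(!ok)
  out
}

pop_summary <- function(d) {
  n <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n)
  h <- colSums(d == 1, na.rm = TRUE) / n
  list(n = n, p = p, h = h)
}

#' Windowed weighted FST
#'
#' Slides half-open windows of `window_bp` advanced by `step_bp` along each
#' chromosome and reports the weighted Weir-Cockerham ratio
#' `sum(a) / sum(a + b + c)` over member SNPs (a ratio of sums, not a mean
#' of per-SNP ratios). Windows with fewer than `min_snps` SNPs are dropped.
#' Negative window values are kept as-is so empirical quantile thresholds
#' stay unbiased.
#'
#' @param components tibble from [wc_fst_components()].
#' @param window_bp,step_bp window and step size in bp (defaults 100 kb and
#'   10 kb).
#' @param min_snps minimum SNPs per retained window (default 5).
#' @return window score track: tibble `chrom`, `start`, `end`, `n_snps`,
#'   `score`, with `attr(, "stat") == "fst"`.
#' @export
windowed_fst <- function(components, window_bp = 1e5, step_bp = 1e4,
                         min_snps = 5) {
  comp <- components |>
    dplyr::filter(is.finite(.data$a + .data$b + .data$c))
  track <- purrr::map_dfr(split(comp, comp$chrom), function(cc) {
    cc <- cc[order(cc$pos), ]
    slide_sums(
      pos0 = cc$pos - 1,
      values = cbind(a = cc$a, abc = cc$a + cc$b + cc$c),
      window_bp = window_bp, step_bp = step_bp
    ) |>
      dplyr::mutate(
        chrom = cc$chrom[1],
        score = .data$a / .data$abc
      )
  })
  track <- track |>
    dplyr::filter(.data$n_snps >= min_snps) |>
    dplyr::select("chrom", "start", "end", "n_snps", "score") |>
    dplyr::arrange(.data$chrom, .data$start)
  attr(track, "stat") <- "fst"
  track
}

## cumulative-sum sliding windows over 0-based SNP coordinates;
## returns one row per window touching at least one SNP
slide_sums <- function(pos0, values, window_bp, step_bp) {
  starts <- seq(0, max(pos0), by = step_bp)
  ends <- starts + window_bp
  cum <- apply(values, 2, cumsum)
  cum <- rbind(0, cum)
  lo <- findInterval(starts - 0.5, pos0)      # SNPs strictly before start
  hi <- findInterval(ends - 0.5, pos0)        # SNPs before end
  out <- tibble::tibble(start = starts, end = ends, n_snps = hi - lo)
  for (j in colnames(values)) {
    out[[j]] <- unname(cum[hi + 1, j] - cum[lo + 1, j])
  }
  out[out$n_snps > 0, ]
}

#' Pairwise genome-wide FST matrix
#'
#' Weighted Weir-Cockerham ratio (sum of a over sum of a + b + c across all
#' SNPs) for every pair of groups.
#'
#' @param cohort a cohort.
#' @param groups group labels (default: all, in sample-table order).
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_global_fst <- function(cohort, groups = unique(cohort$samples$group)) {
  stopifnot(is_cohort(cohort), length(groups) >= 2)
  unknown <- setdiff(groups, cohort$samples$group)
  if (length(unknown) > 0) {
    stop("unknown group: ", paste(unknown, collapse = ", "))
  }
  sizes <- table(cohort$samples$group)[groups]
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  k <- length(groups)
  m <- matrix(0, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      comp <- wc_fst_components(cohort, groups[i], groups[j])
      m[i, j] <- m[j, i] <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
    }
  }
  m
}
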