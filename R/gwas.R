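#' LD pruning of a genotype matrix
#'
#' PLINK-style pruning: within consecutive blocks of `window_snps` SNPs
#' (advancing by `step_snps`), any pair with squared dosage correlation
#' `r^2 >=` `r2_threshold` (pairwise-complete) loses its later-positioned
#' member, greedily in ascending position order. SNPs removed in an earlier
#' block stay removed.
#'
#' @param cohort a cohort.
#' @param window_snps,step_snps block geometry in SNP counts (default 50/50).
#' @param r2_threshold pruning threshold (default 0.2, pruned when `>=`).
#' @return character vector of retained SNP ids; `attr(, "n_removed")`
#'   holds the removed count.
#' @export
ld_prune <- function(cohort, window_snps = 50, step_snps = 50,
                     r2_threshold = 0.2) {
  stopifnot(is_cohort(cohort))
  d <- cohort$dosage
  m <- ncol(d)
  removed <- logical(m)
  for (s in seq(1, m, by = step_snps)) {
    idx <- s:min(s + window_snps - 1, m)
    idx <- idx[!removed[idx]]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(
      cor(d[, idx, drop = FALSE], use = "pairwise.complete.obs")
    )^2
    r2[is.na(r2)] <- 0
    for (j in seq_along(idx)[-1]) {
      kept_before <- which(!removed[idx[seq_len(j - 1)]])
      if (any(r2[kept_before, j] >= r2_threshold)) removed[idx[j]] <- TRUE
    }
    if (s + window_snps - 1 >= m) break
  }
  out <- colnames(d)[!removed]
  attr(out, "n_removed") <- sum(removed)
  out
}

#' Bonferroni significance threshold
#'
#' `1 / m` for `m` independent tests (the LD-pruned SNP count).
#'
#' @param m_independent number of independent tests (>= 1).
#' @return the p-value cutoff.
#' @export
#' @examples
#' bonferroni_threshold(165202)
bonferroni_threshold <- function(m_independent) {
  if (length(m_independent) != 1 || m_independent < 1) {
    stop("m_independent must be a single count >= 1")
  }
  1 / m_independent
}

#' Standardized genomic relationship (kinship) matrix
#'
#' Per-SNP mean imputation, centering by `2p` and scaling by
#' `sqrt(2p(1-p))`; `K = Z Z' / m`. Zero-variance SNPs are excluded. For
#' HWE outbred samples the diagonal averages 1; inbreeding inflates it.
#'
#' @param cohort a cohort.
#' @return symmetric positive semi-definite matrix (samples x samples).
#' @export
kinship <- function(cohort) {
  stopifnot(is_cohort(cohort))
  d <- cohort$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  ok <- !is.na(p) & p > 0 & p < 1
  d <- d[, ok, drop = FALSE]
  p <- p[ok]
  Z <- sweep(d, 2, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation after centering
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(d), rownames(d))
  K
}

#' Mixed-linear-model association scan (P3D)
#'
#' EMMA-style single-trait mixed model `y = W a + x b + u + e`,
#' `u ~ N(0, sg^2 K)`. The variance ratio is estimated once on the null
#' model by restricted maximum likelihood through the eigendecomposition of
#' `K` and 1-D optimization ("population parameters previously determined").
#' Each SNP is then tested by generalized least squares with the ratio
#' fixed; the Wald t statistic is referenced to `n - q - 1` degrees of
#' freedom, so with `K = I` the scan reduces exactly to ordinary least
#' squares. Missing dosages are mean-imputed per SNP; SNPs below `min_maf`
#' (computed on the analyzed samples) are excluded; samples with missing
#' phenotype are dropped.
#'
#' @param cohort a cohort.
#' @param phenotype tibble `sample`, `value` (a `trait` column is carried
#'   through if present).
#' @param K kinship matrix; `NULL` computes [kinship()] on the cohort.
#'   Non-PSD input is repaired by clamping negative eigenvalues (with a
#'   message).
#' @param n_pcs number of kinship principal components used as fixed
#'   covariates (default 3; 0 for intercept only).
#' @param covariates optional extra covariate matrix (samples x k, rownames
#'   = sample ids).
#' @param min_maf minor-allele-frequency filter (default 0.05).
#' @return a `zea_gwas` object; `tidy()` gives the per-SNP table
#'   (`snp_id`, `chrom`, `pos`, `maf`, `effect`, `se`, `statistic`,
#'   `p_value`), `glance()` the fit metadata.
#' @export
mlm_scan <- function(cohort, phenotype, K = NULL, n_pcs = 3,
                     covariates = NULL, min_maf = 0.05) {
  stopifnot(is_cohort(cohort))
  phenotype <- tibble::as_tibble(phenotype)
  ph <- phenotype[!is.na(phenotype$value), ]
  rows <- match(ph$sample, cohort$samples$sample)
  if (anyNA(rows)) stop("phenotype contains samples absent from the cohort")
  y <- ph$value
  n <- length(y)

  if (is.null(K)) K <- kinship(cohort)
  K <- K[rows, rows]
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    message("kinship not PSD; negative eigenvalues clamped")
    eg$values <- pmax(eg$values, 0)
  }
  U <- eg$vectors
  s <- pmax(eg$values, 0)

  W <- matrix(1, n, 1)
  if (n_pcs > 0) {
    W <- cbind(W, U[, seq_len(min(n_pcs, n - 2)), drop = FALSE] %*%
                 diag(sqrt(s[seq_len(min(n_pcs, n - 2))]),
                      min(n_pcs, n - 2)))
  }
  if (!is.null(covariates)) {
    W <- cbind(W, covariates[ph$sample, , drop = FALSE])
  }
  if (qr(W)$rank < ncol(W)) stop("singular covariate matrix")
  q <- ncol(W)

  ## null-model REML over lambda = sg^2 / se^2
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, W)
  reml <- function(log_lambda) {
    dvec <- exp(log_lambda) * s + 1
    sw <- 1 / sqrt(dvec)
    Ws <- Wt * sw
    ys <- yt * sw
    fit <- lm.fit(Ws, ys)
    rss <- sum(fit$residuals^2)
    WtW <- crossprod(Ws)
    -0.5 * ((n - q) * log(rss) + sum(log(dvec)) +
              determinant(WtW, logarithm = TRUE)$modulus)
  }
  opt <- optimize(reml, c(-12, 12), maximum = TRUE)
  lambda <- exp(opt$maximum)
  dvec <- lambda * s + 1
  sw <- 1 / sqrt(dvec)

  ## per-SNP GLS in the rotated/whitened basis
  d <- cohort$dosage[rows, , drop = FALSE]
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(!is.na(maf) & maf >= min_maf)
  X <- d[, keep, drop = FALSE]
  cm <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X))
  if (length(nas) > 0) X[nas] <- cm[(nas - 1) %/% nrow(X) + 1]

  Xs <- crossprod(U, X) * sw
  Ws <- Wt * sw
  ys <- yt * sw
  WtWi <- solve(crossprod(Ws))
  ## residualize against covariates
  RX <- Xs - Ws %*% (WtWi %*% crossprod(Ws, Xs))
  ry <- ys - Ws %*% (WtWi %*% crossprod(Ws, ys))
  sxx <- colSums(RX^2)
  sxy <- drop(crossprod(RX, ry))
  beta <- sxy / sxx
  rss <- drop(sum(ry^2) - beta * sxy)
  df <- n - q - 1
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)

  results <- tibble::tibble(
    snp_id = cohort$variants$snp_id[keep],
    chrom = cohort$variants$chrom[keep],
    pos = cohort$variants$pos[keep],
    maf = unname(maf[keep]),
    effect = unname(beta), se = unname(se),
    statistic = unname(tstat), p_value = unname(pval)
  )
  structure(
    list(
      results = results,
      trait = if ("trait" %in% names(ph)) ph$trait[1] else NA_character_,
      n_used = n, n_snps = length(keep),
      lambda = lambda,
      h2 = lambda / (1 + lambda),
      df = df
    ),
    class = "zea_gwas"
  )
}

#' @exportS3Method print zea_gwas
print.zea_gwas <- function(x, ...) {
  cat(sprintf(
    "<zea_gwas> trait %s: %d SNPs, %d samples, variance ratio %.3g (h2 %.2f)\n",
    x$trait, x$n_snps, x$n_used, x$lambda, x$h2
  ))
  top <- x$results[order(x$results$p_value), ][1, ]
  cat(sprintf("  top SNP %s (p = %.3g)\n", top$snp_id, top$p_value))
  invisible(x)
}

#' Resolve significant SNPs into loci
#'
#' Significant SNPs (`p <= cutoff`) are sorted and consecutive significant
#' SNPs within `merge_distance_bp` on the same chromosome are merged into
#' one locus; the lead SNP is the most significant member.
#'
#' @param gwas a `zea_gwas` object (or its `tidy()` tibble).
#' @param cutoff significance cutoff, e.g. [bonferroni_threshold()].
#' @param merge_distance_bp merge distance (default 1 Mb).
#' @return tibble `locus`, `chrom`, `start`, `end`, `n_snps`, `lead_snp`,
#'   `lead_pos`, `lead_maf`, `lead_p`; empty (not an error) when nothing is
#'   significant.
#' @export
resolve_loci <- function(gwas, cutoff, merge_distance_bp = 1e6) {
  res <- if (inherits(gwas, "zea_gwas")) gwas$results else tibble::as_tibble(gwas)
  sig <- res |>
    dplyr::filter(.data$p_value <= cutoff) |>
    dplyr::arrange(.data$chrom, .data$pos)
  if (nrow(sig) == 0) {
    return(tibble::tibble(
      locus = integer(), chrom = character(), start = numeric(),
      end = numeric(), n_snps = integer(), lead_snp = character(),
      lead_pos = numeric(), lead_maf = numeric(), lead_p = numeric()
    ))
  }
  sig |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      .new = c(TRUE, diff(.data$pos) > merge_distance_bp),
      .cluster = cumsum(.data$.new)
    ) |>
    dplyr::group_by(.data$chrom, .data$.cluster) |>
    dplyr::summarise(
      start = min(.data$pos), end = max(.data$pos),
      n_snps = dplyr::n(),
      lead_snp = .data$snp_id[which.min(.data$p_value)],
      lead_pos = .data$pos[which.min(.data$p_value)],
      lead_maf = .data$maf[which.min(.data$p_value)],
      lead_p = min(.data$p_value),
      .groups = "drop"
    ) |>
    dplyr::select(-".cluster") |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(locus = dplyr::row_number(), .before = 1)
}

#' Per-group allele frequency at one SNP
#'
#' Frequency of the chosen allele in each group. For fully inbred lines
#' this is the fraction of lines homozygous for the allele; heterozygotes
#' count 0.5 (a message reports their presence).
#'
#' @param cohort a cohort.
#' @param snp SNP id.
#' @param allele `"alt"`, `"ref"`, or an allele base present at the SNP.
#' @param groups groups to report (default all).
#' @return tibble `group`, `n_called`, `freq`, `pct` (percentage rounded to
#'   the integer, as conventionally reported); groups with no non-missing
#'   call get `NA` frequencies.
#' @export
group_freq_contrast <- function(cohort, snp, allele = "alt",
                                groups = unique(cohort$samples$group)) {
  stopifnot(is_cohort(cohort))
  j <- match(snp, cohort$variants$snp_id)
  if (is.na(j)) stop("SNP not found: ", snp)
  v <- cohort$variants[j, ]
  allele <- switch(allele, alt = "alt", ref = "ref",
                   if (allele == v$alt) "alt" else if (allele == v$ref) "ref"
                   else stop("allele ", allele, " not present at ", snp))
  dos <- cohort$dosage[, j]
  if (allele == "ref") dos <- 2 - dos
  if (any(dos == 1, na.rm = TRUE)) {
    message(sum(dos == 1, na.rm = TRUE), " heterozygous call(s) counted 0.5")
  }
  purrr::map_dfr(groups, function(gr) {
    gd <- dos[group_idx(cohort, gr)]
    n_called <- sum(!is.na(gd))
    freq <- if (n_called == 0) NA_real_ else mean(gd, na.rm = TRUE) / 2
    tibble::tibble(
      group = gr, n_called = n_called, freq = freq,
      pct = round(100 * freq)
    )
  })
}
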