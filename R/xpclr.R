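#' Drift-scale calibration for the composite-likelihood scan
#'
#' Method-of-moments estimate of the drift variance scale omega between a
#' reference and a test population:
#' `omega = mean((p_test - p_ref)^2 / (p_ref (1 - p_ref)))` over SNPs whose
#' reference frequency lies strictly inside (0.05, 0.95). Under
#' Balding-Nichols drift with parameter F this recovers F in expectation.
#'
#' @param ref_freqs,test_freqs per-SNP allele frequencies (same length).
#' @param min_snps minimum number of informative SNPs (default 100).
#' @return scalar omega.
#' @export
estimate_omega <- function(ref_freqs, test_freqs, min_snps = 100) {
  ok <- !is.na(ref_freqs) & !is.na(test_freqs) &
    ref_freqs > 0.05 & ref_freqs < 0.95
  if (sum(ok) < min_snps) {
    stop("too few informative SNPs (", sum(ok), " < ", min_snps, ")")
  }
  p <- ref_freqs[ok]
  mean((test_freqs[ok] - p)^2 / (p * (1 - p)))
}

## log truncated-normal density with boundary mass absorbed at {0, 1}
log_dens_trunc <- function(x, mu, sd) {
  out <- dnorm(x, mu, sd, log = TRUE)
  at0 <- x <= 0
  at1 <- x >= 1
  out[at0] <- pnorm(0, mu[at0], sd[at0], log.p = TRUE)
  out[at1] <- pnorm(1, mu[at1], sd[at1], lower.tail = FALSE, log.p = TRUE)
  out
}

#' Composite likelihood ratio for one window
#'
#' Evaluates the XP-CLR-style composite likelihood ratio for a window of
#' SNPs. Under the null, the test-population frequency at each SNP is
#' normal with mean `p_ref` and variance `omega * p_ref (1 - p_ref)`,
#' truncated to \[0, 1\] with the boundary mass absorbed at the edges.
#' Under a sweep centered at `center` with strength `s_tilde`, each SNP
#' escapes with probability `c_i = 1 - exp(-r d_i / s_tilde)` and the
#' density becomes the two-component hitchhiking mixture
#' `p_ref N(c_i p_ref + (1 - c_i), omega v) + (1 - p_ref) N(c_i p_ref, omega v)`.
#' The CLR is `2 (max over the s grid of the weighted alt log-likelihood -
#' weighted null log-likelihood)`, floored at zero.
#'
#' @param p_ref,p_test reference/test allele frequencies of the window SNPs
#'   (`p_ref` strictly inside (0, 1); degenerate SNPs must be excluded
#'   upstream).
#' @param pos SNP positions (bp, 1-based).
#' @param center putative sweep position (bp); the window midpoint in
#'   scanning use.
#' @param omega drift scale from [estimate_omega()] (> 0).
#' @param recomb_rate_per_bp recombination rate per bp.
#' @param s_grid grid of sweep-strength values to maximize over.
#' @param weights per-SNP weights (LD down-weighting); default 1.
#' @return scalar CLR (>= 0).
#' @export
xpclr_window <- function(p_ref, p_test, pos, center, omega,
                         recomb_rate_per_bp = 1e-8,
                         s_grid = c(0.001, 0.005, 0.01, 0.05, 0.1),
                         weights = rep(1, length(p_ref))) {
  if (omega <= 0) stop("omega must be > 0")
  if (any(p_ref <= 0 | p_ref >= 1)) {
    stop("degenerate reference frequencies must be excluded")
  }
  v <- omega * p_ref * (1 - p_ref)
  sdv <- sqrt(v)
  ll_null <- sum(weights * log_dens_trunc(p_test, p_ref, sdv))
  d <- abs(pos - center)
  ll_alt <- vapply(s_grid, function(s) {
    cc <- 1 - exp(-recomb_rate_per_bp * d / s)
    l1 <- log_dens_trunc(p_test, cc * p_ref + (1 - cc), sdv)
    l0 <- log_dens_trunc(p_test, cc * p_ref, sdv)
    m <- pmax(l1, l0)
    mix <- m + log(p_ref * exp(l1 - m) + (1 - p_ref) * exp(l0 - m))
    sum(weights * mix)
  }, numeric(1))
  max(0, 2 * (max(ll_alt) - ll_null))
}

## 1/k weights for clusters of reference-LD-correlated SNPs (r^2 > cap)
ld_cluster_weights <- function(ref_dosage, cap) {
  k <- ncol(ref_dosage)
  if (k == 1) return(1)
  r2 <- suppressWarnings(cor(ref_dosage, use = "pairwise.complete.obs"))^2
  r2[is.na(r2)] <- 0
  adj <- r2 > cap
  comp <- rep(0L, k)
  cur <- 0L
  for (i in seq_len(k)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      stack <- i
      while (length(stack) > 0) {
        node <- stack[[1]]; stack <- stack[-1]
        if (comp[node] == 0L) {
          comp[node] <- cur
          stack <- c(stack, which(adj[node, ] & comp == 0L))
        }
      }
    }
  }
  sizes <- table(comp)
  1 / as.numeric(sizes[as.character(comp)])
}

#' Genome-wide composite-likelihood sweep scan
#'
#' Slides the same 100-kb/10-kb window grid as [windowed_fst()] and scores
#' each window with [xpclr_window()], with the putative sweep site fixed at
#' the window center. Exactly `n_snps_window` SNPs are used per window: a
#' seeded random subset when more are available, and the window is skipped
#' when fewer. SNPs fixed in the reference population are excluded. SNP
#' clusters with reference-population `r^2 >` `ld_r2_cap` are down-weighted
#' by one over the cluster size.
#'
#' @param cohort a cohort.
#' @param ref_group,test_group reference and test population labels (the
#'   drift null is conditioned on the reference).
#' @param window_bp,step_bp window geometry in bp.
#' @param n_snps_window SNPs per window (both minimum and maximum, default 5).
#' @param omega drift scale; `NULL` estimates it genome-wide via
#'   [estimate_omega()].
#' @param s_grid,recomb_rate_per_bp,ld_r2_cap model parameters, see
#'   [xpclr_window()].
#' @param seed seed for the per-window SNP subsampling.
#' @return window score track tibble `chrom`, `start`, `end`, `n_snps`,
#'   `score` with `attr(, "stat") == "xpclr"` and `attr(, "omega")`.
#' @export
xpclr_scan <- function(cohort, ref_group, test_group,
                       window_bp = 1e5, step_bp = 1e4, n_snps_window = 5,
                       omega = NULL,
                       s_grid = c(0.001, 0.005, 0.01, 0.05, 0.1),
                       recomb_rate_per_bp = 1e-8, ld_r2_cap = 0.95,
                       seed = 1) {
  stopifnot(is_cohort(cohort))
  ref_rows <- group_idx(cohort, ref_group)
  p_ref <- allele_freq(cohort, ref_group)$freq
  p_test <- allele_freq(cohort, test_group)$freq
  usable <- !is.na(p_ref) & !is.na(p_test) & p_ref > 0 & p_ref < 1
  if (is.null(omega)) omega <- estimate_omega(p_ref[usable], p_test[usable])

  v <- cohort$variants
  set.seed(seed)
  track <- purrr::map_dfr(unique(v$chrom), function(ch) {
    on_chr <- which(v$chrom == ch & usable)
    if (length(on_chr) == 0) return(NULL)
    pos <- v$pos[on_chr]
    starts <- seq(0, max(pos) - 1, by = step_bp)
    ends <- starts + window_bp
    lo <- findInterval(starts - 0.5, pos - 1)
    hi <- findInterval(ends - 0.5, pos - 1)
    n_in <- hi - lo
    keep <- which(n_in >= n_snps_window)
    score <- vapply(keep, function(w) {
      idx <- on_chr[(lo[w] + 1):hi[w]]
      if (length(idx) > n_snps_window) {
        idx <- sort(sample(idx, n_snps_window))
      }
      wts <- ld_cluster_weights(
        cohort$dosage[ref_rows, idx, drop = FALSE], ld_r2_cap
      )
      xpclr_window(
        p_ref = p_ref[idx], p_test = p_test[idx], pos = v$pos[idx],
        center = (starts[w] + ends[w]) / 2, omega = omega,
        recomb_rate_per_bp = recomb_rate_per_bp, s_grid = s_grid,
        weights = wts
      )
    }, numeric(1))
    tibble::tibble(
      chrom = ch, start = starts[keep], end = ends[keep],
      n_snps = n_snps_window, score = score
    )
  })
  track <- dplyr::arrange(track, .data$chrom, .data$start)
  attr(track, "stat") <- "xpclr"
  attr(track, "omega") <- omega
  track
}
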