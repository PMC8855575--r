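## normalize a signal catalogue to 0-based half-open intervals:
## point signals (chrom, pos; 1-based SNP coordinates) become [pos-1, pos)
normalize_signals <- function(signals) {
  signals <- tibble::as_tibble(signals)
  if (all(c("start", "end") %in% names(signals))) {
    tibble::tibble(chrom = signals$chrom,
                   start = signals$start, end = signals$end)
  } else if ("pos" %in% names(signals)) {
    tibble::tibble(chrom = signals$chrom,
                   start = signals$pos - 1, end = signals$pos)
  } else {
    stop("signals need either a pos column or start/end columns")
  }
}

#' Co-localization of sweeps with GWAS signals
#'
#' A sweep is co-located iff at least one signal lies within
#' `[start - flank_bp, end + flank_bp)`. Point signals are SNP positions
#' (1-based); interval signals (e.g. known selected genes as BED) co-locate
#' when they overlap the flanked sweep by >= 1 bp.
#'
#' @param sweeps a sweep set.
#' @param signals signal catalogue: tibble with `chrom` and either `pos` or
#'   `start`/`end`.
#' @param flank_bp symmetric flank added to each sweep.
#' @return list with `sweeps` (the co-located subset plus `n_signals`),
#'   `n` (count of co-located sweeps), `total`, and `pct`
#'   (`100 n / total`, rounded to 1 decimal).
#' @export
signal_overlap <- function(sweeps, signals, flank_bp = 0) {
  sig <- normalize_signals(signals)
  hits <- vapply(seq_len(nrow(sweeps)), function(i) {
    ss <- sig[sig$chrom == sweeps$chrom[i], ]
    sum(ss$start < sweeps$end[i] + flank_bp &
          ss$end > sweeps$start[i] - flank_bp)
  }, numeric(1))
  out <- sweeps
  out$n_signals <- as.integer(hits)
  list(
    sweeps = out[hits > 0, ],
    n = sum(hits > 0),
    total = nrow(sweeps),
    pct = round(100 * sum(hits > 0) / nrow(sweeps), 1)
  )
}

#' Permutation test for sweep-signal enrichment
#'
#' Places, in each permutation, the same number of regions with the same
#' lengths as the observed sweeps at uniformly random genomic positions
#' (chromosome chosen with probability proportional to its length among the
#' chromosomes the region fits on; start uniform such that the region fits;
#' overlaps among placed regions permitted) and recomputes the
#' co-localization statistic (number of regions containing >= 1 signal, or
#' the number of signals hit with `count = "signals"`). The empirical
#' p-value uses the add-one correction
#' `p = (1 + #(perm >= observed)) / (n_perm + 1)`.
#'
#' @param sweeps a sweep set.
#' @param signals signal catalogue (see [signal_overlap()]).
#' @param genome_sizes tibble `chrom`, `length` (bp) or named vector.
#' @param n_perm number of permutations (default 1000).
#' @param seed seed; the test is deterministic given it.
#' @param flank_bp flank passed to the overlap rule.
#' @param count statistic convention: co-located `"sweeps"` (default) or
#'   hit `"signals"`.
#' @return one-row tibble `observed`, `expected_mean`, `p_value`, `n_perm`.
#' @export
permutation_enrichment <- function(sweeps, signals, genome_sizes,
                                   n_perm = 1000, seed = 1, flank_bp = 0,
                                   count = c("sweeps", "signals")) {
  count <- match.arg(count)
  if (!is.data.frame(genome_sizes)) {
    genome_sizes <- tibble::tibble(
      chrom = names(genome_sizes), length = as.numeric(genome_sizes)
    )
  }
  sig <- normalize_signals(signals)
  obs_lens <- sweeps$end - sweeps$start
  if (any(obs_lens > max(genome_sizes$length))) {
    stop("a sweep is longer than every chromosome")
  }
  observed <- if (count == "sweeps") {
    signal_overlap(sweeps, signals, flank_bp)$n
  } else {
    sum(overlaps_any(sig, dplyr::mutate(
      sweeps, start = .data$start - flank_bp, end = .data$end + flank_bp
    )))
  }

  set.seed(seed)
  n_reg <- nrow(sweeps)
  ## draw all placements at once: for each region, chromosomes that fit,
  ## sampled proportional to length
  chrom_id <- matrix(NA_integer_, n_perm, n_reg)
  start <- matrix(NA_real_, n_perm, n_reg)
  for (j in seq_len(n_reg)) {
    fits <- which(genome_sizes$length >= obs_lens[j])
    pr <- genome_sizes$length[fits] / sum(genome_sizes$length[fits])
    cj <- fits[sample.int(length(fits), n_perm, replace = TRUE, prob = pr)]
    chrom_id[, j] <- cj
    start[, j] <- floor(
      runif(n_perm) * (genome_sizes$length[cj] - obs_lens[j] + 1)
    )
  }
  end <- start + rep(obs_lens, each = n_perm)

  ## hit detection, vectorized per chromosome
  point_sig <- all(sig$end - sig$start == 1)
  hit <- matrix(FALSE, n_perm, n_reg)
  if (count == "sweeps") {
    for (ci in seq_len(nrow(genome_sizes))) {
      idx <- which(chrom_id == ci)
      if (length(idx) == 0) next
      ss <- sig[sig$chrom == genome_sizes$chrom[ci], ]
      if (nrow(ss) == 0) next
      if (point_sig) {
        v <- sort(ss$start)
        cnt <- findInterval(end[idx] + flank_bp - 1e-9, v) -
          findInterval(start[idx] - flank_bp - 1e-9, v)
        hit[idx] <- cnt > 0
      } else {
        for (i in idx) {
          hit[i] <- any(ss$start < end[i] + flank_bp &
                          ss$end > start[i] - flank_bp)
        }
      }
    }
    perm_stat <- rowSums(hit)
  } else {
    perm_stat <- vapply(seq_len(n_perm), function(i) {
      tot <- 0L
      for (ci in unique(chrom_id[i, ])) {
        ss <- sig[sig$chrom == genome_sizes$chrom[ci], ]
        if (nrow(ss) == 0) next
        jj <- which(chrom_id[i, ] == ci)
        covered <- vapply(seq_len(nrow(ss)), function(k) {
          any(start[i, jj] < ss$end[k] & end[i, jj] > ss$start[k])
        }, logical(1))
        tot <- tot + sum(covered)
      }
      tot
    }, integer(1))
  }

  tibble::tibble(
    observed = observed,
    expected_mean = mean(perm_stat),
    p_value = (1 + sum(perm_stat >= observed)) / (n_perm + 1),
    n_perm = n_perm
  )
}
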