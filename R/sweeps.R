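## Merge sorted half-open intervals per chromosome. Two intervals merge when
## gap = next_start - running_max_end < max_gap_bp, so:
##   max_gap_bp = 0 merges strictly overlapping intervals only,
##   max_gap_bp = 1 additionally merges touching ones,
##   max_gap_bp = 1e5 merges anything closer than 100 kb (strict <).
merge_intervals <- function(df, max_gap_bp = 0, score_col = NULL) {
  df <- dplyr::arrange(df, .data$chrom, .data$start, .data$end)
  df <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      .prev_end = dplyr::lag(cummax(.data$end)),
      .new = is.na(.data$.prev_end) | (.data$start - .data$.prev_end >= max_gap_bp),
      .cluster = cumsum(.data$.new)
    ) |>
    dplyr::group_by(.data$chrom, .data$.cluster)
  out <- df |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_members = dplyr::n(),
      region_score = if (!is.null(score_col)) max(.data[[score_col]]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::select(-".cluster")
  attr(out, "members") <- dplyr::group_indices(df)
  out
}

#' Call selective sweeps from a window score track
#'
#' The study's two-step empirical rule: (1) compute the merge (P90) and
#' outlier (P99.5) quantiles over all window scores; (2) mark windows at or
#' above P90 and merge overlapping or adjacent marked windows into candidate
#' regions; (3) keep regions whose maximum member-window score reaches
#' P99.5. Both quantiles are computed on the window score distribution.
#'
#' @param track a window score track from [windowed_fst()] or
#'   [xpclr_scan()].
#' @param merge_quantile quantile marking windows for merging (default 0.90).
#' @param outlier_quantile outlier quantile retained as sweeps (default
#'   0.995).
#' @param min_windows minimum track size for the quantiles to be meaningful.
#' @param method,comparison optional labels carried into the output.
#' @return sweep set: tibble `chrom`, `start`, `end`, `n_windows`,
#'   `region_score`, `method`, `comparison`; thresholds in
#'   `attr(, "thresholds")`.
#' @export
call_sweeps <- function(track, merge_quantile = 0.90, outlier_quantile = 0.995,
                        min_windows = 200, method = NA_character_,
                        comparison = NA_character_) {
  if (nrow(track) < min_windows) {
    stop(
      "only ", nrow(track), " windows; quantile thresholds need >= ",
      min_windows, " (use smaller windows or steps)"
    )
  }
  if (is.na(method) && !is.null(attr(track, "stat"))) {
    method <- attr(track, "stat")
  }
  q_merge <- quantile(track$score, merge_quantile, na.rm = TRUE, names = FALSE)
  q_out <- quantile(track$score, outlier_quantile, na.rm = TRUE, names = FALSE)
  empty <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    n_windows = integer(), region_score = numeric(),
    method = character(), comparison = character()
  )
  if (max(track$score) == min(track$score)) {
    warning("all window scores identical: no outliers to call")
    return(empty)
  }
  marked <- track[track$score >= q_merge, ]
  regions <- merge_intervals(marked, max_gap_bp = 1, score_col = "score")
  regions <- regions[regions$region_score >= q_out, ]
  out <- tibble::tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    n_windows = regions$n_members, region_score = regions$region_score,
    method = method, comparison = comparison
  )
  attr(out, "thresholds") <- c(merge = q_merge, outlier = q_out)
  out
}

#' Merge nearby sweeps into selected loci
#'
#' Adjacent sweeps separated by less than `max_gap_bp` (strict) are merged
#' into a single selected locus; the merged region score is the maximum of
#' the parts. Idempotent.
#'
#' @param sweeps a sweep set.
#' @param max_gap_bp maximum separating distance (default 100 kb).
#' @return merged sweep set.
#' @export
merge_nearby <- function(sweeps, max_gap_bp = 1e5) {
  if (nrow(sweeps) == 0) return(sweeps)
  merged <- merge_intervals(sweeps, max_gap_bp = max_gap_bp,
                            score_col = "region_score")
  tibble::tibble(
    chrom = merged$chrom, start = merged$start, end = merged$end,
    n_windows = merged$n_members, region_score = merged$region_score,
    method = sweeps$method[1], comparison = sweeps$comparison[1]
  )
}

#' Combine sweeps from the two scan methods
#'
#' A region is "common" iff it overlaps a region from the other method by at
#' least `min_overlap_bp`. The joint set is the union of both sets with
#' overlapping regions merged; the Venn counts report method-specific and
#' common region numbers.
#'
#' @param fst_sweeps,xpclr_sweeps sweep sets for the same comparison.
#' @param min_overlap_bp minimum overlap to call regions common (default 1).
#' @return list with `sweeps` (the joint set, method `"joint"`) and `venn`
#'   (tibble `fst_only`, `xpclr_only`, `common`, `total`).
#' @export
combine_methods <- function(fst_sweeps, xpclr_sweeps, min_overlap_bp = 1) {
  cmp1 <- fst_sweeps$comparison[1]; cmp2 <- xpclr_sweeps$comparison[1]
  if (!identical(cmp1, cmp2) && !(is.na(cmp1) && is.na(cmp2))) {
    stop("sweep sets come from different comparisons")
  }
  both <- dplyr::bind_rows(
    dplyr::mutate(fst_sweeps, .src = "fst"),
    dplyr::mutate(xpclr_sweeps, .src = "xpclr")
  )
  fst_common <- overlaps_any(fst_sweeps, xpclr_sweeps, min_overlap_bp)
  xp_common <- overlaps_any(xpclr_sweeps, fst_sweeps, min_overlap_bp)

  merged <- merge_intervals(both, max_gap_bp = 1 - min_overlap_bp,
                            score_col = "region_score")
  ## merge_intervals sorts internally; recover member sources by re-sorting
  members <- attr(merged, "members")
  both_sorted <- dplyr::arrange(both, .data$chrom, .data$start, .data$end)
  srcs <- split(both_sorted$.src, members)
  n_common_regions <- sum(vapply(
    srcs, function(s) all(c("fst", "xpclr") %in% s), logical(1)
  ))
  joint <- tibble::tibble(
    chrom = merged$chrom, start = merged$start, end = merged$end,
    n_windows = merged$n_members, region_score = merged$region_score,
    method = "joint", comparison = cmp1
  )
  list(
    sweeps = joint,
    venn = tibble::tibble(
      fst_only = sum(!fst_common), xpclr_only = sum(!xp_common),
      fst_common = sum(fst_common), xpclr_common = sum(xp_common),
      common = n_common_regions, total = nrow(joint)
    )
  )
}

## for each interval of a, does it overlap (>= min_bp) any interval of b?
overlaps_any <- function(a, b, min_bp = 1) {
  if (nrow(a) == 0) return(logical(0))
  vapply(seq_len(nrow(a)), function(i) {
    bb <- b[b$chrom == a$chrom[i], ]
    any(pmin(bb$end, a$end[i]) - pmax(bb$start, a$start[i]) >= min_bp)
  }, logical(1))
}

#' Summarize a sweep set
#'
#' Region count, length statistics, genome coverage and the number of
#' annotated genes overlapping (by at least 1 bp) any sweep.
#'
#' @param sweeps a sweep set.
#' @param genes_bed gene intervals (`chrom`, `start`, `end`, 0-based
#'   half-open); sorted internally if needed.
#' @param genome_sizes tibble `chrom`, `length` or a named vector of
#'   chromosome lengths in bp.
#' @return one-row tibble `n`, `mean_length`, `min_length`, `max_length`,
#'   `total_bp`, `genome_frac`, `n_genes`.
#' @export
summarize_sweeps <- function(sweeps, genes_bed = NULL, genome_sizes = NULL) {
  if (nrow(sweeps) == 0) {
    return(tibble::tibble(
      n = 0L, mean_length = 0, min_length = 0, max_length = 0,
      total_bp = 0, genome_frac = 0, n_genes = 0L
    ))
  }
  len <- sweeps$end - sweeps$start
  total_bp <- sum(len)
  genome_bp <- if (is.null(genome_sizes)) NA_real_ else if (is.data.frame(genome_sizes)) {
    sum(genome_sizes$length)
  } else {
    sum(genome_sizes)
  }
  n_genes <- if (is.null(genes_bed)) NA_integer_ else {
    genes_bed <- dplyr::arrange(
      tibble::as_tibble(genes_bed), .data$chrom, .data$start
    )
    sum(overlaps_any(genes_bed, sweeps, min_bp = 1))
  }
  tibble::tibble(
    n = nrow(sweeps),
    mean_length = mean(len), min_length = min(len), max_length = max(len),
    total_bp = total_bp,
    genome_frac = total_bp / genome_bp,
    n_genes = n_genes
  )
}
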