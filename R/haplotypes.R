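#' Define 50-kb haplotype loci
#'
#' Tiles each chromosome into non-overlapping half-open windows of
#' `window_bp` (default 50 kb); windows containing no SNP are dropped.
#' Windows holding more than `max_snps` SNPs get a seeded uniform random
#' subset of exactly `max_snps` (the same subset is used for every
#' individual), so the SNP count per locus ranges from one to `max_snps`.
#'
#' @param variants variant tibble (`snp_id`, `chrom`, `pos`), sorted by
#'   position within chromosome.
#' @param window_bp window width in bp.
#' @param max_snps maximum SNPs per locus.
#' @param seed seed for the per-window SNP subsampling.
#' @return tibble `locus_id`, `chrom`, `start`, `end`, `n_snps`, and
#'   list-column `snp_id` with the selected SNP ids in ascending position.
#' @export
build_loci <- function(variants, window_bp = 50000, max_snps = 5, seed = 1) {
  variants <- tibble::as_tibble(variants)
  set.seed(seed)
  loci <- variants |>
    dplyr::mutate(start = ((.data$pos - 1) %/% window_bp) * window_bp) |>
    dplyr::group_by(.data$chrom, .data$start) |>
    dplyr::summarise(
      snp_id = list(.data$snp_id[order(.data$pos)]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
  ## seeded subsampling in a fixed locus order keeps the choice reproducible
  loci$snp_id <- lapply(loci$snp_id, function(ids) {
    if (length(ids) > max_snps) sort_by_order(sample(ids, max_snps), ids) else ids
  })
  loci |>
    dplyr::mutate(
      locus_id = sprintf("%s:%d", .data$chrom, .data$start),
      end = .data$start + window_bp,
      n_snps = lengths(.data$snp_id)
    ) |>
    dplyr::select("locus_id", "chrom", "start", "end", "n_snps", "snp_id")
}

## keep the elements of `x` in the order they appear in `template`
sort_by_order <- function(x, template) template[template %in% x]

#' Call window haplotype alleles from phased genotypes
#'
#' For each locus, each sample contributes its two phased haplotype strings
#' over the locus SNP subset; each unique string is one haplotype allele.
#' Haplotypes containing a missing allele are excluded from the counts (the
#' excluded number is reported in `attr(, "n_dropped")`).
#'
#' @param cohort a phased cohort.
#' @param loci loci tibble from [build_loci()].
#' @return a `hap_catalog`: list with `loci`, `samples`, per-haplotype
#'   integer `codes` (loci x 2n matrix; columns are all first then all
#'   second haplotypes in sample order), per-locus allele string labels
#'   `alleles`, and the tidy `counts` tibble
#'   (`locus_id`, `allele`, `group`, `count`).
#' @export
call_haplotypes <- function(cohort, loci) {
  stopifnot(is_cohort(cohort))
  if (!cohort$phased) {
    stop("cohort is not phased: phase the VCF or use simulated haplotypes")
  }
  n <- n_samples(cohort)
  col_idx <- match(unlist(loci$snp_id), colnames(cohort$hap1))
  if (anyNA(col_idx)) stop("locus SNP absent from cohort")
  idx_split <- split(col_idx, rep(seq_len(nrow(loci)), loci$n_snps))

  codes <- matrix(NA_integer_, nrow = nrow(loci), ncol = 2 * n)
  alleles <- vector("list", nrow(loci))
  n_dropped <- 0L
  for (i in seq_len(nrow(loci))) {
    idx <- idx_split[[i]]
    H <- cbind(
      t(cohort$hap1[, idx, drop = FALSE]),
      t(cohort$hap2[, idx, drop = FALSE])
    )
    str <- apply(H, 2, paste0, collapse = "")
    str[colSums(is.na(H)) > 0] <- NA_character_
    n_dropped <- n_dropped + sum(is.na(str))
    lv <- sort(unique(str[!is.na(str)]))
    codes[i, ] <- match(str, lv)
    alleles[[i]] <- lv
  }
  hap_groups <- rep(cohort$samples$group, 2)

  counts <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    cd <- codes[i, ]
    keep <- !is.na(cd)
    if (!any(keep)) return(NULL)
    tab <- table(allele = alleles[[i]][cd[keep]], group = hap_groups[keep])
    out <- tibble::as_tibble(tab, .name_repair = "minimal")
    names(out) <- c("allele", "group", "count")
    out$locus_id <- loci$locus_id[i]
    out[out$count > 0, c("locus_id", "allele", "group", "count")]
  })
  counts$count <- as.integer(counts$count)

  out <- structure(
    list(
      loci = loci, samples = cohort$samples,
      codes = codes, alleles = alleles, counts = counts
    ),
    class = "hap_catalog"
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @exportS3Method print hap_catalog
print.hap_catalog <- function(x, ...) {
  cat(sprintf(
    "<hap_catalog> %d loci, %d samples, %d groups\n",
    nrow(x$loci), nrow(x$samples), dplyr::n_distinct(x$samples$group)
  ))
  invisible(x)
}

#' Rarefied haplotype richness
#'
#' Expected number of distinct haplotype alleles in a random subsample of
#' `g` haplotypes, per locus and group:
#' `sum_i [1 - C(N - N_i, g) / C(N, g)]` with `N` the group's sampled
#' haplotypes at the locus and `N_i` each allele's count. The mean over loci
#' is reported per group. `g` may not exceed the smallest per-locus
#' haplotype sample size of any group.
#'
#' @param catalog a [call_haplotypes()] catalog.
#' @param g rarefaction subsample size (haplotypes).
#' @param groups groups to report; default all.
#' @return tibble `group`, `g`, `richness`.
#' @export
richness <- function(catalog, g, groups = unique(catalog$samples$group)) {
  stopifnot(inherits(catalog, "hap_catalog"), g >= 1)
  cnt <- catalog$counts |> dplyr::filter(.data$group %in% groups)
  totals <- cnt |>
    dplyr::group_by(.data$locus_id, .data$group) |>
    dplyr::summarise(N = sum(.data$count), .groups = "drop")
  lim <- totals |> dplyr::slice_min(.data$N, n = 1, with_ties = FALSE)
  if (g > lim$N) {
    stop(sprintf(
      "g = %d exceeds the smallest haplotype sample size (%d, group %s)",
      g, lim$N, lim$group
    ))
  }
  cnt |>
    dplyr::left_join(totals, by = c("locus_id", "group")) |>
    dplyr::mutate(
      contrib = 1 - exp(lchoose(.data$N - .data$count, g) - lchoose(.data$N, g))
    ) |>
    dplyr::group_by(.data$locus_id, .data$group) |>
    dplyr::summarise(rich = sum(.data$contrib), .groups = "drop") |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(g = g, richness = mean(.data$rich), .groups = "drop")
}

#' Group-specific haplotypes
#'
#' A haplotype allele is specific to a group iff its count is positive in
#' that group and zero in every other comparison group.
#'
#' @param catalog a catalog.
#' @param comparison_groups groups forming the comparison set (>= 2).
#' @return tibble `group`, `n_specific`, `n_lines`, `n_specific_per_line`.
#' @export
group_specific <- function(catalog,
                           comparison_groups = unique(catalog$samples$group)) {
  stopifnot(inherits(catalog, "hap_catalog"), length(comparison_groups) >= 2)
  cnt <- catalog$counts |> dplyr::filter(.data$group %in% comparison_groups)
  spec <- cnt |>
    dplyr::group_by(.data$locus_id, .data$allele) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::count(.data$group, name = "n_specific")
  sizes <- catalog$samples |>
    dplyr::filter(.data$group %in% comparison_groups) |>
    dplyr::count(.data$group, name = "n_lines")
  sizes |>
    dplyr::left_join(spec, by = "group") |>
    dplyr::mutate(
      n_specific = dplyr::coalesce(.data$n_specific, 0L),
      n_specific_per_line = .data$n_specific / .data$n_lines
    ) |>
    dplyr::select("group", "n_specific", "n_lines", "n_specific_per_line")
}

#' Shared-ancestry categories of maize haplotypes
#'
#' Every distinct haplotype observed in the chosen maize subset is assigned
#' exactly one category: `MPM` (also present in mexicana AND parviglumis),
#' `MM` (shared only with mexicana), `PM` (shared only with parviglumis),
#' `M` (private to maize). Percentages are over maize-observed distinct
#' haplotypes and sum to 100.
#'
#' @param catalog a catalog containing groups `mexicana`, `parviglumis` and
#'   the maize groups.
#' @param maize_subset `"all"` (tropical + temperate), `"tropical"` or
#'   `"temperate"`.
#' @param maize_groups the group labels regarded as maize.
#' @return tibble `category`, `n`, `pct`.
#' @export
shared_categories <- function(catalog, maize_subset = c("all", "tropical", "temperate"),
                              maize_groups = c("tropical", "temperate")) {
  stopifnot(inherits(catalog, "hap_catalog"))
  maize_subset <- match.arg(maize_subset)
  sel <- if (maize_subset == "all") maize_groups else maize_subset
  need <- c("mexicana", "parviglumis", sel)
  have <- unique(catalog$counts$group)
  if (!all(need %in% have)) {
    stop("catalog lacks required group(s): ",
         paste(setdiff(need, have), collapse = ", "))
  }
  presence <- catalog$counts |>
    dplyr::mutate(
      who = dplyr::case_when(
        .data$group %in% sel ~ "maize",
        .data$group == "mexicana" ~ "mexicana",
        .data$group == "parviglumis" ~ "parviglumis",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::filter(!is.na(.data$who)) |>
    dplyr::distinct(.data$locus_id, .data$allele, .data$who) |>
    dplyr::mutate(seen = TRUE) |>
    tidyr::pivot_wider(
      names_from = "who", values_from = "seen", values_fill = FALSE
    )
  for (w in c("maize", "mexicana", "parviglumis")) {
    if (!w %in% names(presence)) presence[[w]] <- FALSE
  }
  cats <- presence |>
    dplyr::filter(.data$maize) |>
    dplyr::mutate(
      category = dplyr::case_when(
        .data$mexicana & .data$parviglumis ~ "MPM",
        .data$mexicana ~ "MM",
        .data$parviglumis ~ "PM",
        TRUE ~ "M"
      )
    ) |>
    dplyr::count(.data$category, name = "n")
  tibble::tibble(category = c("MPM", "MM", "PM", "M")) |>
    dplyr::left_join(cats, by = "category") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      pct = 100 * .data$n / sum(.data$n)
    )
}

#' Bootstrap-equalized per-locus haplotype counts
#'
#' Repeatedly subsamples `n` samples per group (without replacement by
#' default; groups of exactly `n` are used whole, smaller groups are used
#' whole with a message) and recounts the distinct haplotypes per locus,
#' returning the per-replicate mean per-locus haplotype count per group.
#' This equalizes sample sizes so haplotype diversity is comparable across
#' groups.
#'
#' @param catalog a catalog.
#' @param n subsample size per group (default 75, the smallest study group).
#' @param reps number of bootstrap replicates.
#' @param seed seed.
#' @param replace sample with replacement instead of subsampling.
#' @return tibble `rep`, `group`, `mean_haplotypes`; group order follows the
#'   catalog sample table and is stable across seeds.
#' @export
bootstrap_equalize <- function(catalog, n = 75, reps = 100, seed = 1,
                               replace = FALSE) {
  stopifnot(inherits(catalog, "hap_catalog"))
  groups <- unique(catalog$samples$group)
  n_ind <- nrow(catalog$samples)
  set.seed(seed)
  res <- purrr::map_dfr(seq_len(reps), function(r) {
    per_group <- purrr::map_dfr(groups, function(gr) {
      idx <- which(catalog$samples$group == gr)
      if (length(idx) < n && !replace) {
        message("group ", gr, " has fewer than ", n, " samples; used whole")
        take <- idx
      } else if (length(idx) == n && !replace) {
        take <- idx
      } else {
        take <- sample(idx, n, replace = replace)
      }
      cols <- c(take, n_ind + take)  # both haplotypes of each sample
      sub <- catalog$codes[, cols, drop = FALSE]
      cnt <- apply(sub, 1, function(z) length(unique(z[!is.na(z)])))
      tibble::tibble(group = gr, mean_haplotypes = mean(cnt[cnt > 0]))
    })
    per_group$rep <- r
    per_group
  })
  res[, c("rep", "group", "mean_haplotypes")]
}

#' Table-1-style haplotype summary
#'
#' Per-group totals of distinct window haplotypes, mean per-locus counts,
#' rarefied richness, and group-specific haplotype statistics.
#'
#' @param catalog a catalog.
#' @param g rarefaction size; default the smallest per-locus haplotype
#'   sample size across groups.
#' @return tibble with one row per group.
#' @export
haplotype_summary <- function(catalog, g = NULL) {
  stopifnot(inherits(catalog, "hap_catalog"))
  per_group <- catalog$counts |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_haplotypes_total = dplyr::n(),
      n_per_locus = dplyr::n() / dplyr::n_distinct(.data$locus_id),
      .groups = "drop"
    )
  if (is.null(g)) {
    g <- catalog$counts |>
      dplyr::group_by(.data$locus_id, .data$group) |>
      dplyr::summarise(N = sum(.data$count), .groups = "drop") |>
      dplyr::pull(.data$N) |>
      min()
  }
  rich <- richness(catalog, g)
  spec <- group_specific(catalog)
  per_group |>
    dplyr::left_join(rich, by = "group") |>
    dplyr::left_join(spec, by = "group")
}
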