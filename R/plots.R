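## cumulative genome coordinate shared by the track/manhattan plots
genome_coord <- function(chrom, pos) {
  lev <- unique(chrom)
  span <- tapply(pos, factor(chrom, levels = lev), max)
  offset <- setNames(c(0, cumsum(as.numeric(span)))[seq_along(lev)], lev)
  list(x = pos + offset[chrom], offsets = offset, levels = lev)
}

#' Plot sample coordinates of a GRM PCA
#'
#' @param object a `zea_pca` object.
#' @param dims which two components to draw.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.zea_pca <- function(object, dims = c(1, 2), ...) {
  nm <- paste0("PC", dims)
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(.data[[nm[1]]], .data[[nm[2]]], colour = .data$group)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", nm[1], 100 * object$var_explained[dims[1]]),
      y = sprintf("%s (%.1f%%)", nm[2], 100 * object$var_explained[dims[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of an association scan
#'
#' @param object a `zea_gwas` object.
#' @param cutoff optional significance line (e.g. the Bonferroni cutoff).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.zea_gwas <- function(object, cutoff = NULL, ...) {
  res <- object$results
  gc <- genome_coord(res$chrom, res$pos)
  res$x <- gc$x
  p <- ggplot2::ggplot(
    res, ggplot2::aes(.data$x, -log10(.data$p_value), colour = .data$chrom)
  ) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "genome position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(cutoff), linetype = 2)
  }
  p
}

#' Plot a window score track with called sweeps
#'
#' @param track a window score track.
#' @param sweeps optional sweep set to shade.
#' @return a ggplot.
#' @export
plot_score_track <- function(track, sweeps = NULL) {
  gc <- genome_coord(track$chrom, track$start)
  track$x <- gc$x
  p <- ggplot2::ggplot(
    track, ggplot2::aes(.data$x, .data$score, colour = .data$chrom)
  ) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::labs(
      x = "genome position",
      y = attr(track, "stat") %||% "score"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(sweeps) && nrow(sweeps) > 0) {
    sw <- sweeps
    sw$xmin <- sw$start + gc$offsets[sw$chrom]
    sw$xmax <- sw$end + gc$offsets[sw$chrom]
    p <- p + ggplot2::geom_rect(
      data = sw,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "red",
      inherit.aes = FALSE
    )
  }
  p
}

#' Shared-ancestry category bar plot
#'
#' @param categories tibble from [shared_categories()].
#' @return a ggplot.
#' @export
plot_shared_categories <- function(categories) {
  categories$category <- factor(
    categories$category, levels = c("MPM", "MM", "PM", "M")
  )
  ggplot2::ggplot(
    categories, ggplot2::aes(.data$category, .data$pct, fill = .data$category)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "% of maize haplotypes") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
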