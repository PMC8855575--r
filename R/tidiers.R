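#' Broom-style tidiers
#'
#' `tidy()` returns the per-observation table of a fitted object and
#' `glance()` a one-row model summary.
#'
#' @param x a `zea_pca` or `zea_gwas` object.
#' @param ... unused.
#' @return a tibble.
#' @name zeascan-tidiers
NULL

#' @rdname zeascan-tidiers
#' @export
tidy.zea_pca <- function(x, ...) x$scores

#' @rdname zeascan-tidiers
#' @export
glance.zea_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    pve_pc1 = x$var_explained[1],
    pve_pc2 = x$var_explained[2],
    pve_pc3 = x$var_explained[3]
  )
}

#' @rdname zeascan-tidiers
#' @export
tidy.zea_gwas <- function(x, ...) x$results

#' @rdname zeascan-tidiers
#' @export
glance.zea_gwas <- function(x, ...) {
  chisq <- stats::qchisq(x$results$p_value, df = 1, lower.tail = FALSE)
  tibble::tibble(
    trait = x$trait,
    n_samples = x$n_used,
    n_snps = x$n_snps,
    variance_ratio = x$lambda,
    h2 = x$h2,
    lambda_gc = stats::median(chisq) / stats::qchisq(0.5, 1)
  )
}
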