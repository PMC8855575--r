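#' PCA on the standardized genomic relationship matrix
#'
#' Genotypes are mean-imputed per SNP, centered by `2p` and scaled by
#' `sqrt(2p(1-p))`; the relationship matrix is the cross-product divided by
#' the number of SNPs, and its top eigenvectors give the sample coordinates.
#' Zero-variance SNPs are excluded automatically. The first three principal
#' components are the conventional choice for visualizing maize/teosinte
#' structure.
#'
#' @param cohort a cohort (>= 2 samples).
#' @param n_components number of components to return.
#' @return a `zea_pca` object: list with `scores` (tibble `sample`, `group`,
#'   `PC1`..), `eigenvalues`, and `var_explained`. `tidy()`, `glance()` and
#'   `autoplot()` methods are provided.
#' @export
grm_pca <- function(cohort, n_components = 3) {
  stopifnot(is_cohort(cohort), n_samples(cohort) >= 2)
  K <- kinship(cohort)
  eg <- eigen(K, symmetric = TRUE)
  k <- min(n_components, ncol(eg$vectors))
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- list(
    scores = dplyr::bind_cols(cohort$samples, tibble::as_tibble(scores)),
    eigenvalues = eg$values,
    var_explained = pmax(eg$values, 0) / sum(pmax(eg$values, 0))
  )
  class(out) <- "zea_pca"
  out
}

#' @exportS3Method print zea_pca
print.zea_pca <- function(x, ...) {
  cat(sprintf(
    "<zea_pca> %d samples; leading eigenvalues: %s\n",
    nrow(x$scores),
    paste(signif(head(x$eigenvalues, 3), 3), collapse = ", ")
  ))
  invisible(x)
}

#' Identity-by-state distance matrix
#'
#' For each pair of samples, distance = 1 - (mean over mutually non-missing
#' SNPs of the shared-allele count / 2). Shared alleles between dosages a, b
#' in \{0,1,2\} equal `2 - |a - b|`. Pairs with no mutually typed SNP are an
#' error.
#'
#' @param cohort a cohort (>= 2 samples).
#' @return symmetric numeric matrix with zero diagonal, entries in \[0, 1\].
#' @export
ibs_distance <- function(cohort) {
  stopifnot(is_cohort(cohort), n_samples(cohort) >= 2)
  d <- cohort$dosage
  M <- !is.na(d)
  dz <- d; dz[!M] <- 0
  A <- list(
    (dz == 0) & M,
    (dz == 1) & M,
    (dz == 2) & M
  )
  A <- lapply(A, function(x) {storage.mode(x) <- "double"; x})
  ## sum over SNPs of |a - b| for mutually typed pairs
  S <- A[[1]] %*% t(A[[2]]) + A[[2]] %*% t(A[[1]]) +
    A[[2]] %*% t(A[[3]]) + A[[3]] %*% t(A[[2]]) +
    2 * (A[[1]] %*% t(A[[3]]) + A[[3]] %*% t(A[[1]]))
  Md <- matrix(as.double(M), nrow = nrow(M))
  counts <- Md %*% t(Md)
  if (any(counts[upper.tri(counts)] == 0)) {
    stop("some sample pairs share no mutually non-missing SNP")
  }
  dist <- S / (2 * counts)
  diag(dist) <- 0
  dimnames(dist) <- list(rownames(d), rownames(d))
  dist
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via `ape::nj()`. Negative branch lengths are
#' clamped to zero (with a message giving the count). If an outgroup taxon
#' is supplied the tree is rooted on its pendant edge.
#'
#' @param dm symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @param outgroup optional taxon label to root on.
#' @return an `ape::phylo` tree; write it with [ape::write.tree()].
#' @export
nj_tree <- function(dm, outgroup = NULL) {
  dm <- as.matrix(dm)
  stopifnot(nrow(dm) >= 3, isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
  tree <- ape::nj(as.dist(dm))
  n_neg <- sum(tree$edge.length < 0)
  if (n_neg > 0) {
    message(n_neg, " negative branch length(s) clamped to 0")
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop("outgroup not among taxa: ", outgroup)
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  tree
}

#' Assign samples to groups from a Q matrix
#'
#' A sample is assigned to the cluster where its membership probability
#' reaches `threshold` (inclusive); samples below threshold in every cluster
#' get `mixed_label`. With more than two clusters and a threshold <= 0.5 a
#' tie is possible; ties break deterministically to the lowest cluster
#' index (with a message).
#'
#' @param q data frame: `sample` column plus one numeric membership column
#'   per cluster; each row must sum to 1 within 1e-6.
#' @param threshold assignment threshold (default 0.70, the study rule).
#' @param mixed_label label for unassigned samples.
#' @return tibble `sample`, `group`.
#' @export
#' @examples
#' q <- tibble::tibble(sample = c("a", "b"), trop = c(0.8, 0.6), temp = c(0.2, 0.4))
#' assign_groups(q)
assign_groups <- function(q, threshold = 0.70, mixed_label = "Mix") {
  q <- tibble::as_tibble(q)
  mem <- as.matrix(q[setdiff(names(q), "sample")])
  if (any(mem < 0 | mem > 1)) stop("memberships must lie in [0, 1]")
  if (any(abs(rowSums(mem) - 1) > 1e-6)) {
    stop("membership rows must sum to 1")
  }
  if (threshold <= 0.5 && ncol(mem) > 2) {
    warning("threshold <= 0.5 with >2 clusters: ties possible")
  }
  hit <- mem >= threshold
  n_tied <- sum(rowSums(hit) > 1)
  if (n_tied > 0) message(n_tied, " tie(s) broken to the lowest cluster index")
  pick <- apply(hit, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  tibble::tibble(
    sample = q$sample,
    group = ifelse(is.na(pick), mixed_label, colnames(mem)[pick])
  )
}
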