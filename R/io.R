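#' Read a phased VCF into a cohort
#'
#' Reads a VCFv4.2 file (plain or gzipped) via `vcfR`, keeping biallelic SNP
#' records only; multiallelic or non-SNP records are skipped and counted in
#' `attr(, "skipped")`. Phased genotypes (`|` separator) populate the
#' haplotype matrices; if any non-missing call is unphased the cohort is
#' marked unphased (haplotype-window analyses will refuse it). `./.` and `.`
#' become missing.
#'
#' @param path VCF file path.
#' @param groups optional tibble/data.frame `sample`, `group`; defaults to a
#'   single group `"all"`.
#' @return a [new_cohort()] object.
#' @export
read_vcf <- function(path, groups = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  ok <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!ok)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[ok, , drop = FALSE]
  fix <- fix[ok, , drop = FALSE]

  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  miss <- is.na(gt) | a1 == "." | a2 == "." | a2 == ""
  a1[miss] <- NA; a2[miss] <- NA
  phased <- all(sep[!miss] == "|")
  ## matrices arrive SNP x sample; cohort stores sample x SNP
  h1 <- t(matrix(as.integer(a1), nrow = nrow(gt)))
  h2 <- t(matrix(as.integer(a2), nrow = nrow(gt)))

  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  variants <- tibble::tibble(
    snp_id = ids,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref[ok], alt = alt[ok]
  )
  sample_ids <- colnames(gt)
  if (is.null(groups)) {
    groups <- tibble::tibble(sample = sample_ids, group = "all")
  } else {
    groups <- tibble::as_tibble(groups)
    groups <- groups[match(sample_ids, groups$sample), ]
    if (anyNA(groups$group)) stop("every VCF sample needs a group label")
  }
  dimnames(h1) <- dimnames(h2) <- list(sample_ids, variants$snp_id)
  out <- new_cohort(h1, h2, variants, groups, phased = phased)
  attr(out, "skipped") <- n_skipped
  out
}

#' Write a cohort and its companion files
#'
#' Emits a phased VCFv4.2 (`cohort.vcf.gz`, `GT` with `|` separators), a
#' sample-group TSV (`samples.tsv`, columns `sample`, `group`), a gene
#' annotation BED (`genes.bed`, random non-overlapping sorted intervals), a
#' GWAS-signal TSV (`signals.tsv`, columns `chrom`, `pos`, `trait`, one row
#' per causal SNP), and optionally a phenotype TSV (`phenotype.tsv`).
#'
#' @param cohort a cohort.
#' @param out_dir output directory (created if absent).
#' @param phenotype optional tibble from [simulate_phenotype()].
#' @param causal_snps optional character vector of causal SNP ids for
#'   `signals.tsv`; a `trait` attribute-free label is taken from `phenotype`
#'   or defaults to `"DTA"`.
#' @param n_genes,gene_length_bp number and length of random gene intervals
#'   per genome.
#' @param seed seed for the gene placement.
#' @return invisibly, a named list of the written paths.
#' @export
write_cohort <- function(cohort, out_dir, phenotype = NULL,
                         causal_snps = character(),
                         n_genes = 200, gene_length_bp = 5000, seed = 1) {
  stopifnot(is_cohort(cohort))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- list(
    vcf = file.path(out_dir, "cohort.vcf.gz"),
    samples = file.path(out_dir, "samples.tsv"),
    genes = file.path(out_dir, "genes.bed"),
    signals = file.path(out_dir, "signals.tsv")
  )

  ## --- VCF via vcfR ---
  v <- cohort$variants
  gt_chr <- matrix(
    paste0(
      ifelse(is.na(cohort$hap1), ".", cohort$hap1), "|",
      ifelse(is.na(cohort$hap2), ".", cohort$hap2)
    ),
    nrow = n_samples(cohort)
  )
  gt_chr[gt_chr == ".|."] <- ".|."
  gt <- cbind(FORMAT = "GT", t(gt_chr))
  colnames(gt) <- c("FORMAT", cohort$samples$sample)
  fix <- cbind(
    CHROM = v$chrom, POS = as.character(v$pos), ID = v$snp_id,
    REF = v$ref, ALT = v$alt, QUAL = ".", FILTER = "PASS", INFO = "."
  )
  truth <- attr(cohort, "truth")
  contigs <- unique(v$chrom)
  clen <- if (!is.null(truth)) truth$chrom_length_bp else NA
  meta <- c(
    "##fileformat=VCFv4.2",
    if (!is.na(clen)) sprintf("##contig=<ID=%s,length=%d>", contigs, clen)
    else sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = paths$vcf)

  write_tsv_plain(cohort$samples, paths$samples)

  ## --- random non-overlapping sorted genes ---
  glen <- if (!is.null(truth)) truth$chrom_length_bp else
    max(tapply(v$pos, v$chrom, max))
  set.seed(seed)
  per_chrom <- table(sample(contigs, n_genes, replace = TRUE))
  genes <- purrr::map_dfr(contigs, function(ch) {
    k <- per_chrom[ch]
    if (is.na(k) || k == 0) return(NULL)
    starts <- sort(sample.int(max(1, glen - gene_length_bp), k))
    keep <- c(TRUE, diff(starts) >= gene_length_bp)
    starts <- starts[keep]
    tibble::tibble(
      chrom = ch, start = starts, end = starts + gene_length_bp,
      name = sprintf("%s_gene%03d", ch, seq_along(starts))
    )
  })
  write_tsv_plain(genes, paths$genes, col_names = FALSE)

  ## --- GWAS-signal catalogue from causal SNPs ---
  trait <- if (!is.null(phenotype)) phenotype$trait[1] else "DTA"
  sig_idx <- match(causal_snps, v$snp_id)
  if (anyNA(sig_idx)) stop("causal SNP not found in cohort variants")
  signals <- tibble::tibble(
    chrom = v$chrom[sig_idx], pos = v$pos[sig_idx], trait = trait
  )
  write_tsv_plain(signals, paths$signals)

  if (!is.null(phenotype)) {
    paths$phenotype <- file.path(out_dir, "phenotype.tsv")
    write_tsv_plain(phenotype, paths$phenotype)
  }
  invisible(paths)
}

write_tsv_plain <- function(df, path, col_names = TRUE) {
  utils::write.table(
    df, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = col_names
  )
}

#' Read companion tables
#'
#' Small readers for the plain-text side files: sample groups
#' (`sample<TAB>group`), phenotypes (`sample trait value`), GWAS-signal
#' catalogues (`chrom pos trait`), and gene BED (3+name columns, 0-based
#' half-open).
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_sample_groups <- function(path) {
  tibble::as_tibble(utils::read.delim(path, colClasses = "character"))
}

#' @rdname read_sample_groups
#' @export
read_phenotype <- function(path) {
  tibble::as_tibble(utils::read.delim(path))
}

#' @rdname read_sample_groups
#' @export
read_signals <- function(path) {
  tibble::as_tibble(utils::read.delim(path))
}

#' @rdname read_sample_groups
#' @export
read_genes_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  tibble::as_tibble(df)
}
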