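# Genotype, phenotype and SNP-gene map input/output plus pre-processing:
# kNN imputation, population-structure correction, per-gene partitioning.

#' Construct a genotype matrix
#'
#' Genotypes are stored as a plain numeric matrix (samples x SNPs) with
#' additive coding: each entry counts copies of the coded allele (0, 1 or 2)
#' and `NA` marks a missing call.  Row names are sample identifiers, column
#' names SNP identifiers; both must be unique.
#'
#' @param values matrix-like, samples in rows, SNPs in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param sample_ids,snp_ids identifiers; default to the dimnames of `values`.
#' @return a numeric matrix with validated entries and dimnames.
#' @export
genotype_matrix <- function(values, sample_ids = rownames(values),
                            snp_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(snp_ids))
    stop("sample and SNP identifiers are required")
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (length(sample_ids) != nrow(values) || length(snp_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids)) stop("duplicated sample identifiers")
  if (anyDuplicated(snp_ids)) stop("duplicated SNP identifiers")
  .check_genotype_values(values)
  dimnames(values) <- list(sample_ids, snp_ids)
  values
}

.check_genotype_values <- function(values) {
  bad <- !(is.na(values) | values == 0 | values == 1 | values == 2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    rn <- rownames(values)[idx[1L]]; cn <- colnames(values)[idx[2L]]
    stop(sprintf(
      "genotype value %s at sample '%s', SNP '%s' is not in {0, 1, 2, NA}",
      format(values[idx[1L], idx[2L]]),
      if (is.null(rn)) idx[1L] else rn,
      if (is.null(cn)) idx[2L] else cn))
  }
  invisible(values)
}

#' Read an additive-coded genotype matrix
#'
#' Supports two dialects:
#' * `plink_raw`: whitespace-delimited PLINK `--recode A` output.  The six
#'   leading columns (`FID IID PAT MAT SEX PHENOTYPE`) are consumed (`IID`
#'   becomes the sample id) and SNP columns named `<snpid>_<allele>` are
#'   stripped to `<snpid>`.
#' * `tsv`: tab-separated, header row of SNP ids, first column sample ids.
#'
#' `NA` and `-9` cells become missing genotypes.
#'
#' @param path file path.
#' @param format `"plink_raw"` or `"tsv"`.
#' @return a genotype matrix (see [genotype_matrix()]).
#' @export
read_genotypes <- function(path, format = c("plink_raw", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  na_marks <- c("NA", "-9")
  if (format == "plink_raw") {
    dat <- utils::read.table(path, header = TRUE, sep = "",
                             stringsAsFactors = FALSE, check.names = FALSE,
                             na.strings = na_marks, colClasses = NA)
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(dat) < 7L || !identical(names(dat)[1:6], lead))
      stop("malformed PLINK RAW header: expected leading columns ",
           paste(lead, collapse = " "))
    snp_cols <- names(dat)[-(1:6)]
    snp_ids <- sub("_[ACGTDI]$", "", snp_cols)
    values <- as.matrix(dat[, -(1:6), drop = FALSE])
    sample_ids <- as.character(dat[["IID"]])
  } else {
    dat <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE,
                             na.strings = na_marks)
    if (ncol(dat) < 2L) stop("malformed TSV: need a sample column and >= 1 SNP")
    sample_ids <- as.character(dat[[1L]])
    values <- as.matrix(dat[, -1L, drop = FALSE])
    snp_ids <- names(dat)[-1L]
  }
  if (!is.numeric(values))
    stop("non-numeric genotype cells found; expected {0, 1, 2, NA}")
  genotype_matrix(values, sample_ids, snp_ids)
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotypes()].  The PLINK RAW dialect writes constant
#' placeholder pedigree columns and suffixes every SNP id with `_A`.
#'
#' @param g genotype matrix.
#' @param path output file.
#' @param format `"tsv"` or `"plink_raw"`.
#' @export
write_genotypes <- function(g, path, format = c("tsv", "plink_raw")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(sample = rownames(g), g, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(FID = rownames(g), IID = rownames(g), PAT = 0, MAT = 0,
                     SEX = 0, PHENOTYPE = -9, g, check.names = FALSE)
    names(df)[-(1:6)] <- paste0(colnames(g), "_A")
    utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a SNP-to-gene map
#'
#' A tab-separated table with columns `snp` and `gene` (optionally `chrom`,
#' `pos`; 1-based positions).  A SNP may map to several genes (eQTL maps are
#' many-to-many); it then contributes to each gene's block.
#'
#' @param path file path.
#' @return a data.frame with at least columns `snp` and `gene`.
#' @export
read_snp_gene_map <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("snp", "gene") %in% names(dat)))
    stop("SNP-gene map needs columns 'snp' and 'gene'")
  dat$snp <- as.character(dat$snp)
  dat$gene <- as.character(dat$gene)
  if (any(!nzchar(dat$gene))) stop("empty gene identifiers in map")
  dat
}

#' Phenotype vectors
#'
#' Phenotypes are named numeric vectors (names are sample ids) carrying a
#' `kind` attribute: `"raw"` for the observed trait (binary case/control or
#' quantitative) and `"corrected"` after population-structure correction.
#'
#' @param values numeric phenotype values.
#' @param sample_ids sample identifiers (defaults to `names(values)`).
#' @param kind `"raw"` or `"corrected"`.
#' @return a named numeric vector with a `kind` attribute.
#' @export
phenotype_vector <- function(values, sample_ids = names(values),
                             kind = c("raw", "corrected")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (is.null(sample_ids) || length(sample_ids) != length(values))
    stop("sample ids must match phenotype length")
  if (kind == "corrected" && anyNA(values))
    stop("corrected phenotypes cannot contain missing values")
  structure(values, names = as.character(sample_ids), kind = kind)
}

#' @rdname phenotype_vector
#' @param path TSV file with columns `sample` and `value`.
#' @export
read_phenotype <- function(path, kind = "raw") {
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample", "value") %in% names(dat)))
    stop("phenotype file needs columns 'sample' and 'value'")
  phenotype_vector(dat$value, dat$sample, kind = kind)
}

#' @rdname phenotype_vector
#' @param y phenotype vector to write.
#' @export
write_phenotype <- function(y, path) {
  utils::write.table(data.frame(sample = names(y), value = as.numeric(y)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pheno_kind <- function(y) {
  k <- attr(y, "kind")
  if (is.null(k)) "raw" else k
}

#' k-nearest-neighbour genotype imputation
#'
#' Fills missing genotype calls by a majority vote among the nearest samples.
#' The distance between two samples is the Euclidean distance over SNPs
#' observed in both, divided by the number of shared SNPs (so samples with
#' different missingness patterns are comparable).  For each missing call the
#' `k` nearest samples *with an observed genotype at that SNP* vote; the mode
#' wins, ties between genotype values resolve toward the smaller value, ties
#' in distance toward the earlier sample.
#'
#' @param g genotype matrix, possibly with `NA` entries.
#' @param k number of neighbours (default 10).
#' @return a complete genotype matrix; non-missing entries are untouched.
#' @export
knn_impute <- function(g, k = 10) {
  n <- nrow(g)
  if (k < 1) stop("k must be >= 1")
  if (k > n - 1) stop("k (", k, ") must be at most n - 1 = ", n - 1)
  miss <- is.na(g)
  if (!any(miss)) return(g)
  nobs_col <- colSums(!miss)
  if (any(nobs_col == 0L))
    stop("all genotypes missing for SNP(s): ",
         paste(colnames(g)[nobs_col == 0L], collapse = ", "))
  if (any(rowSums(!miss) == 0L))
    stop("sample(s) with no observed genotypes: ",
         paste(rownames(g)[rowSums(!miss) == 0L], collapse = ", "))

  M <- 1 - miss                      # observed indicator
  X0 <- g; X0[miss] <- 0
  shared <- tcrossprod(M)            # number of SNPs observed in both
  si <- tcrossprod(X0^2, M)          # sum over shared SNPs of x_i^2
  d2 <- si + t(si) - 2 * tcrossprod(X0)
  d2 <- d2 / shared
  d2[shared == 0] <- Inf

  out <- g
  for (j in which(colSums(miss) > 0L)) {
    obs <- which(!miss[, j])
    for (i in which(miss[, j])) {
      ord <- order(d2[i, obs])       # stable: earlier sample wins ties
      nn <- obs[ord[seq_len(min(k, length(obs)))]]
      tab <- tabulate(g[nn, j] + 1L, nbins = 3L)
      out[i, j] <- which.max(tab) - 1L   # first max: smaller genotype wins
    }
  }
  out
}

#' Correct a phenotype for population structure
#'
#' Regresses the raw phenotype on an intercept plus the top principal
#' components of the column-centered genotype matrix and returns the
#' residuals as a `"corrected"` phenotype.  A user-supplied covariate matrix
#' (e.g. externally computed ancestry PCs) overrides the internal PCA.
#'
#' @param y raw phenotype vector (see [phenotype_vector()]).
#' @param g complete genotype matrix on the same samples.
#' @param n_pcs number of genotype principal components (default 7).
#'   `n_pcs = 0` returns the mean-centered phenotype.
#' @param covariates optional numeric matrix of covariates replacing the PCs.
#' @return a corrected phenotype vector (residuals, mean ~ 0).
#' @export
correct_phenotype <- function(y, g, n_pcs = 7, covariates = NULL) {
  if (pheno_kind(y) != "raw")
    stop("phenotype is already corrected")
  if (anyNA(g)) stop("genotypes must be complete; run knn_impute() first")
  if (!is.null(names(y))) {
    if (!setequal(names(y), rownames(g)))
      stop("phenotype and genotype samples differ")
    y <- y[rownames(g)]
  } else if (length(y) != nrow(g)) {
    stop("phenotype length does not match number of samples")
  }
  yv <- as.numeric(y)
  if (is.null(covariates)) {
    if (n_pcs >= min(dim(g)))
      stop("n_pcs must be smaller than min(n samples, n SNPs)")
    Z <- if (n_pcs > 0)
      stats::prcomp(g, center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                        drop = FALSE]
    else NULL
  } else {
    Z <- as.matrix(covariates)
    if (nrow(Z) != nrow(g)) stop("covariate rows must match samples")
  }
  if (is.null(Z)) {
    res <- yv - mean(yv)
  } else {
    X <- cbind(1, Z)
    qx <- qr(X)
    if (qx$rank < ncol(X))
      stop("rank-deficient design; try fewer principal components")
    res <- as.numeric(stats::residuals(stats::lm.fit(X, yv)))
  }
  phenotype_vector(res, rownames(g), kind = "corrected")
}

#' Per-gene genotype blocks
#'
#' A gene block is the complete genotype submatrix of the SNPs mapped to one
#' gene, in the column order of the parent matrix.
#'
#' @param gene_id gene identifier.
#' @param values complete n x m genotype submatrix (m >= 1).
#' @return an object of class `gene_block`.
#' @export
gene_block <- function(gene_id, values) {
  if (anyNA(values)) stop("gene block must be complete")
  structure(list(gene_id = as.character(gene_id),
                 snp_ids = colnames(values),
                 sample_ids = rownames(values),
                 values = values),
            class = "gene_block")
}

#' @export
print.gene_block <- function(x, ...) {
  cat(sprintf("<gene_block> %s: %d samples x %d SNPs\n",
              x$gene_id, nrow(x$values), length(x$snp_ids)))
  invisible(x)
}

#' Partition a genotype matrix into per-gene blocks
#'
#' Genes with fewer than `min_snps` mapped SNPs present in the matrix are
#' reported via [message()] and dropped; the default threshold of 3 restricts
#' the kernel stage to genes with three or more SNPs.  SNPs mapped to several
#' genes appear in each of their genes' blocks.
#'
#' @param g complete genotype matrix.
#' @param map SNP-gene map (data.frame with columns `snp`, `gene`).
#' @param min_snps minimum number of SNPs per retained gene (default 3).
#' @return a named list of [gene_block()] objects.
#' @export
partition_by_gene <- function(g, map, min_snps = 3) {
  if (anyNA(g)) stop("genotypes must be complete; run knn_impute() first")
  keep <- map$snp %in% colnames(g)
  if (!any(keep))
    stop("no SNP in the map is present in the genotype matrix")
  sp <- split(map$snp[keep], map$gene[keep])
  blocks <- list()
  dropped <- character()
  for (gene in names(sp)) {
    snps <- colnames(g)[colnames(g) %in% unique(sp[[gene]])]
    if (length(snps) < min_snps) {
      dropped <- c(dropped, gene)
    } else {
      blocks[[gene]] <- gene_block(gene, g[, snps, drop = FALSE])
    }
  }
  if (length(dropped))
    message("dropped ", length(dropped), " gene(s) with fewer than ",
            min_snps, " SNPs: ", paste(dropped, collapse = ", "))
  if (!length(blocks))
    stop("no gene retained at min_snps = ", min_snps)
  blocks
}
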