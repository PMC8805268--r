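# Phenotype discretization and information-theoretic synergy between SNPs.
# All entropies are plug-in (maximum likelihood) estimates, base-2 by default.

#' Discretize a corrected phenotype
#'
#' Equal-width binning of the population-structure-corrected phenotype; a
#' discrete phenotype is required by the plug-in entropy estimators.  With
#' `n_bins = "auto"` the number of bins is `round(n^(1/3))` (cube-root rule).
#' The maximum value is assigned to the last bin.  A k-means alternative is
#' available through [discretize_phenotype()].
#'
#' @param y corrected phenotype vector.
#' @param n_bins number of bins (>= 2) or `"auto"`.
#' @return an object of class `discrete_pheno` with elements `labels`
#'   (integers 1..B, named by sample), `n_bins`, and `edges` (B + 1 breaks).
#' @export
discretize_equal_width <- function(y, n_bins = "auto") {
  n <- length(y)
  if (identical(n_bins, "auto")) n_bins <- max(2L, as.integer(round(n^(1 / 3))))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (n < n_bins) stop("need at least n_bins observations")
  rng <- range(y)
  if (diff(rng) == 0)
    stop("phenotype is constant: equal-width bins would have zero width")
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  labels <- findInterval(y, edges, rightmost.closed = TRUE, all.inside = TRUE)
  structure(list(labels = stats::setNames(as.integer(labels), names(y)),
                 n_bins = n_bins, edges = edges),
            class = "discrete_pheno")
}

#' @rdname discretize_equal_width
#'
#' @details `discretize_phenotype()` dispatches on `method`; `"kmeans"` runs
#'   one-dimensional k-means (deterministically initialised at equal-width
#'   bin centers) and labels bins in increasing center order.  A raw binary
#'   phenotype is passed through unchanged (classes become the two bins).
#'
#' @param method `"equal_width"` (default) or `"kmeans"`.
#' @export
discretize_phenotype <- function(y, n_bins = "auto",
                                 method = c("equal_width", "kmeans")) {
  method <- match.arg(method)
  if (pheno_kind(y) == "raw" && all(y %in% c(0, 1))) {
    return(structure(list(labels = stats::setNames(as.integer(y) + 1L,
                                                   names(y)),
                          n_bins = 2L, edges = c(-0.5, 0.5, 1.5)),
                     class = "discrete_pheno"))
  }
  if (method == "equal_width") return(discretize_equal_width(y, n_bins))
  n <- length(y)
  if (identical(n_bins, "auto")) n_bins <- max(2L, as.integer(round(n^(1 / 3))))
  rng <- range(y)
  if (diff(rng) == 0) stop("phenotype is constant")
  centers0 <- seq(rng[1L], rng[2L], length.out = 2L * n_bins + 1L)[2L * seq_len(n_bins)]
  km <- stats::kmeans(as.numeric(y), centers = matrix(centers0, ncol = 1))
  ord <- order(km$centers[, 1L])
  relab <- match(seq_len(n_bins), ord)
  labels <- relab[km$cluster]
  cuts <- (sort(km$centers[, 1L])[-n_bins] + sort(km$centers[, 1L])[-1L]) / 2
  structure(list(labels = stats::setNames(as.integer(labels), names(y)),
                 n_bins = as.integer(n_bins),
                 edges = c(rng[1L], cuts, rng[2L])),
            class = "discrete_pheno")
}

#' @export
print.discrete_pheno <- function(x, ...) {
  cat(sprintf("<discrete_pheno> %d samples in %d bins\n",
              length(x$labels), x$n_bins))
  invisible(x)
}

.joint_code <- function(a, b) {
  # integer coding of the Cartesian product of two discrete vectors
  ai <- match(a, unique(a))
  bi <- match(b, unique(b))
  ai + (bi - 1L) * max(ai)
}

#' Shannon entropy of a discrete vector
#'
#' Plug-in estimate `H = sum_c p(c) log(1/p(c))` with empirical frequencies;
#' empty cells contribute zero.
#'
#' @param x discrete vector (any atomic type).
#' @param base logarithm base; 2 (bits) by default.
#' @return entropy in units of `log(base)`.
#' @export
entropy <- function(x, base = 2) {
  if (!length(x)) stop("empty input")
  p <- tabulate(match(x, unique(x)))
  p <- p / sum(p)
  -sum(p * log(p)) / log(base)
}

#' Conditional entropy H(X | A)
#'
#' `H(X|A) = sum_{a,x} p(a,x) log(1/p(x|a)) = H(X,A) - H(A)`.
#'
#' @param x discrete outcome vector.
#' @param given discrete conditioning vector of the same length.
#' @inheritParams entropy
#' @export
conditional_entropy <- function(x, given, base = 2) {
  if (length(x) != length(given)) stop("length mismatch")
  entropy(.joint_code(x, given), base) - entropy(given, base)
}

#' Information gain (mutual information) I(X; C)
#'
#' `I(X;C) = H(C) - H(C|X)`.  `x` may be a single discrete vector or a pair
#' (two-column matrix / data.frame, or list of two vectors); a pair is coded
#' as its Cartesian product, giving the joint information `I(A,B;C)`.
#'
#' @param x predictor: discrete vector or pair of vectors.
#' @param c discrete outcome vector.
#' @inheritParams entropy
#' @export
information_gain <- function(x, c, base = 2) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) == 2L)
    x <- .joint_code(x[[1L]], x[[2L]])
  } else if (is.matrix(x)) {
    stopifnot(ncol(x) == 2L)
    x <- .joint_code(x[, 1L], x[, 2L])
  } else if (is.list(x)) {
    stopifnot(length(x) == 2L)
    x <- .joint_code(x[[1L]], x[[2L]])
  }
  if (length(x) != length(c)) stop("length mismatch")
  entropy(c, base) - conditional_entropy(c, x, base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bivariate synergy between two SNPs and a phenotype
#'
#' `Syn(A;B;C) = I(A,B;C) - [I(A;C) + I(B;C)]`: the information the SNP pair
#' carries about the phenotype beyond the sum of the individual
#' contributions.  Positive values indicate synergy (e.g. XOR-like
#' epistasis), negative values redundancy (e.g. SNPs in LD).
#'
#' @param a,b discrete genotype vectors.
#' @param c discrete phenotype vector.
#' @inheritParams entropy
#' @export
synergy <- function(a, b, c, base = 2) {
  if (length(a) != length(c) || length(b) != length(c))
    stop("length mismatch")
  information_gain(list(a, b), c, base) -
    information_gain(a, c, base) - information_gain(b, c, base)
}

#' Within-gene synergy matrix
#'
#' Computes the symmetric m x m matrix of bivariate synergies between all SNP
#' pairs of a gene block; the diagonal is zero.  This matrix is the weighted
#' adjacency of the within-gene SNP graph.
#'
#' @param block a [gene_block()].
#' @param c a `discrete_pheno` (or integer label vector) aligned with the
#'   block's samples.
#' @inheritParams entropy
#' @return an m x m matrix of class `synergy_matrix` with `gene_id` attribute.
#' @export
synergy_matrix <- function(block, c, base = 2) {
  labels <- if (inherits(c, "discrete_pheno")) c$labels else c
  if (!is.null(names(labels)) && !is.null(block$sample_ids)) {
    if (!setequal(names(labels), block$sample_ids))
      stop("samples of phenotype and gene block differ")
    labels <- labels[block$sample_ids]
  } else if (length(labels) != nrow(block$values)) {
    stop("misaligned samples")
  }
  G <- block$values
  m <- ncol(G)
  S <- matrix(0, m, m, dimnames = list(colnames(G), colnames(G)))
  if (m >= 2L) {
    ig1 <- vapply(seq_len(m), function(j)
      information_gain(G[, j], labels, base), numeric(1))
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        s <- information_gain(list(G[, i], G[, j]), labels, base) -
          ig1[i] - ig1[j]
        S[i, j] <- S[j, i] <- s
      }
    }
  }
  structure(S, class = c("synergy_matrix", "matrix"),
            gene_id = block$gene_id)
}

#' Write / read per-gene synergy matrices
#'
#' One TSV per gene (SNP x SNP with header row and first column of SNP ids)
#' plus a manifest TSV mapping `gene` to `path`.
#'
#' @param mats named list of `synergy_matrix` objects.
#' @param dir output directory (created if needed).
#' @return path of the manifest file.
#' @export
write_synergy_dir <- function(mats, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(mats))
  for (i in seq_along(mats)) {
    gene <- attr(mats[[i]], "gene_id") %||% names(mats)[i]
    paths[i] <- file.path(dir, paste0(gene, "_synergy.tsv"))
    df <- data.frame(snp = rownames(mats[[i]]), unclass(mats[[i]]),
                     check.names = FALSE)
    utils::write.table(df, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(data.frame(gene = names(mats), path = basename(paths)),
                     manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_synergy_dir
#' @export
read_synergy_dir <- function(dir) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(man))) {
    df <- utils::read.table(file.path(dir, man$path[i]), header = TRUE,
                            sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    out[[man$gene[i]]] <- structure(m, class = c("synergy_matrix", "matrix"),
                                    gene_id = man$gene[i])
  }
  out
}
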