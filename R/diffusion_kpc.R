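# Diffusion kernels on the within-gene synergy graph and kernel-PCA gene
# summaries.  All matrix exponentials go through one symmetric
# eigendecomposition of the Laplacian, re-used across the whole beta grid.

#' Graph Laplacian of a synergy matrix
#'
#' Off-diagonal entries equal the synergy weights, the diagonal is the
#' negative row sum, so every row sums to zero.  (With positive weights this
#' is the negative of the combinatorial Laplacian; its matrix exponential is
#' the diffusion/heat kernel.)
#'
#' @param s symmetric synergy matrix with zero diagonal.
#' @return an m x m matrix with `gene_id` attribute.
#' @export
graph_laplacian <- function(s) {
  W <- unclass(s)
  if (!isSymmetric(W, tol = 1e-10)) stop("synergy matrix must be symmetric")
  L <- W
  diag(L) <- 0
  diag(L) <- -rowSums(L)
  structure(L, gene_id = attr(s, "gene_id"))
}

#' Diffusion kernel of a Laplacian
#'
#' `K = exp(beta * L)` via symmetric eigendecomposition
#' (`V diag(exp(beta * lambda)) V'`), which is exact for symmetric `L` and
#' always symmetric positive definite.  `beta = 0` returns the identity
#' matrix exactly.
#'
#' @param L symmetric Laplacian matrix.
#' @param beta diffusion strength, `beta >= 0`.
#' @return an m x m symmetric positive-definite matrix.
#' @export
diffusion_kernel <- function(L, beta) {
  if (beta < 0) stop("beta must be >= 0")
  m <- ncol(L)
  if (beta == 0) {
    K <- diag(m)
    dimnames(K) <- dimnames(L)
  } else {
    e <- eigen(L, symmetric = TRUE)
    K <- e$vectors %*% (exp(beta * e$values) * t(e$vectors))
    K <- (K + t(K)) / 2
    dimnames(K) <- dimnames(L)
  }
  if (any(!is.finite(K))) stop("non-finite entries in diffusion kernel")
  structure(K, gene_id = attr(L, "gene_id"), beta = beta)
}

#' Default diffusion-strength grid
#'
#' 101 values from 0 to 10 in steps of 0.1.
#'
#' @param from,to,by grid limits and step.
#' @export
default_beta_grid <- function(from = 0, to = 10, by = 0.1) seq(from, to, by = by)

#' Grid-averaged diffusion kernel
#'
#' Elementwise mean of `exp(beta * L)` over a grid of diffusion strengths.
#' Averaging lets each gene's own graph structure decide how far information
#' diffuses instead of committing to a single `beta`.  One eigendecomposition
#' serves the whole grid.  A grid containing only zeros returns the identity
#' exactly.
#'
#' @param L symmetric Laplacian matrix.
#' @param beta_grid non-empty vector of `beta >= 0`
#'   (default [default_beta_grid()], 101 values).
#' @return an m x m symmetric positive-definite matrix.
#' @export
averaged_kernel <- function(L, beta_grid = default_beta_grid()) {
  if (!length(beta_grid)) stop("beta grid must be non-empty")
  if (any(beta_grid < 0)) stop("beta values must be >= 0")
  m <- ncol(L)
  if (all(beta_grid == 0)) {
    K <- diag(m)
    dimnames(K) <- dimnames(L)
  } else {
    e <- eigen(L, symmetric = TRUE)
    avg <- rowMeans(exp(outer(e$values, beta_grid)))
    K <- e$vectors %*% (avg * t(e$vectors))
    K <- (K + t(K)) / 2
    dimnames(K) <- dimnames(L)
  }
  if (any(!is.finite(K))) stop("non-finite entries in averaged kernel")
  structure(K, gene_id = attr(L, "gene_id"), beta_grid = beta_grid)
}

#' Gene-specific sample ("sandwich") kernel
#'
#' `K = G K_L G'` with `G` the n x m genotype block and `K_L` the (averaged)
#' diffusion kernel: an n x n similarity between individuals that blends
#' gene-level genotype similarity with the joint SNP-phenotype structure
#' encoded in the synergy graph.  With `K_L = I` it reduces to the plain
#' genotype Gram matrix.
#'
#' @param block a [gene_block()] whose SNP order matches `kl`.
#' @param kl m x m diffusion kernel.
#' @param center_genotypes if `TRUE`, column-center `G` first (default keeps
#'   the raw 0/1/2 coding; the kernel centering downstream removes sample
#'   mean effects either way).
#' @return an n x n symmetric positive-semidefinite matrix with attributes
#'   `gene_id` and `centered = FALSE`.
#' @export
sandwich_kernel <- function(block, kl, center_genotypes = FALSE) {
  G <- block$values
  if (ncol(G) != ncol(kl)) stop("dimension mismatch between block and kernel")
  if (!is.null(colnames(kl)) && !identical(colnames(G), colnames(kl)))
    stop("SNP order of block and kernel differ")
  if (center_genotypes) G <- scale(G, center = TRUE, scale = FALSE)
  K <- G %*% unclass(kl) %*% t(G)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(G), rownames(G))
  structure(K, gene_id = block$gene_id, centered = FALSE)
}

#' Double-center a sample kernel
#'
#' `K' = H K H` with `H = I - (1/n) 1 1'`: the feature-space centering
#' required before kernel PCA.  Row and column sums of the result are ~ 0.
#' Calling it on an already centered kernel is a no-op with a warning.
#'
#' @param k sample kernel from [sandwich_kernel()].
#' @return the centered kernel (attribute `centered = TRUE`).
#' @export
center_kernel <- function(k) {
  if (isTRUE(attr(k, "centered"))) {
    warning("kernel is already centered; returning unchanged")
    return(k)
  }
  K <- unclass(k)
  rm_ <- rowMeans(K)
  gm <- mean(K)
  K <- K - outer(rm_, rep(1, ncol(K))) - outer(rep(1, nrow(K)), rm_) + gm
  K <- (K + t(K)) / 2
  structure(K, gene_id = attr(k, "gene_id"), centered = TRUE,
            dimnames = dimnames(k))
}

#' First kernel principal component of a gene
#'
#' Leading eigenpair of the centered sample kernel; the per-individual score
#' vector is `sqrt(lambda_1) * v_1` (so its squared norm equals the leading
#' eigenvalue).  The sign is fixed so that the largest-magnitude score is
#' positive.  For kernels up to `dense_n` rows a dense symmetric
#' eigendecomposition is used; above that a deflation-free power iteration
#' extracts only the top eigenpair.
#'
#' @param k centered sample kernel.
#' @param dense_n threshold for the dense solver (default 2000).
#' @return an object of class `gene_summary`: list with `gene_id`,
#'   `sample_ids`, `scores` (named numeric) and `eigenvalue`.
#' @export
first_kpc <- function(k, dense_n = 2000) {
  if (!isTRUE(attr(k, "centered")))
    stop("kernel must be centered first (center_kernel())")
  K <- unclass(k)
  n <- nrow(K)
  gene <- attr(k, "gene_id") %||% "?"
  if (n <= dense_n) {
    e <- eigen(K, symmetric = TRUE)
    lambda <- e$values[1L]
    v <- e$vectors[, 1L]
  } else {
    v <- rowSums(K)
    if (sqrt(sum(v^2)) < .Machine$double.eps) v <- K[, 1L]
    v <- v / sqrt(sum(v^2))
    lambda <- 0
    for (it in seq_len(1000L)) {
      w <- K %*% v
      lam_new <- sqrt(sum(w^2))
      if (lam_new == 0) break
      w <- w / lam_new
      if (max(abs(w - v)) < 1e-12 || max(abs(w + v)) < 1e-12) {
        v <- w; lambda <- lam_new; break
      }
      v <- w; lambda <- lam_new
    }
    lambda <- as.numeric(t(v) %*% K %*% v)
    v <- as.numeric(v)
  }
  if (lambda <= 0)
    stop("degenerate kernel for gene '", gene,
         "': leading eigenvalue is not positive")
  scores <- sqrt(lambda) * v
  if (scores[which.max(abs(scores))] < 0) scores <- -scores
  structure(list(gene_id = gene,
                 sample_ids = rownames(K),
                 scores = stats::setNames(as.numeric(scores), rownames(K)),
                 eigenvalue = lambda),
            class = "gene_summary")
}

#' @export
print.gene_summary <- function(x, ...) {
  cat(sprintf("<gene_summary> %s: %d samples, leading eigenvalue %.4g\n",
              x$gene_id, length(x$scores), x$eigenvalue))
  invisible(x)
}

#' Summarise one gene end to end
#'
#' Convenience wrapper: synergy matrix -> Laplacian -> grid-averaged
#' diffusion kernel -> sandwich kernel -> centering -> first kernel PC.
#'
#' @param block a [gene_block()].
#' @param dpheno a `discrete_pheno` aligned with the block.
#' @param beta_grid diffusion-strength grid (default 101 values 0..10).
#' @param base logarithm base for the synergy computation.
#' @param center_genotypes passed to [sandwich_kernel()].
#' @return a `gene_summary`.
#' @export
summarize_gene <- function(block, dpheno, beta_grid = default_beta_grid(),
                           base = 2, center_genotypes = FALSE) {
  s <- synergy_matrix(block, dpheno, base = base)
  kl <- averaged_kernel(graph_laplacian(s), beta_grid)
  k <- center_kernel(sandwich_kernel(block, kl,
                                     center_genotypes = center_genotypes))
  first_kpc(k)
}

#' Summarise all genes
#'
#' @param blocks named list of gene blocks (see [partition_by_gene()]).
#' @inheritParams summarize_gene
#' @return a list with `summaries` (list of `gene_summary`), `scores`
#'   (n x p matrix, one column per gene) and `eigenvalues` (named vector).
#' @export
summarize_genes <- function(blocks, dpheno, beta_grid = default_beta_grid(),
                            base = 2, center_genotypes = FALSE) {
  summaries <- lapply(blocks, summarize_gene, dpheno = dpheno,
                      beta_grid = beta_grid, base = base,
                      center_genotypes = center_genotypes)
  scores <- vapply(summaries, function(s) s$scores,
                   numeric(length(summaries[[1L]]$scores)))
  rownames(scores) <- summaries[[1L]]$sample_ids
  list(summaries = summaries, scores = scores,
       eigenvalues = vapply(summaries, `[[`, numeric(1), "eigenvalue"))
}

#' Write gene summaries
#'
#' The score matrix (rows = samples, columns = genes) as one TSV - the design
#' matrix of the interaction model - plus a per-gene eigenvalue manifest.
#'
#' @param gs result of [summarize_genes()].
#' @param path output TSV for the scores.
#' @param eigen_path optional TSV for the eigenvalues.
#' @export
write_gene_summaries <- function(gs, path, eigen_path = NULL) {
  df <- data.frame(sample = rownames(gs$scores), gs$scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(eigen_path))
    utils::write.table(data.frame(gene = names(gs$eigenvalues),
                                  eigenvalue = as.numeric(gs$eigenvalues)),
                       eigen_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_summaries
#' @export
read_gene_summaries <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
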