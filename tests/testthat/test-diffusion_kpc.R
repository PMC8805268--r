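test_that("the Laplacian has synergy off-diagonals and zero row sums", {
  W <- as_synergy(matrix(c(0, 2, 2, 0), 2, 2))
  L <- graph_laplacian(W)
  expect_equal(unname(unclass(L)), matrix(c(-2, 2, 2, -2), 2, 2),
               ignore_attr = TRUE)
  expect_equal(unclass(graph_laplacian(as_synergy(matrix(0, 3, 3)))),
               matrix(0, 3, 3), ignore_attr = TRUE)
  withr::local_seed(79)
  W5 <- as_synergy(rand_symmetric(5))
  L5 <- graph_laplacian(W5)
  expect_lt(max(abs(rowSums(L5))), 1e-12)
  off <- upper.tri(L5)
  expect_equal(unclass(L5)[off], unclass(W5)[off])
  expect_error(graph_laplacian(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("diffusion kernels match closed forms and the Taylor oracle", {
  # beta = 0 is exactly the identity
  withr::local_seed(83)
  L <- graph_laplacian(as_synergy(rand_symmetric(4)))
  expect_equal(unname(unclass(diffusion_kernel(L, 0))), diag(4),
               ignore_attr = TRUE)
  expect_true(all(unclass(diffusion_kernel(L, 0)) == diag(4)))
  # two-node closed form: eigenvalues 0 and -2w
  L2 <- graph_laplacian(as_synergy(matrix(c(0, 1, 1, 0), 2, 2)))
  K2 <- diffusion_kernel(L2, 1)
  expect_equal(unname(unclass(K2)),
               matrix(c((1 + exp(-2)) / 2, (1 - exp(-2)) / 2,
                        (1 - exp(-2)) / 2, (1 + exp(-2)) / 2), 2, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # Taylor-series oracle at small beta
  for (rep in 1:5) {
    m <- sample(3:10, 1)
    Lr <- graph_laplacian(as_synergy(rand_symmetric(m, scale = 0.5)))
    beta <- runif(1, 0.01, 0.5)
    expect_equal(unclass(diffusion_kernel(Lr, beta)),
                 o_expm_taylor(unclass(Lr), beta), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("diffusion kernels are symmetric positive definite on the grid", {
  withr::local_seed(89)
  L <- graph_laplacian(as_synergy(rand_symmetric(6, scale = 0.3)))
  for (beta in c(0, 0.1, 0.5, 1, 5, 10)) {
    K <- diffusion_kernel(L, beta)
    expect_true(isSymmetric(unclass(K)))
    expect_gt(min(eigen(unclass(K), symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("the averaged kernel is the elementwise grid mean", {
  withr::local_seed(97)
  L <- graph_laplacian(as_synergy(rand_symmetric(4, scale = 0.3)))
  grid <- default_beta_grid()
  expect_length(grid, 101L)
  direct <- Reduce(`+`, lapply(grid, function(b)
    unclass(diffusion_kernel(L, b)))) / length(grid)
  expect_equal(unclass(averaged_kernel(L, grid)), direct, tolerance = 1e-12,
               ignore_attr = TRUE)
  # single-beta grid collapses to the plain kernel
  expect_equal(unclass(averaged_kernel(L, 0.7)),
               unclass(diffusion_kernel(L, 0.7)), tolerance = 1e-13,
               ignore_attr = TRUE)
  # zero grid / zero Laplacian give the identity
  expect_true(all(unclass(averaged_kernel(L, 0)) == diag(4)))
  L0 <- graph_laplacian(as_synergy(matrix(0, 3, 3)))
  expect_equal(unname(unclass(averaged_kernel(L0, c(0, 1, 2)))), diag(3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(averaged_kernel(L, numeric(0)), "non-empty")
})

test_that("the sandwich kernel reduces correctly in its two limits", {
  withr::local_seed(101)
  # G = identity: K equals the diffusion kernel
  m <- 4
  L <- graph_laplacian(as_synergy(rand_symmetric(m, scale = 0.3)))
  kl <- diffusion_kernel(L, 0.5)
  eye <- diag(m)
  dimnames(eye) <- list(sprintf("s%02d", 1:m), colnames(kl))
  bI <- gene_block("g", eye)
  expect_equal(unclass(sandwich_kernel(bI, kl)), unclass(kl),
               tolerance = 1e-12, ignore_attr = TRUE)
  # K_L = identity: K is the genotype Gram matrix
  blk <- rand_block(30, 5)
  idk <- diag(5); dimnames(idk) <- list(blk$snp_ids, blk$snp_ids)
  expect_equal(unclass(sandwich_kernel(blk, idk)),
               tcrossprod(blk$values), tolerance = 1e-12, ignore_attr = TRUE)
  # random case: symmetric PSD
  kl5 <- diffusion_kernel(graph_laplacian(as_synergy(rand_symmetric(5))), 1)
  K <- sandwich_kernel(blk, kl5)
  expect_true(isSymmetric(unclass(K)))
  ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(abs(ev)))
})

test_that("kernel centering zeroes row sums and is idempotent", {
  n <- 12
  ones <- matrix(1, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  K1 <- structure(ones, centered = FALSE)
  expect_lt(max(abs(center_kernel(K1))), 1e-12)
  withr::local_seed(103)
  A <- matrix(rnorm(n * 20), n)
  K <- structure(tcrossprod(A), centered = FALSE,
                 dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  Kc <- center_kernel(K)
  expect_lt(max(abs(rowSums(Kc))), 1e-8)
  expect_lt(max(abs(colSums(Kc))), 1e-8)
  # centering a centered kernel warns and returns it unchanged
  expect_warning(Kc2 <- center_kernel(Kc), "already centered")
  expect_identical(Kc2, Kc)
  # an algebraically centered input is numerically unchanged
  H <- diag(n) - 1 / n
  Kc3 <- structure(H %*% unclass(K) %*% H, centered = FALSE,
                   dimnames = dimnames(K))
  expect_equal(unclass(center_kernel(Kc3)), unclass(Kc3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the first kernel PC matches a dense eigendecomposition", {
  withr::local_seed(107)
  n <- 50
  # rank-1 kernel: exact eigenpair
  v <- rnorm(n); v <- v - mean(v); v <- v / sqrt(sum(v^2))
  c0 <- 4.2
  K1 <- structure(c0 * tcrossprod(v), centered = TRUE,
                  dimnames = list(paste0("s", 1:n), paste0("s", 1:n)),
                  gene_id = "g1")
  s1 <- first_kpc(K1)
  expect_equal(s1$eigenvalue, c0, tolerance = 1e-10)
  want <- sqrt(c0) * v
  if (want[which.max(abs(want))] < 0) want <- -want
  expect_equal(unname(s1$scores), want, tolerance = 1e-8)
  # random PSD kernel: agree with eigen()
  A <- matrix(rnorm(n * n), n)
  K <- tcrossprod(A)
  H <- diag(n) - 1 / n
  K <- H %*% K %*% H
  Kc <- structure((K + t(K)) / 2, centered = TRUE,
                  dimnames = list(paste0("s", 1:n), paste0("s", 1:n)),
                  gene_id = "g2")
  s <- first_kpc(Kc)
  e <- eigen(unclass(Kc), symmetric = TRUE)
  expect_equal(s$eigenvalue, e$values[1], tolerance = 1e-10)
  expect_equal(abs(sum(s$scores * e$vectors[, 1])), sqrt(e$values[1]),
               tolerance = 1e-8)
  expect_equal(sum(s$scores^2), s$eigenvalue, tolerance = 1e-8)
  # the power-iteration path agrees with the dense path
  sp <- first_kpc(Kc, dense_n = 10)
  expect_equal(sp$eigenvalue, s$eigenvalue, tolerance = 1e-8)
  expect_equal(unname(sp$scores), unname(s$scores), tolerance = 1e-6)
  # degenerate kernels are rejected by gene name
  K0 <- structure(matrix(0, 4, 4), centered = TRUE, gene_id = "bad",
                  dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  expect_error(first_kpc(K0), "bad")
  expect_error(first_kpc(structure(diag(3), centered = FALSE)), "centered")
})

test_that("a zero-diffusion grid reproduces classical PCA gene scores", {
  withr::local_seed(109)
  blk <- rand_block(40, 6)
  dp <- discretize_equal_width(
    phenotype_vector(rnorm(40), rownames(blk$values), kind = "corrected"), 4)
  gs <- summarize_gene(blk, dp, beta_grid = 0)
  pc <- stats::prcomp(blk$values, center = TRUE, scale. = FALSE)
  want <- pc$x[, 1]
  if (want[which.max(abs(want))] < 0) want <- -want
  expect_equal(unname(gs$scores), unname(want), tolerance = 1e-8)
})

test_that("grid averaging commutes with the sandwich product", {
  withr::local_seed(113)
  blk <- rand_block(25, 4)
  L <- graph_laplacian(as_synergy(rand_symmetric(4, scale = 0.4)))
  dimnames(L) <- list(blk$snp_ids, blk$snp_ids)
  grid <- c(0, 0.5, 1.5)
  k_avg <- sandwich_kernel(blk, averaged_kernel(L, grid))
  per_beta <- Reduce(`+`, lapply(grid, function(b)
    unclass(sandwich_kernel(blk, diffusion_kernel(L, b))))) / length(grid)
  expect_equal(unclass(k_avg), per_beta, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("gene summaries are equivariant under sample permutation", {
  withr::local_seed(127)
  blk <- rand_block(30, 5)
  dp <- discretize_equal_width(
    phenotype_vector(rnorm(30), rownames(blk$values), kind = "corrected"), 3)
  s1 <- summarize_gene(blk, dp, beta_grid = c(0, 1))
  perm <- sample(30)
  blk2 <- gene_block(blk$gene_id, blk$values[perm, ])
  dp2 <- dp; dp2$labels <- dp$labels[perm]
  s2 <- summarize_gene(blk2, dp2, beta_grid = c(0, 1))
  expect_equal(unname(s2$scores), unname(s1$scores[perm]), tolerance = 1e-8)
})

test_that("gene summary tables round-trip to TSV", {
  withr::local_seed(131)
  cfg <- simulation_config(n = 40, n_genes = 3, snps_per_gene = 4,
                           missing_rate = 0, seed = 5)
  st <- simulate_study(cfg)
  yc <- correct_phenotype(st$phenotype, st$genotypes, n_pcs = 2)
  dp <- discretize_phenotype(yc, 3)
  blocks <- partition_by_gene(st$genotypes, st$map)
  gs <- summarize_genes(blocks, dp, beta_grid = c(0, 0.5))
  expect_identical(dim(gs$scores), c(40L, 3L))
  dir <- withr::local_tempdir()
  write_gene_summaries(gs, file.path(dir, "scores.tsv"),
                       file.path(dir, "eigen.tsv"))
  back <- read_gene_summaries(file.path(dir, "scores.tsv"))
  expect_equal(back, gs$scores, tolerance = 1e-6)
})
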