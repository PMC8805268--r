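# Synthetic GWAS studies with known ground truth: LD-structured genotypes
# grouped into genes, a confounded quantitative phenotype with planted main
# and epistatic effects, and missing calls at a low rate.

#' Simulation configuration
#'
#' Genotypes follow a latent-Gaussian haplotype model: per gene, each of two
#' haplotypes is drawn from an AR(`ld_rho`) correlated Gaussian across the
#' gene's SNPs and thresholded at each SNP's minor-allele-frequency quantile;
#' the genotype is the haplotype sum.  The phenotype adds centered main
#' effects, centered pairwise epistatic effects (`product`: genotype product;
#' `xor_penetrance`: indicator of exactly one carrier), a confounder
#' proportional to the first genotype principal component, and Gaussian
#' noise.
#'
#' Defaults describe a desk-scale study: 500 individuals, 20 genes of 8 SNPs
#' each, MAFs in (0.1, 0.4), moderate within-gene LD (`ld_rho = 0.7`,
#' typical of eQTL SNP sets after r^2-based pruning), confounder and noise
#' standard deviations 0.5 and 1, and 0.1% missing calls (the order of
#' magnitude seen in post-QC GWAS data).
#'
#' @param n number of individuals.
#' @param n_genes number of genes.
#' @param snps_per_gene SNPs per gene (single value or one per gene).
#' @param maf_range minor-allele-frequency range, inside (0.05, 0.5).
#' @param ld_rho within-gene latent AR correlation in `[0, 1)`.
#' @param main_effects list of `list(gene =, effect =)` entries.
#' @param epistasis_pairs list of `list(gene1 =, gene2 =, model =, effect =)`
#'   entries with `model` one of `"product"`, `"xor_penetrance"`.  In place
#'   of a raw `effect`, an entry may give `r2 =`: the effect size is then
#'   calibrated on the realized genotypes so that the planted term's
#'   marginal variance-explained equals `r2` (the realized effect is
#'   recorded in the truth registry).
#' @param confounder_sd standard deviation of the PC1-aligned confounder.
#' @param noise_sd residual noise standard deviation.
#' @param missing_rate per-entry missingness probability in `[0, 0.5]`.
#' @param binary if `TRUE`, threshold the liability at its median into 0/1
#'   case/control.
#' @param seed RNG seed (mandatory).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n = 500, n_genes = 20, snps_per_gene = 8,
                              maf_range = c(0.1, 0.4), ld_rho = 0.7,
                              main_effects = list(),
                              epistasis_pairs = list(),
                              confounder_sd = 0.5, noise_sd = 1,
                              missing_rate = 0.001, binary = FALSE,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (any(maf_range <= 0.05) || any(maf_range >= 0.5))
    stop("maf_range must lie inside (0.05, 0.5)")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (missing_rate < 0 || missing_rate > 0.5)
    stop("missing_rate must be in [0, 0.5]")
  snps_per_gene <- rep(as.integer(snps_per_gene), length.out = n_genes)
  gene_ids <- sprintf("gene%02d", seq_len(n_genes))
  for (e in main_effects)
    if (!e$gene %in% gene_ids) stop("main effect names unknown gene ", e$gene)
  for (e in epistasis_pairs) {
    if (!all(c(e$gene1, e$gene2) %in% gene_ids))
      stop("epistasis pair names unknown gene")
    if (!e$model %in% c("product", "xor_penetrance"))
      stop("unknown epistasis model ", e$model)
    if (is.null(e$effect) && is.null(e$r2))
      stop("epistasis pair needs an effect or an r2 target")
  }
  structure(list(n = as.integer(n), n_genes = as.integer(n_genes),
                 snps_per_gene = snps_per_gene, gene_ids = gene_ids,
                 maf_range = maf_range, ld_rho = ld_rho,
                 main_effects = main_effects,
                 epistasis_pairs = epistasis_pairs,
                 confounder_sd = confounder_sd, noise_sd = noise_sd,
                 missing_rate = missing_rate, binary = isTRUE(binary),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate LD-structured genotypes
#'
#' @param cfg a [simulation_config()].
#' @return list with `genotypes` (complete genotype matrix) and `map`
#'   (data.frame `snp`, `gene`); sampled MAFs are attached as attribute
#'   `maf` on the genotypes.
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n
  sample_ids <- sprintf("S%04d", seq_len(n))
  blocks <- vector("list", cfg$n_genes)
  maps <- vector("list", cfg$n_genes)
  mafs <- numeric(0)
  for (g in seq_len(cfg$n_genes)) {
    m <- cfg$snps_per_gene[g]
    maf <- stats::runif(m, cfg$maf_range[1L], cfg$maf_range[2L])
    Sigma <- cfg$ld_rho^abs(outer(seq_len(m), seq_len(m), "-"))
    Ch <- chol(Sigma)
    thr <- matrix(stats::qnorm(maf), n, m, byrow = TRUE)
    geno <- matrix(0L, n, m)
    for (hap in 1:2) {
      Z <- matrix(stats::rnorm(n * m), n, m) %*% Ch
      geno <- geno + (Z < thr)
    }
    snp_ids <- sprintf("%s_s%02d", cfg$gene_ids[g], seq_len(m))
    colnames(geno) <- snp_ids
    blocks[[g]] <- geno
    maps[[g]] <- data.frame(snp = snp_ids, gene = cfg$gene_ids[g],
                            stringsAsFactors = FALSE)
    mafs <- c(mafs, stats::setNames(maf, snp_ids))
  }
  values <- do.call(cbind, blocks)
  rownames(values) <- sample_ids
  g <- genotype_matrix(values)
  attr(g, "maf") <- mafs
  list(genotypes = g, map = do.call(rbind, maps))
}

#' Simulate a phenotype with planted effects
#'
#' Causal SNPs are drawn uniformly within the named genes and recorded in
#' the returned truth.  All planted terms are mean-centered so effect sizes
#' are variance contributions on a common footing.
#'
#' @param g complete genotype matrix from [simulate_genotypes()].
#' @param map the matching SNP-gene map.
#' @param cfg the [simulation_config()].
#' @return a raw phenotype vector with attribute `truth`: list with
#'   `main` and `epistasis` data.frames of realized causal SNPs and effects.
#' @export
simulate_phenotype <- function(g, map, cfg) {
  set.seed(cfg$seed + 1L)
  n <- nrow(g)
  y <- numeric(n)
  snps_of <- function(gene) map$snp[map$gene == gene]
  truth_main <- list(); truth_epi <- list()
  for (e in cfg$main_effects) {
    snp <- sample(snps_of(e$gene), 1L)
    y <- y + e$effect * (g[, snp] - mean(g[, snp]))
    truth_main[[length(truth_main) + 1L]] <-
      data.frame(gene = e$gene, snp = snp, effect = e$effect,
                 stringsAsFactors = FALSE)
  }
  epi_terms <- list()
  for (e in cfg$epistasis_pairs) {
    s1 <- sample(snps_of(e$gene1), 1L)
    s2 <- sample(snps_of(e$gene2), 1L)
    term <- if (e$model == "product") g[, s1] * g[, s2]
            else as.numeric(xor(g[, s1] > 0, g[, s2] > 0))
    epi_terms[[length(epi_terms) + 1L]] <-
      list(e = e, s1 = s1, s2 = s2, term = term - mean(term))
  }
  if (cfg$confounder_sd > 0) {
    pc1 <- stats::prcomp(g, center = TRUE, scale. = FALSE)$x[, 1L]
    y <- y + cfg$confounder_sd * pc1 / stats::sd(pc1)
  }
  y <- y + stats::rnorm(n, 0, cfg$noise_sd)
  # epistatic terms enter last: an r2-targeted effect is calibrated against
  # the variance of everything else in the realized study
  for (et in epi_terms) {
    e <- et$e
    effect <- if (!is.null(e$effect)) e$effect
      else {
        # exact in-sample calibration: choose b so the squared marginal
        # correlation of y + b*t with the planted term t equals r2, given
        # the empirical covariance between t and everything already in y
        rho <- e$r2
        vt <- stats::var(et$term); vr <- stats::var(y)
        cv <- stats::cov(y, et$term)
        (-cv * (1 - rho) + sqrt((1 - rho) * rho * (vt * vr - cv^2))) /
          (vt * (1 - rho))
      }
    y <- y + effect * et$term
    truth_epi[[length(truth_epi) + 1L]] <-
      data.frame(gene1 = e$gene1, gene2 = e$gene2, snp1 = et$s1,
                 snp2 = et$s2, model = e$model, effect = effect,
                 stringsAsFactors = FALSE)
  }
  if (cfg$binary) y <- as.numeric(y > stats::median(y))
  out <- phenotype_vector(y, rownames(g), kind = "raw")
  attr(out, "truth") <- list(
    main = if (length(truth_main)) do.call(rbind, truth_main)
           else data.frame(gene = character(), snp = character(),
                           effect = numeric()),
    epistasis = if (length(truth_epi)) do.call(rbind, truth_epi)
                else data.frame(gene1 = character(), gene2 = character(),
                                snp1 = character(), snp2 = character(),
                                model = character(), effect = numeric()))
  out
}

#' Mask genotype entries at random
#'
#' @param g genotype matrix.
#' @param rate per-entry masking probability in `[0, 0.5]`.
#' @param seed RNG seed.
#' @return the matrix with masked entries set to `NA`.
#' @export
inject_missingness <- function(g, rate, seed) {
  if (rate < 0 || rate > 0.5) stop("rate must be in [0, 0.5]")
  if (rate == 0) return(g)
  set.seed(seed)
  mask <- matrix(stats::runif(length(g)) < rate, nrow(g), ncol(g))
  g[mask] <- NA
  g
}

#' Simulate a complete study
#'
#' Genotypes, SNP-gene map, phenotype (computed on the complete genotypes)
#' and then missingness injection, all deterministic under `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return an object of class `simulated_study`: list with `genotypes`
#'   (with missing entries), `map`, `phenotype` and `truth`.
#' @export
simulate_study <- function(cfg) {
  sim <- simulate_genotypes(cfg)
  y <- simulate_phenotype(sim$genotypes, sim$map, cfg)
  truth <- attr(y, "truth")
  attr(y, "truth") <- NULL
  g <- inject_missingness(sim$genotypes, cfg$missing_rate, cfg$seed + 2L)
  structure(list(genotypes = g, map = sim$map, phenotype = y,
                 truth = truth, config = cfg),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d samples, %d SNPs in %d genes; %d main, %d epistatic effect(s)\n",
    nrow(x$genotypes), ncol(x$genotypes), x$config$n_genes,
    nrow(x$truth$main), nrow(x$truth$epistasis)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Genotypes (TSV and PLINK RAW dialects), map TSV, phenotype TSV and a YAML
#' truth registry.
#'
#' @param study a `simulated_study`.
#' @param dir output directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(study$genotypes, file.path(dir, "genotypes.tsv"), "tsv")
  write_genotypes(study$genotypes, file.path(dir, "genotypes.raw"),
                  "plink_raw")
  utils::write.table(study$map, file.path(dir, "snp_gene_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_phenotype(study$phenotype, file.path(dir, "phenotype.tsv"))
  yaml::write_yaml(list(
    main = lapply(seq_len(nrow(study$truth$main)), function(i)
      as.list(study$truth$main[i, ])),
    epistasis = lapply(seq_len(nrow(study$truth$epistasis)), function(i)
      as.list(study$truth$epistasis[i, ]))),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}
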