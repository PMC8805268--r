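# End-to-end driver chaining every stage of the workflow.

#' Run the full epistasis-detection pipeline
#'
#' Imputation -> phenotype correction -> per-gene partitioning -> phenotype
#' discretization -> within-gene synergy, networks and diffusion-kernel
#' summaries -> spike-and-slab interaction model -> epistasis network.
#'
#' @param genotypes genotype matrix (may contain missing calls).
#' @param map SNP-gene map data.frame (`snp`, `gene`).
#' @param phenotype raw phenotype vector.
#' @param k_impute neighbours for [knn_impute()] (default 10).
#' @param n_pcs genotype PCs regressed out of the phenotype (default 7).
#' @param min_snps minimum SNPs per gene (default 3).
#' @param n_bins phenotype bins for the synergy stage (default `"auto"`).
#' @param beta_grid diffusion-strength grid (default 101 values 0..10).
#' @param model a [model_config()] for the interaction sampler.
#' @param threshold PIP threshold for the reported network (default 0).
#' @param infer_networks also infer per-gene MRNET graphs and their
#'   statistics (reporting only; the kernel stage always consumes the full
#'   synergy matrix).  Default `TRUE`.
#' @param verbose print stage messages.
#' @return list with `corrected` (phenotype), `blocks`, `synergy`,
#'   `graphs`, `properties`, `summaries`, `fit`, `network`.
#' @export
run_pipeline <- function(genotypes, map, phenotype, k_impute = 10,
                         n_pcs = 7, min_snps = 3, n_bins = "auto",
                         beta_grid = default_beta_grid(),
                         model = model_config(), threshold = 0,
                         infer_networks = TRUE, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  say("imputing missing genotypes (k = ", k_impute, ")")
  g <- knn_impute(genotypes, k = k_impute)
  say("correcting phenotype for population structure (", n_pcs, " PCs)")
  yc <- correct_phenotype(phenotype, g, n_pcs = n_pcs)
  say("partitioning SNPs into gene blocks (min_snps = ", min_snps, ")")
  blocks <- partition_by_gene(g, map, min_snps = min_snps)
  dp <- discretize_phenotype(yc, n_bins = n_bins)
  say("computing synergy matrices for ", length(blocks), " genes")
  syn <- lapply(blocks, synergy_matrix, c = dp)
  graphs <- NULL; props <- NULL
  if (infer_networks) {
    say("inferring within-gene networks")
    graphs <- lapply(syn, infer_network)
    props <- network_properties_table(graphs)
  }
  say("computing diffusion-kernel gene summaries")
  summaries <- summarize_genes(blocks, dp, beta_grid = beta_grid)
  say("fitting the spike-and-slab interaction model")
  fit <- fit_interaction_model(summaries$scores, yc, config = model)
  net <- build_epistasis_network(fit, threshold = threshold)
  list(corrected = yc, blocks = blocks, synergy = syn, graphs = graphs,
       properties = props, summaries = summaries, fit = fit, network = net)
}
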