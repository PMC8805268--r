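---
title: "Gene-level epistasis detection with diffusion kernel principal components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level epistasis detection with diffusion kernel principal components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide association interaction studies ask whether the contribution of
one locus to a phenotype depends on the genotype at another locus
(statistical epistasis).  Testing all SNP pairs is statistically and
computationally punishing: hundreds of thousands of markers imply billions
of pairs, heavy multiple-testing corrections, and results that are hard to
replicate because linkage disequilibrium (LD) smears signals across nearby
SNPs.  `epikpc` implements a gene-level alternative: compress the SNPs
mapped to each gene into a single phenotype-informed score per individual,
and search for interactions between those gene scores instead of between
raw SNPs.  For a study with a few hundred genes this reduces the
interaction search space from billions of SNP pairs to a few thousand gene
pairs.

## The model, stage by stage

### Pre-processing

Missing genotype calls are filled by k-nearest-neighbour imputation
(`knn_impute()`, default `k = 10`).  The distance between two samples is
the Euclidean distance over SNPs observed in both, divided by the number of
shared SNPs; the `k` nearest samples *with an observed call at the SNP
being imputed* vote, the mode wins, and ties break deterministically
(smaller genotype value; earlier sample on equal distance).  The
deterministic tie-breaks make imputation reproducible bit for bit, and the
neighbour rule guarantees a vote whenever the SNP has at least one observed
call.  Imputation is idempotent and never touches observed calls.

The phenotype is corrected for population structure by regressing it on an
intercept plus the top principal components of the column-centered
genotype matrix (`correct_phenotype()`, default 7 PCs, matching common
GWAS practice for this trait class).  The residuals — mean zero, orthogonal
to every fitted PC — are the working phenotype for everything downstream,
including a binary case/control trait, which the model treats as a
continuous residual rather than through a logistic link.  Externally
computed ancestry covariates can replace the internal PCA via the
`covariates` argument.

SNPs are then partitioned into per-gene blocks (`partition_by_gene()`).
Genes with fewer than 3 SNPs are dropped (kernel summaries of one or two
SNPs carry no within-gene interaction structure); SNPs mapped to several
genes contribute to each, since eQTL maps are many-to-many.

### Within-gene synergy

The corrected phenotype is discretized into equal-width bins
(`discretize_phenotype()`); plug-in entropy estimators need a discrete
outcome.  The default bin count is `round(n^(1/3))` — the cube-root rule,
which balances resolution against empty cells.  A one-dimensional k-means
binning is available as an alternative (`method = "kmeans"`,
deterministically initialised at the equal-width bin centers); the
equal-width default is the documented, reproducible choice.  Raw binary
phenotypes pass through unchanged.

For SNPs $A$, $B$ and the binned phenotype $C$, the bivariate synergy is

$$\mathrm{Syn}(A;B;C) = I(A,B;C) - \big[I(A;C) + I(B;C)\big],$$

with $I(X;C) = H(C) - H(C\mid X)$ the information gain and $H$ the plug-in
Shannon entropy (base 2, so synergies are in bits; the base is configurable
and only rescales results).  Positive synergy means the pair carries
information about the phenotype beyond its parts — XOR-style epistasis
reaches a full bit with no marginal signal — while negative values flag
redundancy, e.g. SNPs in LD.  Plug-in (maximum-likelihood) frequencies are
used without bias correction: they match the synergy definition exactly and
make independent counting oracles exact, at the cost of the usual upward
bias of plug-in mutual information at small $n$, which cancels in the
*difference* structure of the synergy only partially.  `synergy_matrix()`
assembles the symmetric SNP-by-SNP matrix with a zero diagonal; it is
invariant under joint sample permutations.

### Within-gene networks

For reporting, a sparse SNP graph per gene is inferred by the
maximum-relevance-minimum-redundancy scheme (`infer_network()`): each SNP
in turn is the target, the remaining SNPs are greedily ranked by
$u_j - r_j$ (relevance to the target minus mean synergy with the already
selected set), the two directed selection-time scores of each pair are
symmetrized by their maximum, and only strictly positive scores survive as
edge weights.  Negative synergies enter the relevance and redundancy terms
unclipped; only the final edge score is thresholded at zero.  Strict
positivity is required — a zero score means the candidate's relevance is
fully explained by already-selected SNPs, so keeping such edges would make
an all-zero synergy matrix produce a complete graph.  Density, mean
shortest-path distance and global transitivity (`network_properties()`)
summarise each gene's graph; statistics that are undefined on a given graph
(no connected pair, no triple) are reported as `NA` rather than raised as
errors.  The inferred graph is reporting output only: the kernel stage
consumes the full synergy matrix, following the kernel definition, so that
no thresholding decision feeds the gene summaries.  `--use-mrnet` style
node reduction was considered and rejected as a default because it couples
two stages that the definitions keep separate.

### Diffusion-kernel gene summaries

The synergy matrix $W$ of a gene defines a graph Laplacian with
$L_{ij} = W_{ij}$ off the diagonal and $L_{ii} = -\sum_{l \ne i} W_{il}$,
so rows sum to zero.  The diffusion kernel is the matrix exponential

$$K_L = e^{\beta L},$$

computed through one symmetric eigendecomposition
($V\,\mathrm{diag}(e^{\beta\lambda})\,V^\top$), which is exact for
symmetric $L$, always symmetric positive definite regardless of the sign
of the synergy weights, and lets the whole grid of $\beta$ values reuse a
single decomposition ($O(m^3 + Bm^2)$ instead of $B$ exponentials).
Rather than committing to one diffusion strength, kernels are averaged
over the default grid $\beta = 0, 0.1, \dots, 10$ (101 values), letting
each gene's own graph decide how far information spreads.  $\beta = 0$
gives the identity exactly (implemented as a short-circuit, not an
eigendecomposition).

The $n \times n$ sample kernel is the "sandwich"

$$K = G\,K_L\,G^\top,$$

with $G$ the gene's $n \times m$ genotype block.  $G$ enters raw (0/1/2)
by default; a column-centering flag exists, but the double centering of
$K$ downstream ($K' = HKH$, $H = I - \tfrac1n\mathbf{1}\mathbf{1}^\top$)
removes sample-mean effects either way.  The gene summary is the first
kernel principal component of $K'$: scores
$\sqrt{\lambda_1}\,v_1$, sign-fixed so the largest-magnitude score is
positive (principal components are sign-ambiguous; the model is
sign-invariant but reports are easier to compare under a fixed
convention).  Kernels up to 2000 samples use a dense symmetric
eigendecomposition; above that a power iteration extracts only the leading
eigenpair, so the solver is never asked for more than it needs.  With
$\beta$ fixed at 0 the whole construction collapses to the classical first
principal component of the genotype block — a useful exact limit that the
test suite checks to $10^{-8}$.

### The interaction model

Gene scores $X_{j}$ enter a Bayesian semi-parametric regression

$$Y_i \sim \mathrm{Normal}\!\big(f(X_i), \sigma^2\big), \qquad
  f = \sum_{h=1}^{k} f^{(h)},$$

where each additive function $f^{(h)}$ is built from the genes in its
active set $A_h = \{j : \zeta_{jh} = 1\}$: natural cubic spline bases
$\widetilde{X}_j$ ($d$ columns per gene, default $d = 2$, standardized
scores, $d = 1$ degenerating to a linear term) for every member, plus all
pairwise products $\widetilde{X}_{j_1}\!\otimes\!\widetilde{X}_{j_2}$ of
members' bases.  A spike-and-slab prior ties each coefficient block to the
product of its genes' inclusion indicators: a block is nonzero exactly when
all its genes sit in the function, so a gene pair interacts exactly when
both genes co-occupy some $f^{(h)}$.  An identifiability constraint forbids
one nonempty active set from nesting inside another (a singleton $\{j\}$
cannot coexist with $\{j, l\}$ — the pair's function already contains $j$'s
main effect).

Sampling is partially collapsed Gibbs: each indicator $\zeta_{jh}$ is
updated with the function's coefficients integrated out analytically
(Gaussian slab, Gaussian likelihood), then coefficients, residual variance
(inverse-gamma), per-function inclusion probabilities
$\tau_h \sim \mathrm{Beta}(1, p)$ (prior expectation: about one active gene
per function) and the slab scale are refreshed.  Genes are scanned in
lexicographic order of their identifiers, which makes a fit exactly
equivariant under permutations of the input columns at a fixed seed.

**Slab-scale update.**  The slab covariance is diagonal with a common
variance.  A pure empirical-Bayes update — plug in the mean squared active
coefficient, floored at $10^{-6}$ — is available
(`slab_update = "eb"`), but it has a degenerate fixed point: on null data
the active coefficients are tiny, the plug-in variance collapses to the
floor, spike and slab become indistinguishable, and the indicators drift at
their prior, inflating every PIP.  The default is therefore a conjugate
inverse-gamma hyperprior, $v \sim \mathrm{IG}(2, \mathrm{var}(y)/2)$,
refreshed by a Gibbs draw: with nothing active the slab stays on the scale
of the response and inclusion keeps paying its Occam penalty.  This is the
one place the implementation prefers a fully Bayesian update over a plug-in
for robustness.

Marginal PIP$(j)$ is the fraction of retained draws in which gene $j$ is
active in any function; interaction PIP$(j_1, j_2)$ the fraction in which
both share a function.  By construction the interaction PIP can never
exceed either marginal PIP.  With finite chains "PIP $> 0$" means "at least
one inclusion event among the retained draws"; `select_effects(strict =
TRUE)` instead requires a configurable minimum number of events.  The
$\sigma^2$ trace is stored for convergence assessment, with a coarse
Geweke-style z screen that warns but never fails: $\sigma^2$ legitimately
trends downward early in a run as the sampler discovers structure, so a
hard failure would punish exactly the runs that are working.

Defaults — $k = 10$ functions, $d = 2$ basis functions, 10000 iterations
with 5000 burn-in and thinning 5 — follow the published defaults of this
model family; they are declared in `model_config()` and echoed to YAML next
to every saved posterior.

### Reporting

`build_epistasis_network()` turns the posterior into the gene-level
statistical epistasis network: genes with any retained effect as nodes
(marginal PIP as attribute), pairs above the PIP threshold as edges.
Exports cover GraphML (for Cytoscape-class viewers), a ranked edge table,
and a plain gene list in the search-term format of gene-network web
services, so downstream database annotation can be done by hand; querying
those services is deliberately out of scope.

## The synthetic-study generator

`simulate_study()` provides the ground truth that every end-to-end claim in
the test suite rests on.  Genotypes follow a latent-Gaussian haplotype
model: per gene, each of two haplotypes is a draw from an AR($\rho$)
correlated Gaussian across the gene's SNPs, thresholded at each SNP's MAF
quantile, and summed.  This gives Hardy-Weinberg-consistent genotypes with
one-knob LD control — adjacent SNPs correlate at roughly $\rho$, decaying
along the gene — which is what the method consumes; it does not emulate
recombination maps, demography or imputation-panel structure, so passing
tests say nothing about robustness to those.  The phenotype adds centered
main effects (causal SNP drawn uniformly inside the named gene and
recorded), centered pairwise epistasis (`product`, or `xor_penetrance`:
exactly one carrier — the canonical synergy-without-marginals pattern), a
confounder proportional to the first genotype PC (what the PC correction
is meant to remove), Gaussian noise, and optional liability-threshold
binarization.  Missing calls are injected independently per entry.

Default conditions — $n = 500$ individuals, 20 genes of 8 SNPs, MAF in
$(0.1, 0.4)$, $\rho = 0.7$ (moderate within-gene LD, typical of eQTL SNP
sets after $r^2$-based pruning), confounder and noise standard deviations
0.5 and 1, missingness $10^{-3}$ — are the study conditions of the
recovery experiments.  Planted effects can be given either as raw
coefficients or as a target variance-explained (`r2 =`), in which case the
coefficient is calibrated on the realized genotypes — the recovery
experiments plant their product interaction at a marginal $R^2$ of 0.1
this way, so every replicate carries the same signal strength instead of
inheriting the sampling noise of the MAF and causal-SNP draws.  Everything
is deterministic under the configured seed.

## Numerical choices and degenerate inputs

* Entropies use $0 \log 0 := 0$; empty contingency cells contribute
  nothing.
* Equal-width binning assigns the maximum to the last bin; constant
  phenotypes are an error (zero-width bins).
* MRMR ties break toward the lower node index; distance ties in imputation
  toward the earlier sample; mode ties toward the smaller genotype.
* `diffusion_kernel(L, 0)` and an all-zero grid return the identity
  exactly; other kernels are symmetrized as $(K + K^\top)/2$ after the
  spectral reconstruction to scrub floating-point asymmetry.
* A kernel whose leading eigenvalue is not positive (e.g. constant
  genotypes) raises an error naming the gene.
* `center_kernel()` on an already centered kernel warns and returns its
  input; centering state is tracked as an attribute, not guessed from the
  numbers.
* The sampler treats a proposed inclusion state that violates the
  nesting constraint as having zero prior mass and stays put; the residual
  variance and $\tau_h$ draws are clamped away from 0 and 1 by
  $10^{-12}$.

## Problem sizes used in validation

The recovery experiments run the full pipeline on 500 individuals, 20
genes and 160 SNPs with 2000 sampler iterations (1000 burn-in, thinning
2), five seeded replicates with a planted pair and five all-null; the
oracle suites use 200 random discrete triples and graphs up to 10 nodes.
These sizes exercise every code path while keeping a complete validation
run on a single CPU within a coffee break; the sampler's cost grows
linearly in iterations and roughly quadratically in genes, and the
kernel stage cubically in $n$ below the dense-solver threshold.

## Known limitations

* **Single-SNP interactions attenuate through the summary.**  The first
  kernel PC of a gene is a weighted average of its SNPs, so an interaction
  carried by one SNP per gene reaches the gene level multiplied by the
  product of the summary-causal correlations — squared again in
  variance-explained terms.  Under moderate within-gene LD this can push a
  SNP-pair interaction planted at marginal $R^2 = 0.1$ down to the chance
  floor of the null gene pairs, at which point no detector consuming the
  summaries can single it out; the interacting *genes* still surface
  through their marginal PIPs.  The validation suite makes this split
  visible: the interaction model recovers a product interaction planted
  directly on the gene scores in 5/5 seeded replicates, while end-to-end
  top-rank recovery of a single-SNP-pair interaction through the kernel
  stage is unreliable at $n = 500$.  Interactions spread over several SNPs
  per gene, or genes in strong LD, attenuate far less.
* Plug-in information estimates are biased upward at small $n$ and many
  bins; rankings are more trustworthy than absolute bit values.
* The diffusion strength grid is fixed, not tuned; tuning $\beta$ per gene
  is an open extension point.
* One kernel PC per gene: genes whose relevant variation hides in later
  components are summarised poorly.  The component count is an extension
  point, not a tested path.
* PIPs from finite chains are chain-length dependent near zero; use
  `strict` selection when comparing across runs of different lengths.
* Binary traits are handled through residual correction and a Gaussian
  model, not a proper link function.
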