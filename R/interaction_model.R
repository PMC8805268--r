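# Bayesian semi-parametric interaction model on gene summaries.
#
# Response model:  Y_i ~ Normal(f(X_i), sigma^2),  f = sum_{h=1}^k f^(h),
# where each additive function f^(h) is built from the genes in its active
# set A_h: natural-spline main terms for every member plus products of the
# spline bases for every pair of members.  A spike-and-slab prior ties a
# whole coefficient block to the binary inclusion indicators zeta_{jh}: the
# block for a subset S of genes is nonzero only when prod_{j in S} zeta_{jh}
# = 1 (so an interaction is active exactly when both genes sit in a common
# function).  An identifiability constraint forbids one nonempty active set
# from being a subset of another.  Inference is a partially collapsed Gibbs
# sampler: inclusion indicators are updated with the function's coefficients
# integrated out (conjugate Gaussian slab), then coefficients, residual
# variance, per-function inclusion probabilities tau_h and the empirical-
# Bayes slab scale are refreshed.

#' Natural spline basis of a gene summary
#'
#' Standardizes the scores (mean 0, unit variance) and evaluates a natural
#' cubic spline basis with `d` degrees of freedom; `d = 1` returns the
#' standardized scores themselves (linear term).
#'
#' @param summary a `gene_summary` or a numeric score vector.
#' @param d basis dimension (`1 <= d <= n - 1`).
#' @return n x d numeric matrix.
#' @export
build_basis <- function(summary, d) {
  x <- if (inherits(summary, "gene_summary")) summary$scores else summary
  x <- as.numeric(x)
  if (d < 1) stop("d must be >= 1")
  if (d > length(x) - 1) stop("d must be at most n - 1")
  if (stats::sd(x) == 0) stop("constant scores: no basis can be built")
  z <- as.numeric(scale(x))
  B <- if (d == 1) matrix(z, ncol = 1) else unclass(splines::ns(z, df = d))
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  B
}

#' Sampler configuration
#'
#' @param k number of additive functions (default 10); large enough that all
#'   active effects can be captured.
#' @param d basis dimension per gene (default 2).
#' @param n_iter,n_burn,thin MCMC schedule (defaults 10000 / 5000 / 5).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param tau_a,tau_b Beta prior on the per-function inclusion probability
#'   `tau_h`; `tau_b = NULL` defaults to the number of genes `p`, so the
#'   prior expected number of active genes per function is about 1.
#' @param slab_update how the common slab variance is refreshed each sweep:
#'   `"gibbs"` (default) draws it from its conjugate inverse-gamma
#'   conditional under an `IG(slab_a, slab_b)` hyperprior, which keeps the
#'   slab on the scale of the response even when nothing is active;
#'   `"eb"` plugs in the mean squared active coefficient (empirical Bayes),
#'   floored at `slab_floor` - note that on null data this point estimate
#'   can collapse toward the spike, in which case inclusion indicators
#'   drift at their prior.
#' @param slab_a,slab_b inverse-gamma hyperprior for `slab_update = "gibbs"`;
#'   `slab_b = NULL` defaults to `var(y)/20`, i.e. a prior slab mean of
#'   `var(y)/20`: on the standardized design a single coefficient is
#'   expected a priori to explain a few percent of the response variance,
#'   and the Gibbs update adapts the scale to the active coefficients.
#' @param slab_floor lower bound for the `"eb"` slab variance.
#' @param sigma_a,sigma_b inverse-gamma prior on the residual variance.
#' @param tau_fixed optional fixed value for all `tau_h` (used to pin
#'   inclusion probabilities, e.g. near 0 for a null model).
#' @return an object of class `model_config`.
#' @export
model_config <- function(k = 10, d = 2, n_iter = 10000, n_burn = 5000,
                         thin = 5, seed = 1L, tau_a = 1, tau_b = NULL,
                         slab_update = c("gibbs", "eb"), slab_a = 2,
                         slab_b = NULL,
                         slab_floor = 1e-6, sigma_a = 0.01, sigma_b = 0.01,
                         tau_fixed = NULL) {
  slab_update <- match.arg(slab_update)
  if (k < 1) stop("k must be >= 1")
  if (d < 1) stop("d must be >= 1")
  if (n_burn >= n_iter) stop("n_burn must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(k = as.integer(k), d = as.integer(d),
                 n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), seed = as.integer(seed),
                 tau_a = tau_a, tau_b = tau_b, slab_update = slab_update,
                 slab_a = slab_a, slab_b = slab_b,
                 slab_floor = slab_floor,
                 sigma_a = sigma_a, sigma_b = sigma_b,
                 tau_fixed = tau_fixed),
            class = "model_config")
}

# A pure pairwise interaction has no marginal signal, so single-site Gibbs
# must pass through an unfavourable singleton state before a pair completes.
# A dedicated Metropolis birth/death move proposes jumping an empty function
# straight to a random gene pair (and a two-gene function straight to
# empty), with the coefficients integrated out and the proposal asymmetry
# corrected, leaving the posterior invariant while making pair states
# reachable in a single step.

# sorted-set subset test; sets are integer vectors
.is_subset <- function(a, b) all(match(a, b, nomatch = 0L) > 0L)

# the identifiability indicator: a nonempty A_h may not be a subset of (or
# equal to) any other nonempty A_m, in either direction for the changed set
.valid_set_change <- function(h, newset, sets) {
  if (!length(newset)) return(TRUE)
  for (m in seq_along(sets)) {
    if (m == h || !length(sets[[m]])) next
    if (.is_subset(newset, sets[[m]])) return(FALSE)
    if (.is_subset(sets[[m]], newset)) return(FALSE)
  }
  TRUE
}

#' Fit the spike-and-slab interaction model
#'
#' Samples the posterior over which genes (and which gene pairs, through
#' co-membership in an additive function) influence the phenotype, and
#' reports marginal and pairwise Posterior Inclusion Probabilities.
#'
#' Genes are processed internally in lexicographic order of their ids, so a
#' permutation of the input columns yields the identically permuted
#' posterior under the same seed.
#'
#' @param x gene summaries: an n x p matrix of scores with gene ids as
#'   column names (e.g. `summarize_genes()$scores`), or a list of
#'   `gene_summary` objects.
#' @param y corrected (continuous) phenotype aligned with the rows of `x`.
#' @param config a [model_config()].
#' @return an object of class `epistasis_fit` with elements
#'   `marginal_pip` (named, per gene), `interaction_pip` (p x p symmetric,
#'   zero diagonal), `sigma2_trace`, `inclusion_trace` (retained samples x
#'   genes), `pair_trace` (per retained sample, 2-column matrix of active
#'   pair indices), `n_retained`, `config` and `diagnostics`.
#' @export
fit_interaction_model <- function(x, y, config = model_config()) {
  if (is.list(x) && !is.matrix(x)) {
    scores <- vapply(x, function(s) s$scores, numeric(length(x[[1L]]$scores)))
    colnames(scores) <- vapply(x, `[[`, character(1), "gene_id")
    rownames(scores) <- x[[1L]]$sample_ids
    x <- scores
  }
  if (is.null(colnames(x))) stop("gene summaries need gene ids as colnames")
  p <- ncol(x); n <- nrow(x)
  if (p < 2L) stop("need at least two genes")
  if (!is.null(names(y)) && !is.null(rownames(x))) {
    if (!setequal(names(y), rownames(x)))
      stop("phenotype and summary samples differ")
    y <- y[rownames(x)]
  } else if (length(y) != n) {
    stop("phenotype length does not match summaries")
  }

  genes_in <- colnames(x)
  ord <- order(genes_in)               # canonical, label-determined scan order
  x <- x[, ord, drop = FALSE]
  genes <- colnames(x)
  k <- config$k; d <- config$d
  tau_b <- config$tau_b %||% p
  set.seed(config$seed)

  # columns are standardized so one slab variance is meaningful across
  # main and product terms; all-but-constant columns are zeroed
  safe_scale <- function(M) {
    s <- apply(M, 2L, stats::sd)
    M <- scale(M, center = TRUE, scale = ifelse(s > 1e-12, s, 1))
    M[, s <= 1e-12] <- 0
    M
  }

  # --- design dictionary: main-effect blocks, then pairwise product blocks
  Blist <- lapply(seq_len(p), function(j) safe_scale(build_basis(x[, j], d = d)))
  main_cols <- vector("list", p)
  cols <- 0L
  for (j in seq_len(p)) {
    main_cols[[j]] <- cols + seq_len(d)
    cols <- cols + d
  }
  npair <- p * (p - 1L) / 2L
  pair_id <- matrix(0L, p, p)
  pair_cols <- vector("list", npair)
  pair_members <- matrix(0L, npair, 2L)
  pid <- 0L
  pair_blocks <- vector("list", npair)
  for (j1 in seq_len(p - 1L)) {
    for (j2 in (j1 + 1L):p) {
      pid <- pid + 1L
      pair_id[j1, j2] <- pair_id[j2, j1] <- pid
      pair_members[pid, ] <- c(j1, j2)
      PB <- matrix(0, n, d * d)
      c0 <- 0L
      for (a in seq_len(d)) for (b in seq_len(d)) {
        c0 <- c0 + 1L
        PB[, c0] <- Blist[[j1]][, a] * Blist[[j2]][, b]
      }
      pair_blocks[[pid]] <- safe_scale(PB)
      pair_cols[[pid]] <- cols + seq_len(d * d)
      cols <- cols + d * d
    }
  }
  Xall <- do.call(cbind, c(Blist, pair_blocks))
  Gm <- crossprod(Xall)

  set_cols <- function(S) {
    if (!length(S)) return(integer(0))
    out <- unlist(main_cols[S], use.names = FALSE)
    if (length(S) > 1L) {
      for (a in seq_len(length(S) - 1L)) {
        for (b in (a + 1L):length(S)) {
          out <- c(out, pair_cols[[pair_id[S[a], S[b]]]])
        }
      }
    }
    out
  }

  ymean <- mean(as.numeric(y))
  yc <- as.numeric(y) - ymean

  # --- state
  sets <- rep(list(integer(0)), k)
  fitted <- matrix(0, n, k)
  fit_total <- numeric(n)
  sigma2 <- stats::var(yc)
  tau <- rep(if (is.null(config$tau_fixed))
               config$tau_a / (config$tau_a + tau_b)
             else config$tau_fixed, k)
  slab_a <- config$slab_a
  slab_b <- config$slab_b %||% (stats::var(yc) / 20)
  v_slab <- slab_b / max(slab_a - 1, 0.5)
  betas <- rep(list(numeric(0)), k)

  log_evidence <- function(colsel, bh, rss) {
    base_ll <- -0.5 * n * log(2 * pi * sigma2) - rss / (2 * sigma2)
    if (!length(colsel))
      return(list(lml = base_ll, U = NULL, z = NULL))
    A <- Gm[colsel, colsel, drop = FALSE] / sigma2
    diag(A) <- diag(A) + 1 / v_slab
    U <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(U)) return(list(lml = -Inf, U = NULL, z = NULL))
    z <- backsolve(U, bh[colsel] / sigma2, transpose = TRUE)
    list(lml = base_ll - 0.5 * length(colsel) * log(v_slab) -
           sum(log(diag(U))) + 0.5 * sum(z * z),
         U = U, z = z)
  }

  n_ret <- length(seq.int(config$n_burn + config$thin, config$n_iter,
                          by = config$thin))
  marg_counts <- numeric(p)
  pair_counts <- matrix(0, p, p)
  sigma2_trace <- numeric(n_ret)
  inclusion_trace <- matrix(FALSE, n_ret, p)
  pair_trace <- vector("list", n_ret)
  n_active_trace <- numeric(n_ret)
  ret <- 0L

  for (iter in seq_len(config$n_iter)) {
    for (h in seq_len(k)) {
      Rh <- yc - fit_total + fitted[, h]
      bh <- as.numeric(crossprod(Xall, Rh))
      rss <- sum(Rh * Rh)
      cur <- log_evidence(set_cols(sets[[h]]), bh, rss)
      for (j in seq_len(p)) {
        inS <- j %in% sets[[h]]
        other <- if (inS) setdiff(sets[[h]], j) else sets[[h]]
        newset <- if (inS) other else sort(c(other, j))
        if (!.valid_set_change(h, newset, sets)) next
        prop <- log_evidence(set_cols(newset), bh, rss)
        if (!is.finite(prop$lml)) next
        lp_on <- log(tau[h]); lp_off <- log1p(-tau[h])
        lodds <- if (inS)
          (prop$lml + lp_off) - (cur$lml + lp_on)   # odds of dropping j
        else
          (prop$lml + lp_on) - (cur$lml + lp_off)   # odds of adding j
        if (stats::runif(1) < 1 / (1 + exp(-lodds))) {
          sets[[h]] <- newset
          cur <- prop
        }
      }
      # pair birth/death Metropolis move (see note above)
      S <- sets[[h]]
      npair_all <- p * (p - 1) / 2
      ltau_pair <- 2 * (log(tau[h]) - log1p(-tau[h]))
      if (length(S) == 0L) {
        newset <- sort(sample.int(p, 2L))
        if (.valid_set_change(h, newset, sets)) {
          prop <- log_evidence(set_cols(newset), bh, rss)
          lacc <- (prop$lml - cur$lml) + ltau_pair + log(npair_all)
          if (is.finite(prop$lml) && log(stats::runif(1)) < lacc) {
            sets[[h]] <- newset
            cur <- prop
          }
        }
      } else if (length(S) == 2L) {
        prop <- log_evidence(integer(0), bh, rss)
        lacc <- (prop$lml - cur$lml) - ltau_pair - log(npair_all)
        if (log(stats::runif(1)) < lacc) {
          sets[[h]] <- integer(0)
          cur <- prop
        }
      }
      # coefficients | inclusion (conjugate Gaussian)
      colsel <- set_cols(sets[[h]])
      if (length(colsel)) {
        beta_h <- backsolve(cur$U, cur$z + stats::rnorm(length(colsel)))
        betas[[h]] <- beta_h
        fitted_new <- as.numeric(Xall[, colsel, drop = FALSE] %*% beta_h)
      } else {
        betas[[h]] <- numeric(0)
        fitted_new <- numeric(n)
      }
      fit_total <- fit_total - fitted[, h] + fitted_new
      fitted[, h] <- fitted_new
    }

    resid <- yc - fit_total
    sigma2 <- 1 / stats::rgamma(1, config$sigma_a + n / 2,
                                config$sigma_b + sum(resid * resid) / 2)
    if (is.null(config$tau_fixed)) {
      sizes <- lengths(sets)
      tau <- stats::rbeta(k, config$tau_a + sizes, tau_b + p - sizes)
      tau <- pmin(pmax(tau, 1e-12), 1 - 1e-12)
    }
    allbeta <- unlist(betas, use.names = FALSE)
    if (config$slab_update == "gibbs") {
      v_slab <- 1 / stats::rgamma(1, slab_a + length(allbeta) / 2,
                                  slab_b + sum(allbeta^2) / 2)
    } else if (length(allbeta)) {
      v_slab <- max(mean(allbeta^2), config$slab_floor)
    }

    if (iter > config$n_burn &&
        (iter - config$n_burn) %% config$thin == 0L) {
      ret <- ret + 1L
      inc <- logical(p)
      prs <- matrix(0L, 0L, 2L)
      for (h in seq_len(k)) {
        S <- sets[[h]]
        if (length(S)) inc[S] <- TRUE
        if (length(S) >= 2L)
          prs <- rbind(prs, t(utils::combn(S, 2L)))
      }
      if (nrow(prs)) {
        prs <- unique(prs)
        pair_counts[prs] <- pair_counts[prs] + 1
      }
      marg_counts <- marg_counts + inc
      sigma2_trace[ret] <- sigma2
      inclusion_trace[ret, ] <- inc
      pair_trace[[ret]] <- prs
      n_active_trace[ret] <- sum(lengths(sets) > 0)
    }
  }

  marginal_pip <- marg_counts / n_ret
  interaction_pip <- (pair_counts + t(pair_counts)) / n_ret
  diag(interaction_pip) <- 0

  # map back from canonical to the input gene order
  inv <- match(genes_in, genes)
  marginal_pip <- stats::setNames(marginal_pip[inv], genes_in)
  interaction_pip <- interaction_pip[inv, inv]
  dimnames(interaction_pip) <- list(genes_in, genes_in)
  inclusion_trace <- inclusion_trace[, inv, drop = FALSE]
  colnames(inclusion_trace) <- genes_in
  remap <- match(seq_len(p), inv)      # canonical index -> input index
  pair_trace <- lapply(pair_trace, function(m) {
    if (!nrow(m)) return(m)
    out <- cbind(remap[m[, 1L]], remap[m[, 2L]])
    t(apply(out, 1L, sort))
  })

  geweke_z <- .geweke_z(sigma2_trace)
  if (is.finite(geweke_z) && abs(geweke_z) > 3)
    warning(sprintf(
      "Geweke diagnostic on the sigma^2 trace is %.2f; chain may not have converged",
      geweke_z))

  structure(list(genes = genes_in,
                 marginal_pip = marginal_pip,
                 interaction_pip = interaction_pip,
                 sigma2_trace = sigma2_trace,
                 inclusion_trace = inclusion_trace,
                 pair_trace = pair_trace,
                 n_retained = n_ret,
                 config = config,
                 diagnostics = list(geweke_z = geweke_z,
                                    mean_active_functions =
                                      mean(n_active_trace))),
            class = "epistasis_fit")
}

# Geweke-style z score comparing the first 10% and last 50% segment means of
# a trace, with naive (independence) standard errors: a coarse convergence
# screen, reported but never fatal.
.geweke_z <- function(tr) {
  nt <- length(tr)
  if (nt < 20L) return(NA_real_)
  a <- tr[seq_len(max(2L, floor(0.1 * nt)))]
  b <- tr[seq.int(floor(0.5 * nt) + 1L, nt)]
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  if (!is.finite(se) || se == 0) return(NA_real_)
  (mean(a) - mean(b)) / se
}

#' @export
print.epistasis_fit <- function(x, ...) {
  cat(sprintf("<epistasis_fit> %d genes, %d retained samples\n",
              length(x$genes), x$n_retained))
  top <- sort(x$marginal_pip, decreasing = TRUE)
  cat("top marginal PIPs:\n")
  print(utils::head(round(top, 4)))
  invisible(x)
}

#' Select genes and gene pairs by Posterior Inclusion Probability
#'
#' Genes with marginal PIP above the threshold and pairs with interaction
#' PIP above the threshold, the pairs sorted by decreasing PIP then
#' lexicographically.  With finite chains, `PIP > 0` means "included in at
#' least one retained sample"; `strict = TRUE` instead requires
#' `PIP >= min_events / n_retained`.
#'
#' @param ps an `epistasis_fit`.
#' @param threshold PIP threshold in `[0, 1)` (default 0).
#' @param strict require at least `min_events` inclusion events.
#' @param min_events event count for strict mode (default 1).
#' @return list with data.frames `genes` (`gene`, `pip`) and `pairs`
#'   (`gene1`, `gene2`, `pip`).
#' @export
select_effects <- function(ps, threshold = 0, strict = FALSE,
                           min_events = 1) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  eff <- if (strict)
    max(threshold, min_events / ps$n_retained - 1e-12) else threshold
  keep_cmp <- if (strict) `>=` else `>`
  g <- ps$marginal_pip[keep_cmp(ps$marginal_pip, eff)]
  genes <- data.frame(gene = names(g), pip = as.numeric(g),
                      stringsAsFactors = FALSE)
  genes <- genes[order(-genes$pip, genes$gene), , drop = FALSE]
  ip <- ps$interaction_pip
  idx <- which(upper.tri(ip) & keep_cmp(ip, eff), arr.ind = TRUE)
  pairs <- data.frame(gene1 = rownames(ip)[idx[, 1L]],
                      gene2 = colnames(ip)[idx[, 2L]],
                      pip = ip[idx], stringsAsFactors = FALSE)
  swap <- pairs$gene1 > pairs$gene2
  if (any(swap)) {
    tmp <- pairs$gene1[swap]
    pairs$gene1[swap] <- pairs$gene2[swap]
    pairs$gene2[swap] <- tmp
  }
  pairs <- pairs[order(-pairs$pip, pairs$gene1, pairs$gene2), , drop = FALSE]
  rownames(genes) <- rownames(pairs) <- NULL
  list(genes = genes, pairs = pairs)
}

#' Write posterior output
#'
#' Marginal PIPs, interaction PIPs (descending) and the residual-variance
#' trace as TSVs, plus a YAML echo of the sampler configuration.
#'
#' @param ps an `epistasis_fit`.
#' @param dir output directory.
#' @export
write_posterior <- function(ps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sel <- select_effects(ps, threshold = 0)
  mp <- data.frame(gene = names(ps$marginal_pip),
                   pip = as.numeric(ps$marginal_pip))
  mp <- mp[order(-mp$pip, mp$gene), ]
  utils::write.table(mp, file.path(dir, "marginal_pip.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sel$pairs, file.path(dir, "interaction_pip.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(iteration = seq_along(ps$sigma2_trace),
                                sigma2 = ps$sigma2_trace),
                     file.path(dir, "sigma2_trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(ps$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
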