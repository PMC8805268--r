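# Independent brute-force oracles used to validate the package's
# information-theoretic, graph and linear-algebra primitives.  These are
# deliberately written as plain loops over contingency tables / node sets,
# sharing no code with the implementation.

o_entropy <- function(x, base = 2) {
  h <- 0
  for (u in unique(x)) {
    p <- mean(x == u)
    if (p > 0) h <- h - p * log(p, base = base)
  }
  h
}

o_cond_entropy <- function(x, given, base = 2) {
  h <- 0
  for (a in unique(given)) {
    sel <- given == a
    pa <- mean(sel)
    for (u in unique(x[sel])) {
      pj <- mean(sel & x == u)
      h <- h - pj * log(pj / pa, base = base)
    }
  }
  h
}

o_info_gain <- function(x, c, base = 2) {
  o_entropy(c, base) - o_cond_entropy(c, x, base)
}

o_info_gain2 <- function(a, b, c, base = 2) {
  joint <- paste(a, b, sep = "|")
  o_entropy(c, base) - o_cond_entropy(c, joint, base)
}

o_synergy <- function(a, b, c, base = 2) {
  o_info_gain2(a, b, c, base) - o_info_gain(a, c, base) -
    o_info_gain(b, c, base)
}

# brute-force kNN mode imputation: same neighbour rule as the package
# (k nearest samples with the SNP observed; normalized Euclidean distance
# over mutually observed SNPs; mode ties to smaller genotype, distance ties
# to earlier sample), computed with explicit per-pair loops
o_knn_impute <- function(g, k) {
  n <- nrow(g)
  d2 <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sh <- which(!is.na(g[i, ]) & !is.na(g[j, ]))
      if (length(sh))
        d2[i, j] <- sum((g[i, sh] - g[j, sh])^2) / length(sh)
    }
  }
  out <- g
  for (j in seq_len(ncol(g))) {
    obs <- which(!is.na(g[, j]))
    for (i in which(is.na(g[, j]))) {
      nb <- obs[order(d2[i, obs])][seq_len(min(k, length(obs)))]
      vals <- g[nb, j]
      cnt <- sapply(0:2, function(v) sum(vals == v))
      out[i, j] <- (0:2)[which.max(cnt)]
    }
  }
  out
}

# exhaustive greedy MRMR re-implementation
o_mrmr <- function(W, target) {
  m <- ncol(W)
  cand <- setdiff(seq_len(m), target)
  S <- integer(0)
  out <- NULL
  while (length(cand)) {
    best <- NULL
    for (j in cand) {
      u <- W[j, target]
      r <- if (length(S)) mean(W[j, S]) else 0
      s <- u - r
      if (is.null(best) || s > best$s) best <- list(j = j, s = s)
    }
    out <- rbind(out, c(best$j, best$s))
    S <- c(S, best$j)
    cand <- setdiff(cand, best$j)
  }
  out
}

# two-pass MRNET edge set from the oracle ranking
o_mrnet_edges <- function(W) {
  m <- ncol(W)
  D <- matrix(0, m, m)
  for (t in seq_len(m)) {
    r <- o_mrmr(W, t)
    for (row in seq_len(nrow(r))) D[r[row, 1L], t] <- r[row, 2L]
  }
  E <- NULL
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      w <- max(D[i, j], D[j, i])
      if (w > 0) E <- rbind(E, c(i, j, w))
    }
  }
  E
}

o_expm_taylor <- function(L, beta, terms = 20) {
  m <- ncol(L)
  K <- diag(m)
  P <- diag(m)
  for (t in seq_len(terms)) {
    P <- P %*% (beta * L) / t
    K <- K + P
  }
  K
}

# BFS all-pairs shortest paths on an undirected unweighted graph given as an
# adjacency list over nodes 1..m
o_shortest_paths <- function(m, edges) {
  adj <- vector("list", m)
  if (!is.null(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1L]; j <- edges[r, 2L]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  D <- matrix(Inf, m, m)
  for (s in seq_len(m)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (D[s, v] > D[s, u] + 1) {
          D[s, v] <- D[s, u] + 1
          queue <- c(queue, v)
        }
      }
    }
  }
  D
}

o_graph_stats <- function(m, edges) {
  ne <- if (is.null(edges)) 0L else nrow(edges)
  A <- matrix(0L, m, m)
  if (ne) for (r in seq_len(ne)) {
    A[edges[r, 1L], edges[r, 2L]] <- A[edges[r, 2L], edges[r, 1L]] <- 1L
  }
  D <- o_shortest_paths(m, edges)
  fin <- D[is.finite(D) & D > 0]
  tri <- 0; triple <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) for (l in seq_len(m)) {
    if (i != j && j != l && i != l && A[i, j] && A[j, l]) {
      triple <- triple + 1
      if (A[i, l]) tri <- tri + 1
    }
  }
  list(density = 2 * ne / (m * (m - 1)),
       mean_distance = if (length(fin)) mean(fin) else NA_real_,
       transitivity = if (triple) tri / triple else NA_real_)
}

# truncated-power natural cubic spline basis (with intercept); used to
# compare fitted subspaces with the package basis
o_natural_spline_space <- function(x, d) {
  knots <- unname(stats::quantile(x, probs = seq(0, 1, length.out = d + 1)))
  K <- length(knots)
  dk <- function(k, x) {
    (pmax(x - knots[k], 0)^3 - pmax(x - knots[K], 0)^3) / (knots[K] - knots[k])
  }
  out <- cbind(1, x)
  if (K >= 3) {
    for (k in seq_len(K - 2)) out <- cbind(out, dk(k, x) - dk(K - 1, x))
  }
  out
}

proj_matrix <- function(X) {
  q <- qr.Q(qr(X))
  tcrossprod(q)
}

# small random fixtures
rand_discrete <- function(n, levels) sample(levels, n, replace = TRUE)

rand_symmetric <- function(m, scale = 1) {
  W <- matrix(stats::rnorm(m * m, sd = scale), m, m)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

rand_block <- function(n, m, gene = "geneX") {
  vals <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
                 dimnames = list(sprintf("s%03d", seq_len(n)),
                                 sprintf("snp%02d", seq_len(m))))
  gene_block(gene, vals)
}

as_synergy <- function(W, gene = "geneX") {
  dimnames(W) <- list(sprintf("snp%02d", seq_len(ncol(W))),
                      sprintf("snp%02d", seq_len(ncol(W))))
  structure(W, class = c("synergy_matrix", "matrix"), gene_id = gene)
}
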