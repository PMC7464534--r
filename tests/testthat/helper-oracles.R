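# Independent oracles used across the suite.  These re-derive quantities by
# routes the implementation does not take (dense matrix algebra, exhaustive
# enumeration, rejection sampling), so agreement is informative.

random_dna <- function(n, gc = 0.5, n_prob = 0) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  if (n_prob > 0) {
    paste(sample(c("A", "C", "G", "T", "N"), n, TRUE,
                 prob = c(probs * (1 - n_prob), n_prob)), collapse = "")
  } else {
    paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = probs), collapse = "")
  }
}

locus_cols <- c("start", "end", "period", "copies")

# restricted (REML) log-likelihood by dense multivariate-normal algebra
reml_loglik_mvn <- function(tree, x) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric(t(one) %*% Ci %*% x / (t(one) %*% Ci %*% one))
  Q <- as.numeric(t(x - mu) %*% Ci %*% (x - mu))
  s2 <- Q / (n - 1)
  as.numeric(-0.5 * ((n - 1) * log(2 * pi * s2) +
                       determinant(C)$modulus + log(sum(Ci)) + Q / s2))
}

# full ML log-likelihood by dense algebra (root profiled analytically)
ml_loglik_mvn <- function(tree, x) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric(t(one) %*% Ci %*% x / (t(one) %*% Ci %*% one))
  Q <- as.numeric(t(x - mu) %*% Ci %*% (x - mu))
  s2 <- Q / n
  as.numeric(-0.5 * (n * log(2 * pi * s2) + determinant(C)$modulus + Q / s2))
}

# GLS conditional-mean ancestral estimates via shared-path covariances
gls_ancestral <- function(tree, x) {
  nt <- ape::Ntip(tree)
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  Ci <- solve(C)
  one <- rep(1, nt)
  mu <- as.numeric(t(one) %*% Ci %*% x / (t(one) %*% Ci %*% one))
  D <- ape::dist.nodes(tree)
  root <- nt + 1L
  tips <- match(rownames(C), tree$tip.label)
  vapply(seq_len(tree$Nnode), function(k) {
    nd <- nt + k
    ca <- (D[root, nd] + D[root, tips] - D[nd, tips]) / 2
    mu + as.numeric(t(ca) %*% Ci %*% (x - mu))
  }, numeric(1))
}

# two-state Mk likelihood by exhaustive enumeration of ancestral states
mk_loglik_enum <- function(tree, states01, q01, q10, prior = c(0.5, 0.5)) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- ape::Ntip(tree)
  e <- tree$edge
  P <- lapply(seq_len(nrow(e)), function(i) {
    q <- q01 + q10
    if (q == 0) return(diag(2))
    p1 <- q10 / q; p2 <- q01 / q
    ep <- exp(-q * tree$edge.length[i])
    matrix(c(p1 + p2 * ep, p1 * (1 - ep), p2 * (1 - ep), p2 + p1 * ep), 2, 2)
  })
  grid <- as.matrix(expand.grid(rep(list(1:2), tree$Nnode)))
  tot <- 0
  obs <- states01[tree$tip.label] + 1L
  for (r in seq_len(nrow(grid))) {
    st <- c(obs, grid[r, ])
    lik <- prior[st[nt + 1L]]
    for (i in seq_len(nrow(e))) lik <- lik * P[[i]][st[e[i, 1]], st[e[i, 2]]]
    tot <- tot + lik
  }
  log(tot)
}

# classical one-way ANOVA F through R's linear-model machinery
anova_f_lm <- function(y, g) {
  unname(stats::anova(stats::lm(y ~ factor(g)))[["F value"]][1])
}
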