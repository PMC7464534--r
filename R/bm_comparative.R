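## Felsenstein pruning for a Brownian trait on a (resolved) binary tree.
## Returns, for every node, the downpass (subtree-conditional) estimate and
## its extra variance, the raw and standardised contrasts at internal nodes,
## and the quantities needed to reassemble both the restricted and the full
## multivariate-normal likelihoods without forming the covariance matrix.
bm_prune <- function(tree, x) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  tree <- ape::reorder.phylo(tree, "postorder")
  e <- tree$edge
  el <- tree$edge.length
  if (is.null(el)) stop("tree has no branch lengths")
  dval <- numeric(nt + nn)
  dvar <- numeric(nt + nn)   # extra variance accumulated at the node
  vlen <- numeric(nt + nn)   # edge length + dvar, as seen by the parent
  dval[seq_len(nt)] <- x
  node_edge <- integer(nt + nn)
  node_edge[e[, 2]] <- seq_len(nrow(e))
  parents <- unique(e[, 1])  # postorder: children edges precede the parent's
  raw <- numeric(length(parents))
  cvar <- numeric(length(parents))
  kids <- split(seq_len(nrow(e)), e[, 1])
  for (i in seq_along(parents)) {
    k <- parents[i]
    ce <- kids[[as.character(k)]]
    if (length(ce) != 2L) stop("internal error: tree not binary after resolution")
    c1 <- e[ce[1], 2]; c2 <- e[ce[2], 2]
    v1 <- el[ce[1]] + dvar[c1]; v2 <- el[ce[2]] + dvar[c2]
    vlen[c1] <- v1; vlen[c2] <- v2
    s <- v1 + v2
    raw[i] <- dval[c1] - dval[c2]
    cvar[i] <- s
    if (s <= 0) {
      if (abs(raw[i]) > 1e-12)
        stop("zero-length sister branches with differing trait values")
      dval[k] <- (dval[c1] + dval[c2]) / 2
      dvar[k] <- 0
    } else {
      dval[k] <- (dval[c1] * v2 + dval[c2] * v1) / s
      dvar[k] <- v1 * v2 / s
    }
  }
  root <- parents[length(parents)]
  ok <- cvar > 0
  list(tree = tree, ntip = nt, root = root,
       dval = dval, dvar = dvar, vlen = vlen,
       contrast_nodes = parents,
       raw = raw, cvar = cvar,
       contrasts = ifelse(ok, raw / sqrt(cvar), 0),
       root_state = dval[root], root_var = dvar[root],
       kids = kids, node_edge = node_edge)
}

## key internal clades by their sorted descendant tip labels, so node
## estimates can be mapped across alternative resolutions of polytomies
clade_keys <- function(tree) {
  nt <- ape::Ntip(tree)
  pp <- ape::prop.part(tree)
  vapply(pp, function(idx)
    paste(sort(tree$tip.label[idx]), collapse = "|"), character(1))
}

#' Phylogenetically independent contrasts
#'
#' Standardised contrasts for a continuous trait under Brownian motion,
#' computed by Felsenstein's pruning algorithm.  Polytomies are resolved
#' into arbitrary bifurcations with zero-length branches; the sum of squared
#' contrasts (and hence any likelihood built from it) is invariant to the
#' arbitrary resolution.
#'
#' @param tree a `phylo`; branch lengths in time units (My).
#' @param x named numeric vector of tip values (names matching tip labels,
#'   underscores and spaces interchangeable); must be complete.
#' @return list with `contrasts` (standardised, one per internal node of the
#'   resolved tree), `raw`, `variance` (contrast variances, i.e. rescaled
#'   branch-length sums), `node` (node ids in the resolved tree), and
#'   `tree` (the resolved, postordered tree).
#' @export
independent_contrasts <- function(tree, x) {
  x <- check_trait(tree, x)
  pr <- bm_prune(resolve_tree(tree), x)
  list(contrasts = pr$contrasts, raw = pr$raw, variance = pr$cvar,
       node = pr$contrast_nodes, tree = pr$tree)
}

check_trait <- function(tree, x, what = "trait") {
  validate_tree(tree)
  x <- match_to_tips(tree, x, what)
  if (anyNA(x))
    stop(sprintf("missing %s values for: %s", what,
                 paste(names(x)[is.na(x)], collapse = ", ")))
  x
}

#' Fit a single-rate Brownian-motion model
#'
#' Estimates the Brownian rate of a continuous trait.  The default REML
#' estimate is the closed-form contrast estimator
#' `sigma2 = sum(u_i^2)/(n-1)` over standardised contrasts `u_i`, with the
#' restricted log-likelihood of the corresponding multivariate normal; the
#' ML variant divides by `n` and profiles the root state analytically.  No
#' numerical optimiser is involved, so there are no tolerance or
#' initialisation choices.  Rate units are (trait units)^2 per branch-length
#' unit (My for time-calibrated trees).
#'
#' @inheritParams independent_contrasts
#' @param method `"REML"` (default) or `"ML"`.
#' @param units optional human-readable trait unit label carried into the
#'   fit (e.g. `"bp/Mbp"`).
#' @return object of class `bm_fit`: `sigma2`, `root_state`, `loglik`
#'   (restricted for REML, full for ML), `method`, `node_estimates` and
#'   `node_var` (ancestral states and their variances, named by node id of
#'   the input tree), `n`, `units`.
#' @export
fit_bm <- function(tree, x, method = c("REML", "ML"), units = NULL) {
  method <- match.arg(method)
  x <- check_trait(tree, x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 tips")
  rtree <- resolve_tree(tree)
  pr <- bm_prune(rtree, x)
  ssq <- sum(pr$raw^2 / ifelse(pr$cvar > 0, pr$cvar, Inf))
  logv <- sum(log(pr$cvar))
  if (method == "REML") {
    sigma2 <- ssq / (n - 1)
    loglik <- if (sigma2 > 0)
      -0.5 * ((n - 1) * log(2 * pi * sigma2) + logv + (n - 1))
    else Inf  # constant trait: density degenerates
  } else {
    sigma2 <- ssq / n
    logdetC <- logv + log(pr$root_var)
    loglik <- if (sigma2 > 0)
      -0.5 * (n * log(2 * pi * sigma2) + logdetC + n)
    else Inf
  }
  anc <- bm_ancestral(tree, rtree, pr)
  structure(list(sigma2 = sigma2, root_state = pr$root_state,
                 loglik = loglik, method = method,
                 node_estimates = anc$estimate,
                 node_var = sigma2 * anc$scaled_var,
                 n = n, units = units),
            class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  u <- if (is.null(x$units)) "trait units" else x$units
  cat(sprintf("Brownian-motion fit (%s, n = %d tips)\n", x$method, x$n))
  cat(sprintf("  sigma^2    = %g (%s)^2 / My\n", x$sigma2, u))
  cat(sprintf("  root state = %g\n  log-lik    = %g\n", x$root_state, x$loglik))
  invisible(x)
}

## two-pass (down + up) ML/GLS ancestral states on the resolved tree,
## mapped back to the node ids of the original tree via clade keys
bm_ancestral <- function(orig, rtree, pr) {
  tree <- pr$tree                       # postordered resolved tree
  nt <- pr$ntip
  nn <- tree$Nnode
  e <- tree$edge
  el <- tree$edge.length
  uval <- numeric(nt + nn)
  uvar <- numeric(nt + nn)
  aval <- numeric(nt + nn)              # "above" estimate before the stem edge
  avar <- numeric(nt + nn)
  root <- pr$root
  ## preorder: reverse postorder edge order
  for (i in rev(seq_len(nrow(e)))) {
    k <- e[i, 1]; ch <- e[i, 2]
    ce <- pr$kids[[as.character(k)]]
    sib <- e[setdiff(ce, i), 2]
    vs <- pr$vlen[sib]
    if (k == root) {
      A <- dv <- pr$dval[sib]; Av <- vs
    } else {
      if (uvar[k] == 0) { A <- uval[k]; Av <- 0 }
      else if (vs == 0) { A <- pr$dval[sib]; Av <- 0 }
      else {
        Av <- 1 / (1 / uvar[k] + 1 / vs)
        A <- (uval[k] / uvar[k] + pr$dval[sib] / vs) * Av
      }
    }
    aval[ch] <- A; avar[ch] <- Av
    uval[ch] <- A
    uvar[ch] <- el[i] + Av
  }
  inner <- (nt + 1L):(nt + nn)
  est <- numeric(nn); svar <- numeric(nn)
  for (j in seq_along(inner)) {
    k <- inner[j]
    if (k == root) {
      est[j] <- pr$dval[k]; svar[j] <- pr$dvar[k]
    } else if (pr$dvar[k] == 0) {
      est[j] <- pr$dval[k]; svar[j] <- 0
    } else if (uvar[k] == 0) {
      est[j] <- uval[k]; svar[j] <- 0
    } else {
      prec <- 1 / pr$dvar[k] + 1 / uvar[k]
      est[j] <- (pr$dval[k] / pr$dvar[k] + uval[k] / uvar[k]) / prec
      svar[j] <- 1 / prec
    }
  }
  names(est) <- names(svar) <- as.character(inner)
  ## map back to original node ids when polytomies were resolved
  if (!identical(rtree, orig) && !ape::is.binary.phylo(orig)) {
    ko <- clade_keys(orig)
    kr <- clade_keys(tree)
    idx <- match(ko, kr)
    if (anyNA(idx)) stop("internal error: clade mapping failed")
    onodes <- as.character((ape::Ntip(orig) + 1L):(ape::Ntip(orig) + orig$Nnode))
    est <- stats::setNames(est[idx], onodes)
    svar <- stats::setNames(svar[idx], onodes)
  }
  list(estimate = est, scaled_var = svar,
       above_val = aval, above_var = avar, tree = tree)
}

#' Ancestral state estimates under Brownian motion
#'
#' Generalised-least-squares (equivalently joint ML) estimates of the trait
#' at every internal node, given a fitted Brownian rate.  Estimates are
#' invariant to rescaling `sigma2`; only the reported variances scale.
#'
#' @inheritParams independent_contrasts
#' @param fit optional [fit_bm()] result used only for its `sigma2` when
#'   scaling variances; refitted by REML when omitted.
#' @return data.frame with `node` (node id of the input tree), `estimate`,
#'   `variance`.
#' @export
ancestral_states <- function(tree, x, fit = NULL) {
  x <- check_trait(tree, x)
  if (is.null(fit)) fit <- fit_bm(tree, x)
  rtree <- resolve_tree(tree)
  pr <- bm_prune(rtree, x)
  anc <- bm_ancestral(tree, rtree, pr)
  data.frame(node = as.integer(names(anc$estimate)),
             estimate = unname(anc$estimate),
             variance = unname(fit$sigma2 * anc$scaled_var))
}

#' Per-lineage tip rates of trait evolution
#'
#' The recent-rate statistic: for each species, the difference between its
#' trait value and the ancestral estimate at the node it descends from,
#' divided by the length of its terminal branch.  The result is a signed
#' rate in trait units per My, describing change since the last sampled
#' speciation event.  By default the parent estimate is the joint GLS
#' estimate over all data (so the focal tip contributes to it);
#' `include_tip = FALSE` instead uses the estimate with the focal tip's
#' datum removed, for sensitivity analysis.
#'
#' @inheritParams independent_contrasts
#' @param include_tip logical; see Details.
#' @return data.frame with `species`, `rate`, `parent_estimate`,
#'   `branch_length`, satisfying
#'   `rate == (tip value - parent_estimate)/branch_length` exactly.
#' @export
tip_rates <- function(tree, x, include_tip = TRUE) {
  x <- check_trait(tree, x)
  nt <- ape::Ntip(tree)
  term <- match(seq_len(nt), tree$edge[, 2])
  bl <- tree$edge.length[term]
  if (any(bl <= 0))
    stop(sprintf("zero-length terminal branch for: %s",
                 paste(tree$tip.label[bl <= 0], collapse = ", ")))
  rtree <- resolve_tree(tree)
  pr <- bm_prune(rtree, x)
  anc <- bm_ancestral(rtree, rtree, pr)
  if (include_tip) {
    parent <- rtree$edge[match(seq_len(nt), rtree$edge[, 2]), 1]
    pe <- unname(anc$estimate[as.character(parent)])
  } else {
    ## the above-estimate at the tip, before its stem edge, is exactly the
    ## parent-node GLS estimate computed without the focal datum
    pe <- anc$above_val[seq_len(nt)]
  }
  ## terminal branch lengths are identical in the resolved tree
  bl2 <- rtree$edge.length[match(seq_len(nt), rtree$edge[, 2])]
  data.frame(species = rtree$tip.label,
             rate = (x[rtree$tip.label] - pe) / bl2,
             parent_estimate = pe,
             branch_length = bl2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Brownian rates per group of species
#'
#' Fits a single-rate Brownian model separately within each group (e.g.
#' taxonomic order) on the induced subtree of its members (no stem branch),
#' skipping groups below a minimum size.
#'
#' @inheritParams fit_bm
#' @param groups named character vector of group labels for every tip.
#' @param min_n minimum group size to fit (default 10).
#' @return named list of `bm_fit` objects for groups with `>= min_n`
#'   members; skipped groups are reported via `message()` and recorded in
#'   the `"skipped"` attribute.
#' @export
rates_by_group <- function(tree, x, groups, min_n = 10, method = "REML",
                           units = NULL) {
  x <- check_trait(tree, x)
  groups <- match_to_tips(tree, groups, "group label")
  tab <- table(groups)
  keep <- names(tab)[tab >= min_n]
  skip <- names(tab)[tab < min_n]
  if (length(skip))
    message(sprintf("skipping groups below %d members: %s", min_n,
                    paste(skip, collapse = ", ")))
  fits <- lapply(keep, function(g) {
    sub <- prune_to(tree, names(groups)[groups == g])
    fit_bm(sub, x[sub$tip.label], method = method, units = units)
  })
  names(fits) <- keep
  attr(fits, "skipped") <- skip
  fits
}
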