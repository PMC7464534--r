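## two-state transition probability matrix, closed form:
## P(t) = Pi + exp(-(q01+q10) t) (I - Pi), rows of Pi = stationary dist
mk_pmat <- function(q01, q10, t) {
  q <- q01 + q10
  if (q == 0) return(diag(2))
  p1 <- q10 / q; p2 <- q01 / q
  ept <- exp(-q * t)
  matrix(c(p1 + p2 * ept, p1 * (1 - ept),
           p2 * (1 - ept), p2 + p1 * ept), 2, 2)
}

## coerce tip states to a 2-level factor matched to the tree's tips;
## NA = missing/ambiguous (partial likelihood 1 in both states)
mk_states <- function(tree, tip_states, states = NULL) {
  validate_tree(tree)
  st <- match_to_tips(tree, tip_states, "tip state")
  if (is.null(states)) {
    states <- sort(unique(as.character(st[!is.na(st)])))
    if (length(states) == 0L) stop("all tip states missing")
    if (length(states) == 1L)
      states <- c(states, paste0("not_", states))  # degenerate but admissible
    if (length(states) > 2L)
      stop(sprintf("more than two states observed: %s",
                   paste(states, collapse = ", ")))
  }
  f <- factor(as.character(st), levels = states)
  if (any(!is.na(st) & is.na(f)))
    stop("tip states outside the declared state set")
  f
}

mk_root_prior <- function(root_prior, q01, q10, states) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == 2L, all(root_prior >= 0),
              sum(root_prior) > 0)
    return(root_prior / sum(root_prior))
  }
  switch(match.arg(root_prior, c("flat", "stationary")),
         flat = c(0.5, 0.5),
         stationary = {
           q <- q01 + q10
           if (q == 0) c(0.5, 0.5) else c(q10, q01) / q
         })
}

## scaled pruning: per-node conditional likelihood vectors plus log scaler
mk_partials <- function(tree, f, q01, q10) {
  nt <- ape::Ntip(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  e <- tree$edge; el <- tree$edge.length
  nn <- tree$Nnode
  L <- matrix(1, nt + nn, 2)
  obs <- !is.na(f)
  L[seq_len(nt)[obs], ] <- 0
  L[cbind(seq_len(nt)[obs], as.integer(f)[obs])] <- 1
  logscale <- 0
  kids <- split(seq_len(nrow(e)), e[, 1])
  parents <- unique(e[, 1])
  Pedge <- vector("list", nrow(e))
  for (i in seq_len(nrow(e)))
    Pedge[[i]] <- mk_pmat(q01, q10, el[i])
  for (k in parents) {
    ce <- kids[[as.character(k)]]
    v <- c(1, 1)
    for (i in ce) v <- v * as.vector(Pedge[[i]] %*% L[e[i, 2], ])
    m <- max(v)
    if (m <= 0) return(list(valid = FALSE))
    L[k, ] <- v / m
    logscale <- logscale + log(m)
  }
  list(valid = TRUE, L = L, logscale = logscale, tree = tree,
       root = parents[length(parents)], Pedge = Pedge, kids = kids)
}

#' Log-likelihood of a two-state Markov (Mk) model
#'
#' Felsenstein pruning with the closed-form two-state transition matrix.
#' `q01` is the transition rate from the first to the second state (per My),
#' `q10` the reverse.  Missing tip states contribute a partial likelihood of
#' 1 in both states.
#'
#' @param tree a `phylo` with branch lengths.
#' @param tip_states named vector of states (two levels; NA = missing).
#' @param q01,q10 non-negative transition rates.
#' @param root_prior `"flat"` (default), `"stationary"`, or a numeric
#'   2-vector of root-state weights.
#' @param states optional explicit 2-vector giving the state levels (first
#'   level = state "0" of `q01`).
#' @return log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, q01, q10, root_prior = "flat",
                      states = NULL) {
  if (q01 < 0 || q10 < 0) stop("rates must be non-negative")
  f <- mk_states(tree, tip_states, states)
  pr <- mk_partials(resolve_tree(tree), f, q01, q10)
  if (!pr$valid) return(-Inf)
  prior <- mk_root_prior(root_prior, q01, q10, levels(f))
  lik <- sum(prior * pr$L[pr$root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale
}

#' Fit an all-rates-different two-state Mk model
#'
#' Maximises [mk_loglik()] over `(q01, q10)` with Nelder-Mead searches on
#' the log-rate scale from multiple starting points (scaled to tree height).
#' When only one state is observed the ML rates sit on the zero boundary;
#' the fit is returned flagged `degenerate` with a warning.
#'
#' @inheritParams mk_loglik
#' @return object of class `mk_fit`: `q01`, `q10`, `loglik`, `states`,
#'   `root_prior`, `converged`, `degenerate`.
#' @export
fit_mk_ard <- function(tree, tip_states, root_prior = "flat", states = NULL) {
  f <- mk_states(tree, tip_states, states)
  states <- levels(f)
  rtree <- resolve_tree(tree)
  degenerate <- length(unique(stats::na.omit(as.character(f)))) < 2L
  if (degenerate)
    warning("only one state observed; rate estimates lie on the zero boundary")
  h <- max(ape::node.depth.edgelength(rtree))
  nll <- function(lq) {
    q <- exp(lq)
    if (any(!is.finite(q))) return(1e10)
    ll <- mk_loglik(rtree, stats::setNames(as.character(f), rtree$tip.label),
                    q[1], q[2], root_prior = root_prior, states = states)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- expand.grid(a = log(c(0.1, 1, 10) / h), b = log(c(0.1, 1, 10) / h))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  q <- exp(best$par)
  if (degenerate) q <- pmin(q, 1e-8)
  structure(list(q01 = q[1], q10 = q[2], loglik = -best$value,
                 states = states, root_prior = root_prior,
                 converged = best$convergence == 0,
                 degenerate = degenerate),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Two-state Mk fit (all rates different)\n")
  cat(sprintf("  %s -> %s: %g / My\n", x$states[1], x$states[2], x$q01))
  cat(sprintf("  %s -> %s: %g / My\n", x$states[2], x$states[1], x$q10))
  cat(sprintf("  log-lik %g%s%s\n", x$loglik,
              if (x$converged) "" else " (optimiser did not converge)",
              if (x$degenerate) " [degenerate: single observed state]" else ""))
  invisible(x)
}

## endpoint-conditioned path on one branch by uniformization: exact
## conditional sampling of the number and placement of state changes
sample_path_uniformization <- function(a, b, t, q01, q10, pmat = NULL) {
  omega <- max(q01, q10)
  if (omega == 0 || t == 0) {
    if (a != b) stop("impossible endpoint combination with zero rates")
    return(a)  # state sequence of length 1 (single segment)
  }
  Q <- matrix(c(-q01, q10, q01, -q10), 2, 2)
  R <- diag(2) + Q / omega
  if (is.null(pmat)) pmat <- mk_pmat(q01, q10, t)
  pab <- pmat[a, b]
  ## sample N | endpoints: P(N=n) = dpois(n, omega t) R^n[a,b] / pab
  u <- stats::runif(1) * pab
  Rpow <- list(diag(2))
  n <- 0L
  acc <- stats::dpois(0, omega * t) * Rpow[[1]][a, b]
  while (acc < u && n < 10000L) {
    n <- n + 1L
    Rpow[[n + 1L]] <- Rpow[[n]] %*% R
    acc <- acc + stats::dpois(n, omega * t) * Rpow[[n + 1L]][a, b]
  }
  if (n == 0L) return(a)
  ## state sequence across the n uniformized jumps (forward sampling with
  ## backward weights); self-transitions are virtual and collapse later
  s <- integer(n + 1L)
  s[1] <- a
  for (k in seq_len(n)) {
    back <- Rpow[[n - k + 1L]][, b]
    w <- R[s[k], ] * back
    s[k + 1L] <- sample.int(2L, 1L, prob = w)
  }
  if (s[n + 1L] != b) stop("internal error: path endpoint mismatch")
  s
}

## assemble segment durations (parent -> child order) from a jump-state
## sequence and sorted jump times on a branch of length t
collapse_path <- function(s, jump_times, t, state_names) {
  if (length(s) == 1L) {
    seg <- stats::setNames(t, state_names[s])
    return(seg)
  }
  bounds <- c(0, jump_times, t)
  keep <- c(TRUE, diff(s) != 0)          # drop virtual (self) jumps
  starts <- bounds[-length(bounds)][keep]
  states <- s[keep]
  durs <- diff(c(starts, t))
  stats::setNames(durs, state_names[states])
}

#' Sample stochastic character maps
#'
#' Draws full histories of the two-state character conditional on the
#' observed tip states and fitted transition rates: node states are sampled
#' from their joint conditional distribution (root from prior x conditional
#' likelihoods, then descending), and each branch's internal history is
#' sampled exactly, conditional on its endpoint states, by uniformization.
#' Missing tip states are sampled along with the nodes.
#'
#' @inheritParams mk_loglik
#' @param fit an [fit_mk_ard()] result (or any list with `q01`, `q10`,
#'   `states`, `root_prior`).
#' @param nmaps number of maps to draw.
#' @return a `simmap` object (single map) or list of them: the tree with
#'   `$maps` (per-edge named duration vectors, parent-to-child order),
#'   `$mapped.edge` (per-edge time in each state), `$node_state`, and
#'   `$states` (tip states used, sampled where missing).  Uses the global
#'   RNG stream; seed with [set.seed()] for reproducibility.
#' @export
sample_stochastic_map <- function(tree, tip_states, fit, nmaps = 1) {
  f <- mk_states(tree, tip_states, fit$states)
  rtree <- resolve_tree(tree)
  pr <- mk_partials(rtree, f, fit$q01, fit$q10)
  if (!pr$valid) stop("data have zero likelihood under the fitted rates")
  prior <- mk_root_prior(fit$root_prior, fit$q01, fit$q10, levels(f))
  maps <- lapply(seq_len(nmaps), function(i)
    draw_one_map(pr, prior, fit$q01, fit$q10, levels(f)))
  if (nmaps == 1L) maps[[1]] else maps
}

draw_one_map <- function(pr, prior, q01, q10, state_names) {
  tree <- pr$tree
  nt <- ape::Ntip(tree)
  e <- tree$edge; el <- tree$edge.length
  nnode <- nt + tree$Nnode
  ns <- integer(nnode)
  w <- prior * pr$L[pr$root, ]
  ns[pr$root] <- sample.int(2L, 1L, prob = w)
  ## preorder: parents before children
  for (i in rev(seq_len(nrow(e)))) {
    a <- ns[e[i, 1]]
    ch <- e[i, 2]
    w <- pr$Pedge[[i]][a, ] * pr$L[ch, ]
    ns[ch] <- sample.int(2L, 1L, prob = w)
  }
  maps <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    a <- ns[e[i, 1]]; b <- ns[e[i, 2]]
    s <- sample_path_uniformization(a, b, el[i], q01, q10, pr$Pedge[[i]])
    jt <- if (length(s) > 1L) sort(stats::runif(length(s) - 1L)) * el[i]
          else numeric(0)
    maps[[i]] <- collapse_path(s, jt, el[i], state_names)
  }
  build_simmap(tree, maps, state_names, ns)
}

## assemble a phytools-compatible simmap object
build_simmap <- function(tree, maps, state_names, node_state) {
  tree$maps <- maps
  me <- matrix(0, nrow(tree$edge), length(state_names),
               dimnames = list(paste(tree$edge[, 1], tree$edge[, 2], sep = ","),
                               state_names))
  for (i in seq_along(maps)) {
    agg <- tapply(maps[[i]], names(maps[[i]]), sum)
    me[i, names(agg)] <- agg
  }
  tree$mapped.edge <- me
  tree$node_state <- stats::setNames(state_names[node_state],
                                     c(tree$tip.label,
                                       seq_len(tree$Nnode) + ape::Ntip(tree)))
  tree$states <- tree$node_state[seq_len(ape::Ntip(tree))]
  class(tree) <- c("simmap", class(tree))
  attr(tree, "map.order") <- "right-to-left"
  tree
}

#' Validate stochastic-map invariants
#'
#' Checks that segment durations on every branch sum to the branch length,
#' adjacent segments differ in state, the first segment of each branch
#' matches the parent node's state, and the last matches the child's.
#'
#' @param map a `simmap`.
#' @param tol absolute tolerance on duration sums.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_simmap <- function(map, tol = 1e-9) {
  stopifnot(inherits(map, "simmap") || !is.null(map$maps))
  e <- map$edge
  for (i in seq_len(nrow(e))) {
    seg <- map$maps[[i]]
    if (abs(sum(seg) - map$edge.length[i]) > tol)
      stop(sprintf("edge %d: segment durations do not sum to branch length", i))
    st <- names(seg)
    if (length(st) > 1L && any(st[-1] == st[-length(st)]))
      stop(sprintf("edge %d: adjacent segments share a state", i))
    if (!is.null(map$node_state)) {
      key <- function(n) if (n <= length(map$tip.label)) map$tip.label[n]
                         else as.character(n)
      if (st[1] != map$node_state[key(e[i, 1])])
        stop(sprintf("edge %d: first segment != parent state", i))
      if (st[length(st)] != map$node_state[key(e[i, 2])])
        stop(sprintf("edge %d: last segment != child state", i))
    }
  }
  invisible(TRUE)
}

#' Time spent in each state across a map
#' @param map a `simmap`.
#' @return named numeric: total branch time in each state.
#' @export
state_times <- function(map) {
  colSums(map$mapped.edge)
}

#' Write / read stochastic maps (SIMMAP-annotated Newick)
#'
#' Serialisation to the SIMMAP dialect (`{state,duration:...}` branch
#' annotations), via phytools' writer and reader for interchange with other
#' tools.  Round-trips preserve topology and segment structure to the
#' writer's printed precision.
#'
#' @param map a `simmap` or list of them.
#' @param path file path.
#' @export
write_simmap_file <- function(map, path) {
  phytools::write.simmap(map, file = path)
  invisible(path)
}

#' @rdname write_simmap_file
#' @return for the reader: a `simmap` (or `multiSimmap` for multi-map
#'   files).
#' @export
read_simmap_file <- function(path) {
  phytools::read.simmap(path, format = "phylip", version = 1)
}
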