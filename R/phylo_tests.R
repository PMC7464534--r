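## classical one-way ANOVA F statistics, vectorised over columns of ymat
anova_f <- function(ymat, group) {
  g <- as.factor(group)
  k <- nlevels(g)
  n <- nrow(ymat)
  cnt <- as.vector(table(g))
  gm <- rowsum(ymat, g) / cnt               # group means (k x m)
  tot <- colMeans(ymat)
  ssb <- colSums(cnt * (gm - rep(tot, each = k))^2)
  ssw <- colSums((ymat - gm[as.integer(g), , drop = FALSE])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Phylogenetic ANOVA with a simulation null
#'
#' Classical one-way F statistic on the tip values, assessed against a null
#' distribution of F statistics obtained by simulating a single-rate
#' Brownian trait on the phylogeny (rate estimated from the observed data
#' by REML, ignoring group structure) and recomputing F with the observed
#' group labels.  The empirical p-value uses the plus-one correction,
#' `(#{F_sim >= F_obs} + 1)/(n_sim + 1)`.  The classical (non-phylogenetic)
#' ANOVA p-value is reported alongside for comparison.  Uses the global RNG
#' stream; seed with [set.seed()].
#'
#' @param tree a `phylo`.
#' @param y named numeric tip trait (complete).
#' @param group named group labels; at least 2 groups of at least 2 members.
#' @param n_sim number of null simulations (default 100).
#' @return object of class `phylo_anova`: `f_obs`, `p_phylo`, `p_standard`,
#'   `n_sim`, `df`.
#' @export
phylo_anova <- function(tree, y, group, n_sim = 100) {
  y <- check_trait(tree, y)
  group <- match_to_tips(tree, group, "group label")
  g <- droplevels(as.factor(group))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L))
    stop(sprintf("groups with fewer than 2 members: %s",
                 paste(names(table(g))[table(g) < 2], collapse = ", ")))
  n <- length(y)
  k <- nlevels(g)
  f_obs <- anova_f(matrix(y, ncol = 1), g)
  p_standard <- stats::pf(f_obs, k - 1, n - k, lower.tail = FALSE)
  sigma2 <- fit_bm(tree, y)$sigma2
  sims <- simulate_bm(tree, sigma2, root_value = 0, nsim = n_sim)$tips
  f_sim <- anova_f(sims, g)
  structure(list(f_obs = unname(f_obs),
                 p_phylo = (sum(f_sim >= f_obs) + 1) / (n_sim + 1),
                 p_standard = unname(p_standard),
                 n_sim = n_sim, df = c(k - 1, n - k)),
            class = "phylo_anova")
}

#' @export
print.phylo_anova <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic ANOVA: F(%d,%d) = %.4g, p_phylo = %.4g (%d sims), p_standard = %.4g\n",
    x$df[1], x$df[2], x$f_obs, x$p_phylo, x$n_sim, x$p_standard))
  invisible(x)
}

## restricted (or full) BM log-likelihood with per-edge effective lengths;
## sigma2 is profiled out in closed form, so only the state-rate ratio needs
## numerical work in the censored test
bm_profile_loglik <- function(tree, x, lengths, method = "REML") {
  tree$edge.length <- lengths
  pr <- bm_prune(tree, x)
  n <- length(x)
  ssq <- sum(pr$raw^2 / ifelse(pr$cvar > 0, pr$cvar, Inf))
  logv <- sum(log(pr$cvar))
  if (method == "REML") {
    s <- ssq / (n - 1)
    list(scale = s,
         loglik = -0.5 * ((n - 1) * log(2 * pi * s) + logv + (n - 1)))
  } else {
    s <- ssq / n
    list(scale = s,
         loglik = -0.5 * (n * log(2 * pi * s) + logv + log(pr$root_var) + n))
  }
}

#' Censored two-rate Brownian test on a stochastic map
#'
#' Compares a single-rate Brownian model for a continuous trait with a
#' model in which each state of the mapped discrete character (e.g.
#' holocentric vs monocentric) carries its own rate on the branch segments
#' it paints.  The two-rate restricted likelihood is computed by rescaling
#' each branch to the effective length `sum(sigma2_state * duration)` and
#' evaluating the contrast-based restricted likelihood; the rate pair is
#' optimised by profiling on the rate ratio, with the overall scale in
#' closed form.  Models are compared by a likelihood-ratio test
#' (chi-squared, 1 df), with the AIC difference also reported.
#'
#' @param map a `simmap` (tree with `$mapped.edge`).
#' @param x named numeric tip trait.
#' @param alpha significance level for declaring the two-rate model favored.
#' @param method `"REML"` (default, mirroring restricted-likelihood rate
#'   comparisons) or `"ML"`.
#' @return object of class `censored_test`: `sigma2_single`,
#'   `sigma2_by_state` (named), `loglik_single`, `loglik_two`, `lrt_stat`,
#'   `p_lrt`, `delta_aic` (AIC_single - AIC_two; positive favors two
#'   rates), `favored`, `degenerate`.
#' @export
censored_rate_test <- function(map, x, alpha = 0.05, method = c("REML", "ML")) {
  method <- match.arg(method)
  if (is.null(map$mapped.edge)) stop("map must carry a mapped.edge matrix")
  tree <- map
  class(tree) <- "phylo"
  if (!ape::is.binary.phylo(tree))
    stop("censored_rate_test requires a binary mapped tree")
  x <- check_trait(tree, x)
  n <- length(x)
  states <- colnames(map$mapped.edge)
  if (length(states) != 2L) stop("map must have exactly two states")
  ptree <- ape::reorder.phylo(tree, "postorder")
  ## state-time matrix reordered to match the postordered edges
  key <- paste(tree$edge[, 1], tree$edge[, 2], sep = ",")
  pkey <- paste(ptree$edge[, 1], ptree$edge[, 2], sep = ",")
  Tmat <- map$mapped.edge[match(pkey, key), , drop = FALSE]
  one <- bm_profile_loglik(ptree, x, ptree$edge.length, method)
  tot <- colSums(Tmat)
  if (any(tot <= 0)) {
    absent <- states[tot <= 0]
    return(structure(list(
      sigma2_single = one$scale,
      sigma2_by_state = stats::setNames(rep(one$scale, 2), states),
      loglik_single = one$loglik, loglik_two = one$loglik,
      lrt_stat = 0, p_lrt = 1, delta_aic = -2,
      favored = "one_rate", degenerate = TRUE, absent_state = absent,
      alpha = alpha, method = method), class = "censored_test"))
  }
  ## profile restricted likelihood over log rate ratio r = sigma2_2/sigma2_1
  prof <- function(logr) {
    bm_profile_loglik(ptree, x, Tmat[, 1] + exp(logr) * Tmat[, 2],
                      method)$loglik
  }
  opt <- stats::optimize(prof, interval = c(-16, 16), maximum = TRUE,
                         tol = 1e-8)
  ## the one-rate model is nested at r = 1; guard against optimiser misses
  if (opt$objective < one$loglik) {
    opt <- list(maximum = 0, objective = prof(0))
  }
  r <- exp(opt$maximum)
  fit2 <- bm_profile_loglik(ptree, x, Tmat[, 1] + r * Tmat[, 2], method)
  s1 <- fit2$scale
  lrt <- 2 * (fit2$loglik - one$loglik)
  if (lrt < -1e-8) stop("internal error: two-rate likelihood below one-rate")
  lrt <- max(lrt, 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(
    sigma2_single = one$scale,
    sigma2_by_state = stats::setNames(c(s1, s1 * r), states),
    loglik_single = one$loglik, loglik_two = fit2$loglik,
    lrt_stat = lrt, p_lrt = p,
    delta_aic = (2 * 1 - 2 * one$loglik) - (2 * 2 - 2 * fit2$loglik),
    favored = if (p < alpha) "two_rate" else "one_rate",
    degenerate = FALSE, alpha = alpha, method = method),
    class = "censored_test")
}

#' @export
print.censored_test <- function(x, ...) {
  cat(sprintf("Censored rate test (%s)\n", x$method))
  cat(sprintf("  one rate : sigma^2 = %.6g, logL = %.4f\n",
              x$sigma2_single, x$loglik_single))
  cat(sprintf("  two rates: %s = %.6g, %s = %.6g, logL = %.4f\n",
              names(x$sigma2_by_state)[1], x$sigma2_by_state[1],
              names(x$sigma2_by_state)[2], x$sigma2_by_state[2],
              x$loglik_two))
  cat(sprintf("  LRT = %.4g (df 1), p = %.4g, dAIC = %.3f -> %s%s\n",
              x$lrt_stat, x$p_lrt, x$delta_aic, x$favored,
              if (x$degenerate) " [degenerate map]" else ""))
  invisible(x)
}

#' Censored rate test over a set of stochastic maps
#'
#' Runs [censored_rate_test()] on each map (e.g. one per posterior tree)
#' and tallies how many favored the two-rate model, along with the
#' distribution of per-state rates and of the between-state rate
#' difference.
#'
#' @param maps list of `simmap` objects (or a `multiSimmap`).
#' @inheritParams censored_rate_test
#' @return object of class `censored_summary`: `results` (per-map tests),
#'   `n_maps`, `n_two_rate`, and `rates` (data.frame with per-map
#'   per-state `sigma2` and their difference, second state minus first).
#' @export
censored_over_maps <- function(maps, x, alpha = 0.05, method = "REML") {
  if (inherits(maps, "simmap")) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  results <- lapply(maps, censored_rate_test, x = x, alpha = alpha,
                    method = method)
  states <- names(results[[1]]$sigma2_by_state)
  rates <- data.frame(map = seq_along(results),
                      s1 = vapply(results, function(r) r$sigma2_by_state[1],
                                  numeric(1)),
                      s2 = vapply(results, function(r) r$sigma2_by_state[2],
                                  numeric(1)))
  names(rates)[2:3] <- states
  rates$difference <- rates[[3]] - rates[[2]]
  structure(list(results = results, n_maps = length(results),
                 n_two_rate = sum(vapply(results, function(r)
                   r$favored == "two_rate", logical(1))),
                 rates = rates, states = states),
            class = "censored_summary")
}

#' @export
print.censored_summary <- function(x, ...) {
  cat(sprintf("Censored rate test over %d stochastic maps\n", x$n_maps))
  cat(sprintf("  %d of %d favored a two-rate model\n", x$n_two_rate, x$n_maps))
  cat(sprintf("  median sigma^2: %s = %.6g, %s = %.6g (difference %.6g)\n",
              x$states[1], stats::median(x$rates[[2]]),
              x$states[2], stats::median(x$rates[[3]]),
              stats::median(x$rates$difference)))
  invisible(x)
}

#' Phylogenetic linear model (PGLS under Brownian motion)
#'
#' Generalised least squares with residual covariance `sigma2 * C`, where
#' `C` holds shared root-to-tip path lengths:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`, with the ML residual variance.
#' Coefficient t-tests use the (n-k)-denominator variance estimate.
#' Confidence intervals come from a parametric bootstrap: responses are
#' re-simulated as `X beta + Brownian noise`, refit, and summarised by
#' percentiles.  Species with missing response or predictor values are
#' dropped (with a message) and the tree pruned accordingly.  Uses the
#' global RNG stream; seed with [set.seed()].
#'
#' @param tree a `phylo`.
#' @param y named numeric response.
#' @param X predictor matrix or data.frame with species as rownames (an
#'   intercept is added automatically); pass `NULL` for an intercept-only
#'   model.
#' @param n_boot bootstrap replicates (default 100).
#' @param conf confidence level for percentile intervals.
#' @return object of class `phylo_lm`: `coefficients` (data.frame with
#'   `term`, `estimate`, `se`, `t`, `p`, `ci_lo`, `ci_hi`), `sigma2` (ML),
#'   `loglik`, `n`, `n_dropped`, `n_boot`.
#' @export
phylo_lm <- function(tree, y, X = NULL, n_boot = 100, conf = 0.95) {
  validate_tree(tree)
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = length(y), ncol = 0)
    rownames(X) <- names(y)
  }
  X <- as.matrix(X)
  if (is.null(rownames(X))) {
    if (nrow(X) != length(y)) stop("X rows must match y")
    rownames(X) <- names(y)
  }
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  common <- intersect(normalize_labels(names(y)),
                      normalize_labels(tree$tip.label))
  yl <- y[match(common, normalize_labels(names(y)))]
  Xl <- X[match(common, normalize_labels(rownames(X))), , drop = FALSE]
  cc <- !is.na(yl) & stats::complete.cases(Xl)
  n_dropped <- sum(!cc)
  if (n_dropped > 0)
    message(sprintf("dropping %d species with missing values", n_dropped))
  keep <- common[cc]
  if (length(keep) < ncol(X) + 2L) stop("too few complete cases")
  tr <- if (length(keep) < ape::Ntip(tree)) prune_to(tree, tree$tip.label[
    match(keep, normalize_labels(tree$tip.label))]) else tree
  ord <- match(normalize_labels(tr$tip.label), normalize_labels(keep))
  yv <- as.numeric(yl[cc][ord])
  M <- cbind(`(Intercept)` = 1, Xl[cc, , drop = FALSE][ord, , drop = FALSE])
  k <- ncol(M)
  qrM <- qr(M)
  if (qrM$rank < k)
    stop(sprintf("collinear design columns: %s",
                 paste(colnames(M)[-seq_len(qrM$rank)], collapse = ", ")))
  C <- ape::vcv(tr)
  R <- chol(C)
  tM <- backsolve(R, M, transpose = TRUE)
  ty <- backsolve(R, yv, transpose = TRUE)
  fit <- stats::lm.fit(tM, ty)
  beta <- fit$coefficients
  Q <- sum(fit$residuals^2)
  n <- length(yv)
  s2_ml <- Q / n
  s2_unb <- Q / (n - k)
  XtX_inv <- chol2inv(qr.R(qr(tM)))
  se <- sqrt(diag(XtX_inv) * s2_unb)
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df = n - k, lower.tail = FALSE)
  loglik <- -0.5 * (n * log(2 * pi * s2_ml) + 2 * sum(log(diag(R))) +
                      Q / s2_ml)
  ## parametric bootstrap: y* = M beta + BM noise; in the whitened basis
  ## the noise is iid normal, so refits are a single matrix product
  A <- XtX_inv %*% t(tM)
  mu_t <- as.vector(tM %*% beta)
  Z <- matrix(stats::rnorm(n * n_boot), n, n_boot)
  B <- A %*% (mu_t + sqrt(s2_ml) * Z)
  a <- (1 - conf) / 2
  ci <- t(apply(B, 1, stats::quantile, probs = c(a, 1 - a)))
  coef_tab <- data.frame(term = colnames(M), estimate = unname(beta),
                         se = unname(se), t = unname(tstat), p = unname(pval),
                         ci_lo = unname(ci[, 1]), ci_hi = unname(ci[, 2]),
                         stringsAsFactors = FALSE)
  structure(list(coefficients = coef_tab, sigma2 = s2_ml, loglik = loglik,
                 n = n, n_dropped = n_dropped, n_boot = n_boot, conf = conf),
            class = "phylo_lm")
}

#' @export
print.phylo_lm <- function(x, ...) {
  cat(sprintf("Phylogenetic linear model (n = %d%s, sigma^2 = %.6g)\n",
              x$n, if (x$n_dropped) sprintf(", %d dropped", x$n_dropped)
              else "", x$sigma2))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("  log-lik %.4f; %d bootstrap replicates, %.0f%% CIs\n",
              x$loglik, x$n_boot, 100 * x$conf))
  invisible(x)
}

#' Phylogenetic linear models across a set of trees
#'
#' Fits [phylo_lm()] on every tree of a posterior sample and tallies, per
#' predictor, how many trees gave a significant slope and the slope-sign
#' counts.
#'
#' @param trees a `multiPhylo` or list of `phylo` trees sharing the data's
#'   species.
#' @inheritParams phylo_lm
#' @param alpha per-tree significance level.
#' @return object of class `phylo_lm_set`: `fits` (per-tree `phylo_lm`),
#'   `tally` (data.frame per non-intercept term: `n_trees`,
#'   `n_significant`, `n_positive`, `n_negative`).
#' @export
lm_over_trees <- function(trees, y, X = NULL, n_boot = 100, alpha = 0.05) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1L)
  base_tips <- sort(normalize_labels(trees[[1]]$tip.label))
  for (i in seq_along(trees)) {
    ti <- sort(normalize_labels(trees[[i]]$tip.label))
    if (!identical(ti, base_tips))
      stop(sprintf("tree %d tip set differs from tree 1: %s", i,
                   paste(union(setdiff(ti, base_tips),
                               setdiff(base_tips, ti)), collapse = ", ")))
  }
  fits <- lapply(trees, function(tr)
    phylo_lm(tr, y = y, X = X, n_boot = n_boot))
  terms <- setdiff(fits[[1]]$coefficients$term, "(Intercept)")
  tally <- do.call(rbind, lapply(terms, function(tm) {
    est <- vapply(fits, function(f)
      f$coefficients$estimate[f$coefficients$term == tm], numeric(1))
    p <- vapply(fits, function(f)
      f$coefficients$p[f$coefficients$term == tm], numeric(1))
    data.frame(term = tm, n_trees = length(fits),
               n_significant = sum(p < alpha),
               n_positive = sum(est > 0), n_negative = sum(est < 0),
               stringsAsFactors = FALSE)
  }))
  structure(list(fits = fits, tally = tally, alpha = alpha),
            class = "phylo_lm_set")
}

#' @export
print.phylo_lm_set <- function(x, ...) {
  cat(sprintf("Phylogenetic linear models over %d trees (alpha = %g)\n",
              length(x$fits), x$alpha))
  print(x$tally, row.names = FALSE)
  invisible(x)
}
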