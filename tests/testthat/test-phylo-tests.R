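star_tree <- function(n, bl = 1) {
  st <- ape::stree(n, "star")
  st$edge.length <- rep(bl, n)
  st
}

test_that("phylogenetic ANOVA handles degenerate and star-tree cases", {
  set.seed(103)
  st <- star_tree(20)
  # identical group means and within-group values: F = 0, p = 1
  y0 <- stats::setNames(rep(c(0, 1, 2, 3, 4), 4), st$tip.label)
  g <- stats::setNames(rep(c("a", "b"), 10), st$tip.label)
  r0 <- phylo_anova(st, y0, g, n_sim = 50)
  expect_equal(r0$f_obs, 0)
  expect_equal(r0$p_phylo, 1)
  expect_error(phylo_anova(st, y0, stats::setNames(c("a", rep("b", 19)),
                                                   st$tip.label), n_sim = 10),
               "fewer than 2")
  # observed F equals the classical linear-model F
  y <- stats::setNames(rnorm(20), st$tip.label)
  y[11:20] <- y[11:20] + 1
  r <- phylo_anova(st, y, g, n_sim = 100)
  expect_equal(r$f_obs, anova_f_lm(y[st$tip.label], g[st$tip.label]),
               tolerance = 1e-10)
  expect_gte(r$p_phylo, 1 / 101)
  expect_lte(r$p_phylo, 1)
})

test_that("on a star tree the simulation null converges to the classical p", {
  set.seed(107)
  st <- star_tree(24)
  g <- stats::setNames(rep(c("a", "b", "c"), each = 8), st$tip.label)
  y <- stats::setNames(rnorm(24), st$tip.label)
  y[g == "b"] <- y[g == "b"] + 1.0
  r <- phylo_anova(st, y, g, n_sim = 5000)
  expect_lt(abs(r$p_phylo - r$p_standard), 0.02)
})

test_that("censored test collapses correctly on single-state maps", {
  set.seed(109)
  tr <- simulate_bd_tree(30, 0.2, 0.05)
  m <- simulate_mk(tr, 0, 0, root_state = 2)   # all monocentric
  x <- simulate_bm(tr, 2)$tips[, 1]
  res <- censored_rate_test(m, x)
  expect_true(res$degenerate)
  expect_equal(res$lrt_stat, 0)
  expect_equal(unname(res$sigma2_by_state),
               rep(res$sigma2_single, 2))
  expect_equal(res$favored, "one_rate")
})

test_that("two-rate likelihood is never below one-rate (nesting)", {
  set.seed(113)
  for (i in 1:10) {
    tr <- simulate_bd_tree(40, 0.2, 0.05)
    m <- simulate_mk(tr, 0.03, 0.03)
    if (length(unique(m$states)) < 2) next
    x <- simulate_bm(tr, 1)$tips[, 1]
    res <- censored_rate_test(m, x)
    expect_gte(res$loglik_two, res$loglik_single - 1e-8)
    expect_gte(res$lrt_stat, 0)
    expect_equal(res$lrt_stat,
                 2 * (res$loglik_two - res$loglik_single), tolerance = 1e-12)
  }
})

test_that("censored test agrees with the restricted-likelihood reference", {
  # independent cross-check against phytools' brownieREML on true histories
  set.seed(127)
  for (i in 1:5) {
    tr <- simulate_bd_tree(40, 0.2, 0.05)
    m <- simulate_mk(tr, 0.03, 0.03)
    if (length(unique(m$states)) < 2) next
    x <- simulate_bm_two_rate(m, c(holocentric = 1, monocentric = 8))$tips[, 1]
    res <- censored_rate_test(m, x)
    ref <- phytools::brownieREML(m, x)
    expect_equal(res$sigma2_single, ref$sig2.single, tolerance = 1e-4)
    expect_equal(res$loglik_single, ref$logL1, tolerance = 1e-6)
    expect_equal(unname(res$sigma2_by_state),
                 unname(ref$sig2.multiple[names(res$sigma2_by_state)]),
                 tolerance = 1e-3)
    expect_equal(res$loglik_two, ref$logL.multiple, tolerance = 1e-4)
  }
})

test_that("censored_over_maps tallies per-map outcomes", {
  set.seed(131)
  tr <- simulate_bd_tree(40, 0.2, 0.05)
  m <- simulate_mk(tr, 0.03, 0.03)
  x <- simulate_bm_two_rate(m, c(holocentric = 1, monocentric = 10))$tips[, 1]
  single <- censored_rate_test(m, x)
  summ <- censored_over_maps(list(m, m, m), x)
  expect_equal(summ$n_maps, 3L)
  expect_equal(summ$rates$difference,
               rep(single$sigma2_by_state[2] - single$sigma2_by_state[1], 3),
               ignore_attr = TRUE)
  expect_equal(summ$n_two_rate, 3L * (single$favored == "two_rate"))
  one <- censored_over_maps(m, x)
  expect_equal(one$results[[1]]$lrt_stat, single$lrt_stat)
})

test_that("phylo_lm equals OLS on star trees and GLS closed forms", {
  set.seed(137)
  st <- star_tree(25)
  xv <- rnorm(25)
  y <- stats::setNames(2 + 0.5 * xv + rnorm(25), st$tip.label)
  X <- matrix(xv, ncol = 1, dimnames = list(st$tip.label, "x"))
  f <- phylo_lm(st, y, X, n_boot = 20)
  ols <- stats::coef(stats::lm(y ~ xv))
  expect_lt(max(abs(f$coefficients$estimate - ols)), 1e-8)
  # intercept-only: GLS mean
  tr <- simulate_bd_tree(30, 0.2, 0.05)
  y2 <- stats::setNames(rnorm(30), tr$tip.label)
  f0 <- phylo_lm(tr, y2, NULL, n_boot = 10)
  C <- ape::vcv(tr); Ci <- solve(C); one <- rep(1, 30)
  mu <- as.numeric(t(one) %*% Ci %*% y2[rownames(C)] /
                     (t(one) %*% Ci %*% one))
  expect_equal(f0$coefficients$estimate[1], mu, tolerance = 1e-10)
  # collinear design named in the error
  Xc <- cbind(a = xv, b = 2 * xv)
  rownames(Xc) <- st$tip.label
  expect_error(phylo_lm(st, y, Xc, n_boot = 5), "collinear.*b")
  # missing predictors dropped with a message
  Xm <- X; Xm[1, 1] <- NA
  expect_message(fm <- phylo_lm(st, y, Xm, n_boot = 5), "dropping 1")
  expect_equal(fm$n, 24L)
})

test_that("lm_over_trees tallies significance and sign per tree", {
  set.seed(139)
  tr <- simulate_bd_tree(40, 0.2, 0.05)
  xv <- rnorm(40)
  X <- matrix(xv, ncol = 1, dimnames = list(tr$tip.label, "x"))
  y <- stats::setNames(1 + 2 * xv + simulate_bm(tr, 0.2)$tips[, 1],
                       tr$tip.label)
  single <- phylo_lm(tr, y, X, n_boot = 10)
  res <- lm_over_trees(list(tr), y, X, n_boot = 10)
  expect_equal(res$fits[[1]]$coefficients$estimate,
               single$coefficients$estimate)
  expect_equal(res$tally$n_trees, 1L)
  # strong effect on several jittered trees: all significant, same sign
  trees <- lapply(1:5, function(i) {
    tj <- tr
    tj$edge.length <- tj$edge.length * stats::rlnorm(length(tj$edge.length),
                                                     0, 0.05)
    tj
  })
  res5 <- lm_over_trees(trees, y, X, n_boot = 10)
  expect_equal(res5$tally$n_significant, 5L)
  expect_equal(res5$tally$n_positive, 5L)
  # mismatched tip sets are rejected with the offending taxa listed
  tr2 <- simulate_bd_tree(40, 0.2, 0.05)
  tr2$tip.label <- paste0("z", 1:40)
  expect_error(lm_over_trees(list(tr, tr2), y, X), "differs")
})
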