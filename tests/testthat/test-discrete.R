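test_that("Mk likelihood matches limits and hand enumeration on a cherry", {
  tr <- read_newick("(A:1,B:1);")
  # q -> 0: both tips must equal the root; flat prior -> log(1/2)
  ll0 <- mk_loglik(tr, c(A = "0", B = "0"), 1e-12, 1e-12, states = c("0", "1"))
  expect_equal(ll0, log(0.5), tolerance = 1e-6)
  # symmetric rates, states (0,1): direct sum over root states
  q <- 0.5
  P <- function(t) {
    ep <- exp(-2 * q * t)
    matrix(c((1 + ep) / 2, (1 - ep) / 2, (1 - ep) / 2, (1 + ep) / 2), 2, 2)
  }
  hand <- log(0.5 * (P(1)[1, 1] * P(1)[1, 2] + P(1)[2, 1] * P(1)[2, 2]))
  expect_equal(mk_loglik(tr, c(A = "0", B = "1"), q, q, states = c("0", "1")),
               hand, tolerance = 1e-12)
  expect_error(mk_loglik(tr, c(A = "0", B = "1"), -1, 1), "non-negative")
})

test_that("pruning equals brute-force enumeration on small random trees", {
  set.seed(61)
  for (i in 1:15) {
    tr <- simulate_bd_tree(sample(4:10, 1), 0.3, 0.1)
    s <- stats::setNames(sample(0:1, ape::Ntip(tr), TRUE), tr$tip.label)
    q1 <- runif(1, 0.01, 1); q2 <- runif(1, 0.01, 1)
    expect_lt(abs(mk_loglik(tr, s, q1, q2, states = c("0", "1")) -
                    mk_loglik_enum(tr, s, q1, q2)), 1e-10)
  }
})

matrixStats_logsum <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(max(a, b))
  m + log(exp(a - m) + exp(b - m))
}

test_that("missing tip states contribute partial likelihood one", {
  set.seed(67)
  tr <- simulate_bd_tree(8, 0.3, 0.1)
  s <- stats::setNames(c(0, 1, NA, 0, 1, NA, 0, 1), tr$tip.label)
  llm <- mk_loglik(tr, s, 0.3, 0.2, states = c("0", "1"))
  # oracle: marginalise the missing tips by summing over their states
  idx <- which(is.na(s))
  tot <- -Inf
  for (a in 0:1) for (b in 0:1) {
    sf <- s; sf[idx] <- c(a, b)
    tot <- matrixStats_logsum(tot, mk_loglik_enum(tr, sf, 0.3, 0.2))
  }
  expect_equal(llm, tot, tolerance = 1e-10)
})

test_that("ARD fit recovers symmetry and beats the truth in likelihood", {
  set.seed(71)
  tr <- simulate_bd_tree(150, 0.1, 0.02)
  h <- max(ape::node.depth.edgelength(tr))
  q <- 2 / h
  sim <- simulate_mk(tr, q, q, states = c("0", "1"))
  fit <- fit_mk_ard(tr, sim$states)
  expect_true(fit$converged)
  # ML optimum at least as good as the generating rates
  ll_truth <- mk_loglik(tr, sim$states, q, q, states = c("0", "1"))
  expect_gte(fit$loglik, ll_truth - 1e-6)
  # symmetric truth: estimates within a factor of ~4 of each other
  expect_lt(abs(log(fit$q01 / fit$q10)), log(8))
  # single observed state: degenerate boundary fit
  mono <- stats::setNames(rep("0", ape::Ntip(tr)), tr$tip.label)
  expect_warning(fitd <- fit_mk_ard(tr, mono, states = c("0", "1")),
                 "one state")
  expect_true(fitd$degenerate)
  expect_lt(fitd$q01, 1e-6)
})

test_that("sampled stochastic maps satisfy all structural invariants", {
  set.seed(73)
  tr <- simulate_bd_tree(40, 0.2, 0.05)
  sim <- simulate_mk(tr, 0.05, 0.08)
  expect_true(validate_simmap(sim))
  fit <- fit_mk_ard(tr, sim$states)
  maps <- sample_stochastic_map(tr, sim$states, fit, nmaps = 10)
  for (m in maps) {
    expect_true(validate_simmap(m))
    # tip-adjacent segment states equal the observed states
    expect_equal(unname(m$states[names(sim$states)]), unname(sim$states))
    # durations per edge sum to branch lengths
    expect_equal(unname(rowSums(m$mapped.edge)), m$edge.length,
                 tolerance = 1e-9)
  }
})

test_that("zero rates with monomorphic tips give transition-free maps", {
  set.seed(79)
  tr <- simulate_bd_tree(12, 0.3, 0.05)
  s <- stats::setNames(rep("m", 12), tr$tip.label)
  fit <- list(q01 = 0, q10 = 0, states = c("h", "m"), root_prior = "flat")
  m <- sample_stochastic_map(tr, s, fit)
  expect_true(all(lengths(m$maps) == 1L))
  expect_true(all(vapply(m$maps, names, character(1)) == "m"))
})

test_that("uniformization change-counts match the analytic conditional law", {
  # single branch, endpoints 0 -> 0, symmetric rates q: real state changes
  # occur at constant rate q, so the unconditional count is Poisson(q t)
  # and conditioning on 0 -> 0 keeps exactly the even counts:
  # P(K = k | 0 -> 0) = dpois(k, q t) / P(even), truncated analytically
  q <- 0.7; t <- 1.5
  kmax <- 20L
  ks <- seq(0L, kmax, by = 2L)
  pk <- stats::dpois(ks, q * t) / ((1 + exp(-2 * q * t)) / 2)
  set.seed(83)
  uni <- replicate(20000, {
    s <- msatphylo:::sample_path_uniformization(1L, 1L, t, q, q)
    sum(diff(s) != 0)
  })
  expect_true(all(uni %% 2 == 0))
  ot <- table(factor(uni, levels = ks))
  keep <- pk > 1e-5
  chi <- suppressWarnings(
    stats::chisq.test(ot[keep], p = pk[keep] / sum(pk[keep])))
  expect_gt(chi$p.value, 0.01)
  expect_lt(abs(mean(uni) - sum(ks * pk)), 0.03)
})

test_that("map-averaged time in a state tracks the true simulated histories", {
  set.seed(89)
  tr <- simulate_bd_tree(80, 0.1, 0.02)
  truth_frac <- replicate(40, {
    sim <- simulate_mk(tr, 0.02, 0.02)
    st <- state_times(sim)
    st["monocentric"] / sum(st)
  })
  sim <- simulate_mk(tr, 0.02, 0.02)
  fit <- list(q01 = 0.02, q10 = 0.02, states = c("holocentric", "monocentric"),
              root_prior = "flat")
  maps <- sample_stochastic_map(tr, sim$states, fit, nmaps = 40)
  frac <- vapply(maps, function(m) {
    st <- state_times(m); unname(st["monocentric"] / sum(st))
  }, numeric(1))
  # conditional on data the fraction is biased toward the realised history,
  # but it must stay inside the generative range
  expect_gt(mean(frac), min(truth_frac) - 0.1)
  expect_lt(mean(frac), max(truth_frac) + 0.1)
})

test_that("simmap files round-trip through the annotated-Newick dialect", {
  set.seed(97)
  tr <- simulate_bd_tree(15, 0.3, 0.05)
  sim <- simulate_mk(tr, 0.08, 0.05)
  f <- tempfile(fileext = ".smap")
  write_simmap_file(sim, f)
  back <- read_simmap_file(f)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  st0 <- state_times(sim)
  st1 <- colSums(back$mapped.edge)[names(st0)]
  expect_equal(unname(st1), unname(st0), tolerance = 1e-6)
})
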