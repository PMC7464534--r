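test_that("birth-death trees are ultrametric with the requested tip count", {
  set.seed(149)
  for (i in 1:10) {
    n <- sample(3:50, 1)
    tr <- simulate_bd_tree(n, 0.3, 0.1)
    expect_equal(ape::Ntip(tr), n)
    expect_true(is_ultrametric(tr))
    expect_true(all(tr$edge.length >= 0))
  }
  expect_error(simulate_bd_tree(10, 0.1, 0.2), "birth > death")
  expect_error(simulate_bd_tree(2, 0.1, 0), "n_taxa")
})

test_that("pure-birth lineage growth matches the Yule expectation", {
  # E[N(t)] = 2 exp(birth * t) for a reconstructed pure-birth tree started
  # from 2 lineages; check the time to reach n instead: for Yule,
  # E[T_n] = sum_{k=2}^{n-1} 1/(birth*k)
  set.seed(151)
  birth <- 0.5; n <- 20
  ages <- replicate(400, {
    tr <- simulate_bd_tree(n, birth, 0)
    max(ape::node.depth.edgelength(tr))
  })
  expected <- sum(1 / (birth * 2:(n - 1)))
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - expected), 4 * se + 0.05 * expected)
})

test_that("Brownian simulation reproduces its variance structure", {
  tr <- read_newick("(A:1,B:1);")
  expect_equal(unname(simulate_bm(tr, 0, root_value = 3)$tips[, 1]),
               c(3, 3))
  set.seed(157)
  d <- simulate_bm(tr, 2, nsim = 20000)$tips
  v <- var(d["A", ] - d["B", ])
  expect_lt(abs(v - 4) / 4, 0.05)   # Var(xA - xB) = 2 sigma2
  # cross-tip covariance matches sigma2 * C on a fixed tree
  tr6 <- read_newick("(((A:1,B:1):1,C:2):1,(D:2,E:2):1);")
  sims <- simulate_bm(tr6, 1.5, nsim = 20000)$tips
  C <- ape::vcv(tr6)[rownames(sims), rownames(sims)]
  emp <- cov(t(sims))
  expect_lt(max(abs(emp - 1.5 * C)), 0.2)
})

test_that("two-rate Brownian reduces to single-rate when rates are equal", {
  set.seed(163)
  tr <- simulate_bd_tree(30, 0.2, 0.05)
  m <- simulate_mk(tr, 0.05, 0.05)
  a <- simulate_bm_two_rate(m, c(holocentric = 2, monocentric = 2),
                            nsim = 3000)$tips
  b <- simulate_bm(tr, 2, nsim = 3000)$tips
  # same per-tip marginal variance
  expect_lt(max(abs(apply(a, 1, var) - apply(b[rownames(a), ], 1, var)) /
                  apply(b[rownames(a), ], 1, var)), 0.25)
  # one state with rate zero accrues variance only from the other state
  z <- simulate_bm_two_rate(m, c(holocentric = 0, monocentric = 1),
                            nsim = 3000)$tips
  ev <- as.vector(m$mapped.edge %*% c(holocentric = 0, monocentric = 1))
  # per-tip variance = summed effective variance on the root-to-tip path
  ptree <- m; class(ptree) <- "phylo"
  paths <- ape::nodepath(ptree)
  key <- paste(ptree$edge[, 1], ptree$edge[, 2], sep = ",")
  for (i in seq_len(5)) {
    tip <- i
    pth <- paths[[tip]]
    eidx <- match(paste(pth[-length(pth)], pth[-1], sep = ","), key)
    expect_lt(abs(var(z[ptree$tip.label[tip], ]) - sum(ev[eidx])) /
                max(sum(ev[eidx]), 1e-9), 0.25)
  }
})

test_that("Markov simulation matches closed-form transition probabilities", {
  set.seed(167)
  tr <- read_newick("(A:1,B:1);")
  q <- 0.4
  flips <- replicate(20000, {
    m <- simulate_mk(tr, q, q, root_state = 1, states = c("0", "1"))
    m$states[["A"]] == "1"
  })
  p01 <- (1 - exp(-2 * q)) / 2
  expect_lt(abs(mean(flips) - p01), 0.01)
  # zero rates: tips inherit the root state, no transitions
  m0 <- simulate_mk(tr, 0, 0, root_state = 2, states = c("0", "1"))
  expect_true(all(m0$states == "1"))
  expect_true(all(lengths(m0$maps) == 1L))
})

test_that("long-run state frequency approaches the stationary distribution", {
  set.seed(173)
  tr <- simulate_bd_tree(150, 0.1, 0)
  tr$edge.length <- tr$edge.length * 50   # deep tree: many expected changes
  q01 <- 0.02; q10 <- 0.01
  fr <- mean(replicate(20, {
    m <- simulate_mk(tr, q01, q10, states = c("0", "1"))
    mean(m$states == "1")
  }))
  expect_lt(abs(fr - q01 / (q01 + q10)), 0.12)
})

test_that("synthetic genomes carry exact oracle-derived truth tables", {
  set.seed(179)
  g0 <- synth_genome(1000, NULL, gc = 0.5)
  expect_identical(g0$truth[, locus_cols],
                   scan_sequence("synth", g0$seq)[, locus_cols])
  # one (AC)8 plant: a period-2 locus spanning at least 16 bp at the site
  g1 <- synth_genome(500, data.frame(motif = "AC", copies = 8, start = 100),
                     gc = 0.5)
  hit <- g1$truth[g1$truth$period == 2 & g1$truth$start <= 100 &
                    g1$truth$end >= 116, ]
  expect_equal(nrow(hit), 1L)
  expect_gte(hit$end - hit$start, 16L)
  # overlapping plants rejected
  expect_error(synth_genome(500, data.frame(motif = c("AC", "AG"),
                                            copies = c(8, 8),
                                            start = c(100, 110))),
               "overlap")
  expect_error(synth_genome(100, data.frame(motif = "AC", copies = 8,
                                            start = 95)),
               "outside")
})

test_that("planted repeats across a large genome are recovered set-identically", {
  set.seed(181)
  periods <- sample(2:6, 50, replace = TRUE)
  plants <- data.frame(
    motif = vapply(periods, msatphylo:::random_primitive_motif, character(1)),
    copies = sample(6:15, 50, replace = TRUE))
  g <- synth_genome(100000, plants, gc = 0.4)
  fast <- scan_sequence("synth", g$seq)
  expect_identical(fast[, locus_cols], g$truth[, locus_cols])
  # every sufficiently long plant appears inside some reported locus
  minc <- c(`2` = 6, `3` = 4, `4` = 3, `5` = 3, `6` = 3)
  p <- nchar(g$plants$motif)
  strong <- g$plants$copies >= minc[as.character(p)]
  covered <- vapply(which(strong), function(i)
    any(fast$start <= g$plants$start[i] & fast$end >= g$plants$end[i]),
    logical(1))
  expect_true(all(covered))
})

test_that("simulate_study is deterministic and honours its configuration", {
  cfg <- study_sim_config(n_taxa = 30, n_trees = 4, genome_length = 3000,
                          busco_low_frac = 0.2, seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$trait_table, s2$trait_table)
  expect_identical(write_newick(s1$trees[[3]]), write_newick(s2$trees[[3]]))
  expect_identical(s1$genomes[[5]]$seq, s2$genomes[[5]]$seq)
  # structure
  expect_equal(nrow(s1$trait_table), 30L)
  expect_length(s1$trees, 4L)
  for (tr in s1$trees) expect_true(is_ultrametric(tr, rel_tol = 1e-8))
  expect_true(validate_simmap(s1$truth$history))
  expect_equal(sum(s1$trait_table$busco_score < 0.9), 6L)
  expect_setequal(s1$trait_table$species[s1$trait_table$busco_score < 0.9],
                  s1$truth$busco_low)
  expect_true(all(s1$trait_table$centromere_type %in%
                    c("holocentric", "monocentric")))
  expect_length(s1$genomes, 30L)
})
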