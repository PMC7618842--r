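test_that("marginal ASR matches symmetry and limiting cases", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  st <- setNames(c(1, 2), c("A", "B"))
  asr <- marginal_asr(tr, st, er2_Q(0.7))
  expect_equal(unname(attr(asr, "root")), c(0.5, 0.5), tolerance = 1e-12)
  # vanishing rates with identical tips: root certain
  st2 <- setNames(c(1, 1), c("A", "B"))
  asr2 <- marginal_asr(tr, st2, er2_Q(1e-8))
  expect_gt(attr(asr2, "root")[1], 0.999)
  # rows sum to one
  expect_equal(rowSums(asr), 1, ignore_attr = TRUE)
  # unfitted / malformed model argument errors
  expect_error(marginal_asr(tr, st, list(oops = 1)), "fitted")
})

test_that("marginal ASR equals enumeration on small trees", {
  set.seed(131)
  for (i in 1:8) {
    n <- sample(3:5, 1)
    k <- sample(2:3, 1)
    tr <- ape::rcoal(n)
    tr$edge.length <- tr$edge.length + 0.1
    st <- setNames(sample(seq_len(k), n, TRUE), tr$tip.label)
    Q <- random_Q(k)
    got <- marginal_asr(tr, st, Q)
    want <- enum_asr(tr, st, Q)
    expect_equal(unname(got[, , drop = FALSE]), want, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("summarize_root aggregates per-tree vectors", {
  same <- rbind(c(0.7, 0.3), c(0.7, 0.3), c(0.7, 0.3))
  s <- summarize_root(same)
  expect_equal(s$mean, c(0.7, 0.3))
  expect_equal(s$upper - s$lower, c(0, 0))
  two <- rbind(c(1, 0), c(0, 1))
  expect_equal(summarize_root(two)$mean, c(0.5, 0.5))
})

test_that("joint transition counting equals discordant-edge counting", {
  set.seed(141)
  tr <- scale_branch_lengths(simulate_tree(60, 1, 0, seed = 141), 0.1)
  sim <- simulate_discrete(tr, er2_Q(0.4), seed = 142)
  fit <- fit_mk_ml(tr, sim$tip_states,
                   constraint_map(matrix(c(NA, "shared:r", "shared:r", NA),
                                         2, 2)), seed = 1)
  Q <- er2_Q(fit$params[["r"]])
  ct <- count_transitions(tr, sim$tip_states, Q, method = "joint")
  # internal consistency: summary mean equals the per-tree tally
  expect_equal(sum(ct$summary$mean), sum(ct$per_tree[[1]]))
  expect_equal(nrow(ct$transitions[[1]]), sum(ct$per_tree[[1]]))
  # no variation -> zero counts
  same <- setNames(rep(1L, 60), tr$tip.label)
  ct0 <- count_transitions(tr, same, er2_Q(0.01), method = "joint")
  expect_equal(sum(ct0$summary$mean), 0)
})

test_that("stochastic maps average at least as many events as joint counts", {
  set.seed(151)
  tr <- scale_branch_lengths(simulate_tree(80, 1, 0, seed = 151), 0.1)
  diffs <- replicate(5, {
    sim <- simulate_discrete(tr, er2_Q(0.6))
    Q <- er2_Q(0.6)
    joint <- sum(count_transitions(tr, sim$tip_states, Q,
                                   method = "joint")$summary$mean)
    stoch <- sum(count_transitions(tr, sim$tip_states, Q,
                                   method = "stochastic",
                                   n_maps = 20)$summary$mean)
    stoch - joint
  })
  expect_gte(mean(diffs), 0)
})

test_that("ancestral_continuous reproduces BM limiting cases", {
  tr <- simulate_tree(8, 1, 0, seed = 161)
  const <- setNames(rep(2.5, 8), tr$tip.label)
  anc <- ancestral_continuous(tr, const)
  expect_equal(anc$estimate, rep(2.5, nrow(anc)), tolerance = 1e-9)
  # star tree: root estimate is the tip mean
  st <- star_tree(6)
  vals <- setNames(rnorm(6), st$tip.label)
  anc2 <- ancestral_continuous(st, vals)
  expect_equal(anc2$estimate[1], mean(vals), tolerance = 1e-9)
  # root equals the GLS phylogenetic mean (cross-module consistency)
  set.seed(162)
  y <- simulate_continuous_bm(tr, 1, 0)$tip_values
  anc3 <- ancestral_continuous(tr, y)
  C <- phylo_covariance(tr)[tr$tip.label, tr$tip.label]
  Ci <- solve(C)
  mu <- sum(Ci %*% y[tr$tip.label]) / sum(Ci)
  expect_equal(anc3$estimate[1], mu, tolerance = 1e-9)
})

test_that("ancestral_continuous node estimates are unbiased and calibrated", {
  set.seed(171)
  tr <- simulate_tree(50, 1, 0, seed = 171)
  err <- c(); hit <- c()
  for (i in 1:40) {
    sim <- simulate_continuous_bm(tr, sigma2 = 1, root_value = 0)
    anc <- ancestral_continuous(tr, sim$tip_values)
    truth <- sim$node_values[as.character(anc$node)]
    err <- c(err, anc$estimate - truth)
    hit <- c(hit, abs(anc$estimate - truth) <= 1.96 * anc$se)
  }
  expect_lt(abs(mean(err)), 0.1)
  expect_gt(mean(hit), 0.85)
  expect_lte(mean(hit), 1.0)
})

test_that("transition_context_compare contrasts and degenerate cases", {
  tr <- simulate_tree(20, 1, 0, seed = 181)
  ntip <- 20L
  vals <- rep(1.5, ntip + tr$Nnode)  # constant trait
  trans <- data.frame(parent = ntip + c(2L, 4L), child = c(1L, 2L))
  res <- transition_context_compare(tr, list(trans), list(vals),
                                    mode = "origin-vs-nonorigin")
  expect_equal(res$mean_difference, 0)
  res2 <- transition_context_compare(tr, list(trans), list(vals),
                                     mode = "before-vs-after")
  expect_equal(res2$mean_difference, 0)
  # no transitions: typed empty result
  none <- data.frame(parent = integer(0), child = integer(0))
  res3 <- transition_context_compare(tr, list(none), list(vals))
  expect_true(res3$empty)
  expect_equal(res3$n_transitions, 0L)
})

test_that("planted high-value origins are detected by the origin contrast", {
  set.seed(191)
  hits <- 0L
  for (rep in 1:10) {
    tr <- simulate_tree(40, 1, 0)
    ntip <- 40L
    bm <- simulate_continuous_bm(tr, 1, 0)
    vals <- c(bm$tip_values[tr$tip.label], bm$node_values)
    internal <- (ntip + 1L):(ntip + tr$Nnode)
    # plant transitions at the 3 largest-value internal nodes
    origin <- internal[order(bm$node_values, decreasing = TRUE)[1:3]]
    ch <- vapply(origin, function(p) tr$edge[tr$edge[, 1] == p, 2][1], 0)
    trans <- data.frame(parent = origin, child = ch)
    res <- transition_context_compare(tr, list(trans), list(vals),
                                      mode = "origin-vs-nonorigin")
    if (res$mean_difference > 0) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
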