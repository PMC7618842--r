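test_that("build_rate_matrix honours free, zero and shared labels", {
  specs <- multistate_model_specs()
  # sequential: exactly the 6 adjacent off-diagonals can be nonzero
  seq_groups <- castevol:::constraint_groups(specs$SEQUENTIAL)$groups
  Q <- build_rate_matrix(setNames(seq(0.1, 0.6, by = 0.1), seq_groups),
                         specs$SEQUENTIAL)
  off <- which(Q > 0, arr.ind = TRUE)
  expect_equal(nrow(off), 6L)
  expect_true(all(abs(off[, 1] - off[, 2]) == 1))
  expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12)

  # all-zero parameters give the zero matrix
  Q0 <- build_rate_matrix(setNames(rep(0, 6), seq_groups), specs$SEQUENTIAL)
  expect_equal(Q0, matrix(0, 4, 4))

  # shared groups propagate one rate to all members
  cm <- pagel_cm <- castevol:::pagel_constraints()$independent
  Qp <- build_rate_matrix(c(A_gain = 1, A_loss = 2, B_gain = 3, B_loss = 4),
                          cm)
  expect_equal(Qp[1, 3], Qp[2, 4])
  expect_equal(Qp[3, 1], Qp[4, 2])

  expect_error(build_rate_matrix(setNames(rep(-1, 6), seq_groups),
                                 specs$SEQUENTIAL), "nonnegative")
  expect_error(build_rate_matrix(c(nope = 1), specs$SEQUENTIAL), "missing")
})

test_that("pruning likelihood handles the analytic edge cases", {
  # two tips on zero-length branches, both state 1, flat root over 4 states
  tr <- ape::read.tree(text = "(A:0,B:0);")
  Q <- random_Q(4)
  st <- setNames(c(1, 1), c("A", "B"))
  expect_equal(mk_loglik(tr, st, Q, root_mode = "flat"), log(0.25),
               tolerance = 1e-12)
  # fully ambiguous tips carry no information: logL = 0 under any Q
  sta <- setNames(rep(NA_character_, 2), c("A", "B"))
  expect_equal(mk_loglik(tr, sta, Q), 0, tolerance = 1e-12)
  set.seed(2)
  tr8 <- simulate_tree(8, 1, 0, seed = 2)
  sta8 <- setNames(rep(NA_character_, 8), tr8$tip.label)
  expect_equal(mk_loglik(tr8, sta8, random_Q(3)), 0, tolerance = 1e-10)
  # impossible data under a zero matrix: -Inf sentinel, not an error
  expect_identical(mk_loglik(tr, setNames(c(1, 2), c("A", "B")),
                             matrix(0, 2, 2)), -Inf)
})

test_that("pruning equals brute-force enumeration on random micro-instances", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:5, 1)
    k <- sample(2:4, 1)
    tr <- ape::rcoal(n)
    tr$edge.length <- tr$edge.length + 0.05
    st <- setNames(sample(seq_len(k), n, TRUE), tr$tip.label)
    # mix in an ambiguous tip
    if (k > 2 && runif(1) < 0.5) st[1] <- paste(1:2, collapse = "/")
    Q <- random_Q(k)
    mode <- sample(c("flat", "stationary"), 1)
    expect_equal(mk_loglik(tr, st, Q, root_mode = mode),
                 brute_force_loglik(tr, st, Q, root_mode = mode),
                 tolerance = 1e-10)
  }
  # enumeration refuses large trees
  big <- simulate_tree(30, 1, 0, seed = 3)
  expect_error(brute_force_loglik(big, setNames(rep(1, 30), big$tip.label),
                                  er2_Q(1)), "internal nodes")
})

test_that("fit_mk_ml maximizes the likelihood and reports AIC", {
  set.seed(41)
  tr <- scale_branch_lengths(simulate_tree(150, 1, 0, seed = 41), 0.1)
  truth <- 0.8
  sim <- simulate_discrete(tr, er2_Q(truth), seed = 42)
  cm <- constraint_map(matrix(c(NA, "shared:r", "shared:r", NA), 2, 2))
  fit <- fit_mk_ml(tr, sim$tip_states, cm, seed = 1)
  expect_equal(fit$n_free, 1L)
  expect_equal(fit$AIC, 2 * 1 - 2 * fit$logL)
  expect_gt(fit$params[["r"]], truth / 3)
  expect_lt(fit$params[["r"]], truth * 3)
  # the ML point beats nearby rates
  for (r in c(0.5, 2) * fit$params[["r"]])
    expect_gte(fit$logL, mk_loglik(tr, sim$tip_states, er2_Q(r)) - 1e-6)
  # a fully zero constraint cannot be built
  expect_error(constraint_map(matrix("zero", 2, 2)), "free or shared")
  expect_error(fit_mk_ml(tr, setNames(rep(1, 150), tr$tip.label), cm),
               "distinct states")
})

test_that("mcmc_sample recovers the prior when data are uninformative", {
  set.seed(51)
  tr <- simulate_tree(10, 1, 0, seed = 51)
  cm <- constraint_map(matrix(c(NA, "shared:r", "shared:r", NA), 2, 2))
  amb <- setNames(rep(NA_character_, 10), tr$tip.label)
  ch <- mcmc_sample(tr, amb, cm, prior = prior_spec(0.1),
                    settings = mcmc_settings(iterations = 60000L,
                                             burn_in = 5000L, thinning = 10L,
                                             n_chains = 1L, seed = 5))
  expect_true(all(abs(ch$samples$logL) < 1e-9))
  # compare sampled rates with direct draws from the hierarchical prior
  set.seed(6)
  direct <- rexp(5000, 1 / runif(5000, 0, 0.1))
  ks <- suppressWarnings(stats::ks.test(ch$samples$r, direct))
  expect_gt(ks$p.value, 0.01)
  expect_gt(ch$acceptance_rate, 0.05)
})

test_that("mcmc_sample mixes over a tree set and logs acceptance", {
  set.seed(61)
  tr <- scale_branch_lengths(simulate_tree(40, 1, 0, seed = 61), 0.1)
  ts <- jitter_tree_set(tr, n_trees = 4, seed = 62)
  sim <- simulate_discrete(tr, er2_Q(0.5), seed = 63)
  cm <- constraint_map(matrix(c(NA, "free", "free", NA), 2, 2))
  ch <- mcmc_sample(ts, sim$tip_states, cm,
                    settings = mcmc_settings(iterations = 20000L,
                                             burn_in = 2000L, thinning = 10L,
                                             n_chains = 1L, seed = 7))
  expect_true(length(unique(ch$samples$tree_index)) > 1L)
  expect_false(is.na(ch$tree_acceptance_rate))
  # two independent chains agree by Gelman-Rubin
  ch2 <- mcmc_sample(ts, sim$tip_states, cm,
                     settings = mcmc_settings(iterations = 20000L,
                                              burn_in = 2000L, thinning = 10L,
                                              n_chains = 1L, seed = 8))
  n <- min(nrow(ch$samples), nrow(ch2$samples))
  psrf <- gelman_rubin(list(ch$samples$logL[1:n], ch2$samples$logL[1:n]))
  expect_lt(psrf, 1.2)
})

test_that("stepping stone handles the degenerate exact cases", {
  set.seed(71)
  tr <- simulate_tree(6, 1, 0, seed = 71)
  Q <- er2_Q(0.4)
  st <- setNames(sample(1:2, 6, TRUE), tr$tip.label)
  # fixed Q (no free parameters): lnML is exactly the log-likelihood
  m <- stepping_stone_log_marginal(tr, st, fixed_Q = Q)
  expect_equal(m$log_marginal, mk_loglik(tr, st, Q))
  # fully ambiguous data: lnML = 0
  amb <- setNames(rep(NA_character_, 6), tr$tip.label)
  cm <- constraint_map(matrix(c(NA, "shared:r", "shared:r", NA), 2, 2))
  m0 <- stepping_stone_log_marginal(tr, amb, cm, ss = ss_settings(5, 50),
                                    seed = 1)
  expect_equal(m0$log_marginal, 0, tolerance = 1e-9)
  # reproducible under seed
  m1 <- stepping_stone_log_marginal(tr, st, cm, ss = ss_settings(10, 100),
                                    seed = 3)
  m2 <- stepping_stone_log_marginal(tr, st, cm, ss = ss_settings(10, 100),
                                    seed = 3)
  expect_identical(m1$log_marginal, m2$log_marginal)
})

test_that("stepping-stone spread shrinks with more iterations per stone", {
  set.seed(81)
  tr <- simulate_tree(5, 1, 0, seed = 81)
  st <- setNames(c(1, 2, 1, 2, 1), tr$tip.label)
  cm <- constraint_map(matrix(c(NA, "shared:r", "shared:r", NA), 2, 2))
  est <- function(iters, seeds) vapply(seeds, function(s)
    stepping_stone_log_marginal(tr, st, cm, ss = ss_settings(15, iters),
                                seed = s)$log_marginal, 0)
  sd_small <- sd(est(60, 1:8))
  sd_large <- sd(est(1200, 1:8))
  expect_lt(sd_large, sd_small)
})

test_that("bayes_factor arithmetic, labels and antisymmetry", {
  expect_equal(bayes_factor(-10, -10), list(BF = 0, label = "minimal"))
  expect_equal(bayes_factor(-6, -10)$BF, 8)
  expect_equal(bayes_factor(-6, -10)$label, "strong")
  expect_equal(bayes_factor(-4.5, -10)$BF, 11)
  expect_equal(bayes_factor(-4.5, -10)$label, "very strong")
  expect_equal(bayes_factor(-9, -10)$label, "positive")
  expect_equal(bayes_factor(-10, -6)$BF, -bayes_factor(-6, -10)$BF)
  expect_error(bayes_factor(-Inf, -1), "finite")
})

test_that("stationary distribution solves pi Q = 0", {
  Q <- random_Q(4)
  p <- stationary_dist(Q)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(as.numeric(p %*% Q), rep(0, 4), tolerance = 1e-10)
})
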