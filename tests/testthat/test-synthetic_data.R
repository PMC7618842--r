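test_that("simulate_tree is reproducible, ultrametric and validated", {
  t1 <- simulate_tree(10, 1, 0.3, seed = 5)
  t2 <- simulate_tree(10, 1, 0.3, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_equal(length(t1$tip.label), 10L)
  t3 <- simulate_tree(3, 1, 0, seed = 1)
  expect_equal(t3$Nnode, 2L)
  expect_error(simulate_tree(10, 1, 1.5), "death")
  expect_error(simulate_tree(2, 1, 0), "n_tips")
})

test_that("Yule tree depth matches the closed-form expectation", {
  # E[depth] under Yule(lambda) with n tips = sum_{k=2}^{n} 1/(lambda k)
  n <- 8; lambda <- 1
  expected <- sum(1 / (lambda * 2:n))
  set.seed(77)
  depths <- replicate(500, max(ape::node.depth.edgelength(
    ape::rphylo(n, lambda, 0))))
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 3 * se)
})

test_that("simulate_discrete records exact event truth", {
  tr <- simulate_tree(20, 1, 0, seed = 8)
  # zero rate matrix: everything stays in the root state
  Q0 <- matrix(0, 3, 3)
  sim <- simulate_discrete(tr, Q0, root_dist = c(0, 1, 0), seed = 2)
  expect_true(all(sim$tip_states == 2))
  expect_equal(sum(sim$counts), 0)
  expect_equal(nrow(sim$events), 0L)

  # structural zeros of a sequential matrix never generate events
  Qs <- sequential_Q(1)
  sim2 <- simulate_discrete(tr, Qs, root_dist = c(1, 0, 0, 0), seed = 3)
  forbidden <- rbind(c(1, 3), c(1, 4), c(2, 4), c(3, 1), c(4, 1), c(4, 2))
  expect_true(all(sim2$counts[forbidden] == 0))
  if (nrow(sim2$events))
    expect_true(all(abs(sim2$events$from - sim2$events$to) == 1))
  # counts equal the event tally
  expect_equal(sum(sim2$counts), nrow(sim2$events))

  # determinism
  sim3 <- simulate_discrete(tr, Qs, root_dist = c(1, 0, 0, 0), seed = 3)
  expect_identical(sim2$tip_states, sim3$tip_states)
  expect_identical(sim2$counts, sim3$counts)
})

test_that("2-state symmetric event count matches the Poisson expectation", {
  tr <- simulate_tree(15, 1, 0, seed = 12)
  r <- 0.5
  L <- sum(tr$edge.length)
  set.seed(99)
  totals <- replicate(200, sum(simulate_discrete(tr, er2_Q(r))$counts))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - r * L), 3 * se)
})

test_that("simulate_continuous_bm follows the BM covariance law", {
  # degenerate diffusion pins tips at the root value
  tr <- simulate_tree(6, 1, 0, seed = 4)
  sim <- simulate_continuous_bm(tr, sigma2 = 1e-12, root_value = 3, seed = 1)
  expect_equal(unname(sim$tip_values), rep(3, 6), tolerance = 1e-4)

  # determinism
  a <- simulate_continuous_bm(tr, 1, 0, seed = 9)
  b <- simulate_continuous_bm(tr, 1, 0, seed = 9)
  expect_identical(a, b)

  # empirical tip covariance ~ sigma2 * C entrywise
  tr4 <- balanced4
  sigma2 <- 0.7
  set.seed(123)
  reps <- replicate(2000,
    simulate_continuous_bm(tr4, sigma2, 0)$tip_values[tr4$tip.label])
  emp <- cov(t(reps))
  theo <- sigma2 * phylo_covariance(tr4)[tr4$tip.label, tr4$tip.label]
  # 3 SE bound: var of sample cov entries approx (C_ii C_jj + C_ij^2)/n
  nrep <- ncol(reps)
  for (i in 1:4) for (j in 1:4) {
    se <- sqrt((theo[i, i] * theo[j, j] + theo[i, j]^2) / nrep)
    expect_lt(abs(emp[i, j] - theo[i, j]), 3.5 * se)
  }
})

test_that("simulate_causal_traits builds traits in topological order", {
  tr <- simulate_tree(150, 1, 0, seed = 21)
  dag <- causal_dag(c("x", "y"), rbind(c("x", "y")))
  sim <- simulate_causal_traits(tr, dag, c("x->y" = 1.5),
                                noise_sigma2 = 0.5, seed = 31)
  # PGLS recovers the generating slope within its CI
  y <- setNames(sim$tip_traits$y, rownames(sim$tip_traits))
  X <- sim$tip_traits["x"]
  fit <- pgls_fit(y, X, tr)
  co <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_lt(abs(co$estimate - 1.5), 2.5 * co$se)

  # zero coefficients give independent traits
  sim0 <- simulate_causal_traits(tr, dag, c("x->y" = 0), seed = 32)
  y0 <- setNames(sim0$tip_traits$y, rownames(sim0$tip_traits))
  fit0 <- pgls_fit(y0, sim0$tip_traits["x"], tr)
  expect_gt(fit0$coefficients$p[2], 0.001)

  # cycles are rejected at construction
  expect_error(causal_dag(c("a", "b"), rbind(c("a", "b"), c("b", "a"))),
               "cycle")
})

test_that("generate_study_like_dataset matches its configured marginals", {
  cfg <- simulation_config(seed = 11, n_tips = 500, n_trees = 3,
                           category_freqs = c(0.08, 0.12, 0.47, 0.33))
  out <- generate_study_like_dataset(cfg)
  expect_length(out$trees, 3L)
  tab <- out$table
  expect_true(all(c("species_id", "repro_potential", "realised_repro",
                    "confidence", "colony_size", "queen_number",
                    "mating_frequency", "queen_head_widths_mm",
                    "worker_head_widths_mm", "excluded_flags")
                  %in% names(tab)))
  expect_true(all(tab$repro_potential %in% 1:4))
  # 99% binomial bounds around each configured frequency
  n <- nrow(tab)
  freq <- as.numeric(table(factor(tab$repro_potential, levels = 1:4))) / n
  for (i in 1:4) {
    p <- cfg$category_freqs[i]
    half <- 2.58 * sqrt(p * (1 - p) / n)
    expect_lt(abs(freq[i] - p), half + 2 / n)
  }
  # colony size rises with the latent axis (positive association)
  expect_gt(cor(out$truth$latent, out$truth$log_colony), 0.2)
  # determinism
  out2 <- generate_study_like_dataset(cfg)
  expect_identical(out$table, out2$table)
})
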