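test_that("phylo_covariance has the textbook structure", {
  st <- star_tree(5, t = 2)
  C <- phylo_covariance(st)
  expect_equal(unname(C), diag(2, 5), tolerance = 1e-12)
  # two sisters with stem s share covariance s
  tr <- ape::read.tree(text = "((A:1,B:1):0.5,C:1.5);")
  C2 <- phylo_covariance(tr)
  expect_equal(C2["A", "B"], 0.5)
  expect_equal(C2["A", "C"], 0)
  expect_equal(C2["A", "A"], 1.5)
})

test_that("pgls_fit reduces to OLS on a star tree and fits exactly", {
  set.seed(201)
  st <- star_tree(40)
  x <- rnorm(40); y <- 1 + 0.5 * x + rnorm(40)
  names(y) <- st$tip.label
  X <- data.frame(x = x, row.names = st$tip.label)
  fit <- pgls_fit(y, X, st)
  ols <- lm(y ~ x)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-9)
  expect_equal(fit$coefficients$p[2], summary(ols)$coefficients[2, 4],
               tolerance = 1e-9)
  # exact linear data: slope recovered with zero residual variance
  y2 <- setNames(2 * x, st$tip.label)
  fit2 <- pgls_fit(y2, X, st)
  expect_equal(fit2$coefficients$estimate[2], 2, tolerance = 1e-9)
  expect_lt(fit2$sigma2, 1e-16)
  # singular designs are refused
  X2 <- data.frame(x = x, x2 = x, row.names = st$tip.label)
  expect_error(pgls_fit(y, X2, st), "singular")
})

test_that("pgls lambda endpoints: 0 = OLS, 1 = full BM GLS", {
  set.seed(211)
  tr <- simulate_tree(50, 1, 0, seed = 211)
  sim <- simulate_causal_traits(tr, causal_dag(c("x", "y"),
                                               rbind(c("x", "y"))),
                                c("x->y" = 1), seed = 212)
  y <- setNames(sim$tip_traits$y, rownames(sim$tip_traits))
  X <- sim$tip_traits["x"]
  f0 <- pgls_fit(y, X, tr, lambda = 0)
  ols <- lm(y ~ x, data = data.frame(y = y, x = X$x))
  expect_equal(f0$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
  f1 <- pgls_fit(y, X, tr, lambda = 1)
  fml <- pgls_fit(y, X, tr, lambda = "ML")
  expect_gte(fml$loglik, max(f0$loglik, f1$loglik) - 1e-6)
})

test_that("bpmm_fit gaussian approximates OLS on a star tree", {
  set.seed(221)
  st <- star_tree(60)
  x <- rnorm(60); y <- setNames(2 + 1.2 * x + rnorm(60, 0, 0.5),
                                st$tip.label)
  X <- data.frame(x = x, row.names = st$tip.label)
  fit <- bpmm_fit(y, X, st, family = "gaussian",
                  settings = mcmc_settings(iterations = 4000L,
                                           burn_in = 1000L, thinning = 3L,
                                           n_chains = 2L, seed = 9))
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "x"] - 1.2), 0.25)
  expect_lt(co$pMCMC[co$term == "x"], 0.05)
  expect_true(co$lower[co$term == "x"] < co$upper[co$term == "x"])
  expect_false(is.na(fit$converged))
})

test_that("bpmm_fit threshold-binary recovers the sign of a strong effect", {
  set.seed(231)
  tr <- simulate_tree(80, 1, 0, seed = 231)
  x <- simulate_continuous_bm(tr, 1, 0, seed = 232)$tip_values
  lat <- 1.5 * scale(x)[, 1] + rnorm(80, 0, 0.8)
  y <- setNames(as.integer(lat > 0), tr$tip.label)
  X <- data.frame(x = scale(x)[, 1], row.names = tr$tip.label)
  fit <- bpmm_fit(y, X, tr, family = "threshold-binary",
                  settings = mcmc_settings(iterations = 3000L,
                                           burn_in = 1000L, thinning = 2L,
                                           n_chains = 1L, seed = 10))
  expect_gt(fit$coefficients$estimate[2], 0)
})

test_that("gelman_rubin separates converged from divergent chains", {
  set.seed(241)
  same <- list(rnorm(10000), rnorm(10000))
  expect_lt(gelman_rubin(same), 1.05)
  apart <- list(rnorm(1000, 0, 1), rnorm(1000, 100, 1))
  expect_gt(gelman_rubin(apart), 10)
  flat <- list(rep(1, 100), rep(1, 100))
  expect_lte(gelman_rubin(flat), 1)
  expect_error(gelman_rubin(list(rnorm(100))), "2 chains")
  expect_error(gelman_rubin(list(rnorm(5), rnorm(5))), "short")
})

test_that("basis_set produces the documented claims", {
  chain <- causal_dag(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
  claims <- basis_set(chain)
  expect_length(claims, 1L)
  expect_equal(claims[[1]]$x, "X")
  expect_equal(claims[[1]]$y, "Z")
  expect_equal(claims[[1]]$cond, "Y")
  # fully connected: empty basis
  full <- causal_dag(c("A", "B", "C"),
                     rbind(c("A", "B"), c("A", "C"), c("B", "C")))
  expect_length(basis_set(full), 0L)
  # 4 nodes with an isolated vertex: exact hand enumeration
  dag4 <- causal_dag(c("X", "Y", "Z", "W"), rbind(c("X", "Y"), c("Y", "Z")))
  cl <- basis_set(dag4)
  got <- vapply(cl, function(c)
    paste0(c$x, "_", c$y, "|", paste(c$cond, collapse = ",")), "")
  expect_setequal(got, c("X_Z|Y", "X_W|", "W_Y|X", "W_Z|Y"))
})

test_that("fisher_c closed forms, errors and monotonicity", {
  expect_equal(fisher_c(numeric(0)), list(C = 0, df = 0L, p = 1))
  fc <- fisher_c(c(0.5, 0.5))
  expect_equal(fc$C, 4 * log(2), tolerance = 1e-12)
  expect_equal(fc$df, 4L)
  expect_error(fisher_c(c(0.5, 0)), "0")
  expect_error(fisher_c(c(0.5, 1.2)), "\\(0, 1\\]")
  # permutation invariance and monotone growth as any p shrinks
  p <- c(0.1, 0.4, 0.9)
  expect_equal(fisher_c(p)$C, fisher_c(rev(p))$C)
  expect_gt(fisher_c(c(0.05, 0.4, 0.9))$C, fisher_c(p)$C)
})

test_that("cicc formula and guards", {
  expect_equal(cicc(2.7726, 3, 20), 2.7726 + 7.5, tolerance = 1e-12)
  expect_equal(cicc(5, 0, 10), 5)
  expect_equal(cicc(1, 2, 1e9), 1 + 4, tolerance = 1e-6)
  expect_error(cicc(1, 5, 6), "exceed")
})

test_that("compare_path_models: saturated model and structure recovery", {
  set.seed(251)
  tr <- simulate_tree(120, 1, 0, seed = 251)
  dag_true <- causal_dag(c("x", "y", "z"), rbind(c("x", "y"), c("y", "z")))
  sim <- simulate_causal_traits(tr, dag_true,
                                c("x->y" = 1.2, "y->z" = 1.2),
                                noise_sigma2 = 0.4, seed = 252)
  tab <- sim$tip_traits
  dags <- list(
    true_chain = dag_true,
    reversed = causal_dag(c("x", "y", "z"), rbind(c("z", "y"), c("y", "x"))),
    saturated = causal_dag(c("x", "y", "z"),
                           rbind(c("x", "y"), c("x", "z"), c("y", "z"))),
    independent = causal_dag(c("x", "y", "z")))
  cmp <- compare_path_models(dags, tab, tr)
  res <- cmp$per_tree[[1]]
  # saturated: C = 0 and CICc = 2qn/(n - q - 1) exactly
  sat <- res[res$model == "saturated", ]
  expect_equal(sat$C, 0)
  expect_equal(sat$CICc, 2 * sat$q * sat$n / (sat$n - sat$q - 1))
  # independence model is strongly rejected
  expect_lt(res$p[res$model == "independent"], 0.01)
  # generating chain beats the no-edge model
  expect_lt(res$CICc[res$model == "true_chain"],
            res$CICc[res$model == "independent"])
  # weights sum to one; averaged coefficient for the planted path positive
  expect_equal(sum(cmp$combined$weight), 1, tolerance = 1e-12)
  if ("x->y" %in% names(cmp$averaged_coefficients))
    expect_gt(cmp$averaged_coefficients[["x->y"]], 0)
})
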