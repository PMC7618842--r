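## Mk engine: k-state continuous-time Markov models on phylogenies with
## free / zero / shared rate constraints; pruning likelihood (C++ core),
## brute-force enumeration oracle, ML fitting, posterior MCMC, stepping-stone
## marginal likelihoods and Bayes factors.

#' Build a constraint map
#'
#' A constraint map labels every ordered off-diagonal cell (i, j) of a
#' k-state rate matrix as `"free"` (its own rate), `"zero"` (structurally
#' impossible) or `"shared:<group>"` (one rate shared by all cells in the
#' group).
#'
#' @param labels a k x k character matrix; the diagonal is ignored.
#' @return an object of class `constraint_map`.
#' @export
constraint_map <- function(labels) {
  if (!is.matrix(labels) || nrow(labels) != ncol(labels))
    stop2("labels must be a square character matrix")
  k <- nrow(labels)
  diag(labels) <- NA_character_
  ok <- is.na(labels) | labels %in% c("free", "zero") |
    startsWith(ifelse(is.na(labels), "", labels), "shared:")
  if (!all(ok)) stop2("invalid constraint label(s): %s",
                      paste(unique(labels[!ok]), collapse = ", "))
  off <- labels[row(labels) != col(labels)]
  if (all(off == "zero"))
    stop2("constraint has no free or shared rate")
  structure(list(labels = labels, k = k), class = "constraint_map")
}

#' All-rates-free constraint on k states
#' @param k number of states.
#' @export
constraint_free <- function(k) {
  m <- matrix("free", k, k)
  constraint_map(m)
}

## Internal: integer map (0 = zero, g >= 1 = parameter index) + group names.
constraint_groups <- function(cm) {
  k <- cm$k
  lab <- cm$labels
  map <- matrix(0L, k, k)
  groups <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    l <- lab[i, j]
    if (l == "zero") next
    gname <- if (l == "free") sprintf("q_%d_%d", i, j) else sub("^shared:", "", l)
    g <- match(gname, groups)
    if (is.na(g)) { groups <- c(groups, gname); g <- length(groups) }
    map[i, j] <- g
  }
  list(map = map, groups = groups)
}

#' Number of free parameters of a constraint map
#' @param cm a `constraint_map`.
#' @export
n_free_params <- function(cm) length(constraint_groups(cm)$groups)

#' Build a rate matrix from parameters and a constraint map
#'
#' Zero-labelled cells are exactly 0, shared cells take their group's rate,
#' free cells take their own, and the diagonal completes each row to 0.
#'
#' @param params named nonnegative vector covering every free/shared group
#'   (free groups are named `q_<i>_<j>`).
#' @param constraint a `constraint_map`.
#' @return a k x k rate matrix.
#' @export
build_rate_matrix <- function(params, constraint) {
  cg <- constraint_groups(constraint)
  miss <- setdiff(cg$groups, names(params))
  if (length(miss)) stop2("missing rate(s) for group(s): %s",
                          paste(miss, collapse = ", "))
  if (any(params < 0)) stop2("rates must be nonnegative")
  rates <- as.numeric(params[cg$groups])
  k <- constraint$k
  Q <- matrix(0, k, k)
  nz <- cg$map > 0
  Q[nz] <- rates[cg$map[nz]]
  diag(Q) <- -rowSums(Q)
  Q
}

validate_rate_matrix <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop2("Q must be square")
  offs <- Q[row(Q) != col(Q)]
  if (any(offs < 0)) stop2("off-diagonal rates must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-10)) stop2("rows of Q must sum to 0")
  invisible(Q)
}

#' Stationary distribution of a rate matrix
#' @param Q a valid rate matrix.
#' @return probability vector pi with pi Q = 0.
#' @export
stationary_dist <- function(Q) {
  validate_rate_matrix(Q)
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  p <- qr.solve(A, b)
  p[p < 0] <- 0
  p / sum(p)
}

## Tip partial likelihoods: tip_states is a named vector over tree tips;
## entries are integers 1..k, strings like "1/3" (ambiguity sets), or NA
## (fully ambiguous).
build_tip_partials <- function(tree, tip_states, k) {
  tips <- tree$tip.label
  miss <- setdiff(names(tip_states), tips)
  if (length(miss)) stop2("tip state(s) for species absent from tree: %s",
                          paste(head(miss, 5), collapse = ", "))
  P <- matrix(0, length(tips), k)
  for (i in seq_along(tips)) {
    s <- tip_states[[tips[i]]]
    if (is.null(s) || length(s) == 0L || is.na(s)) { P[i, ] <- 1; next }
    states <- if (is.character(s))
      as.integer(strsplit(s, "/", fixed = TRUE)[[1]]) else as.integer(s)
    if (anyNA(states) || any(states < 1 | states > k))
      stop2("invalid state '%s' for tip %s (k = %d)", s, tips[i], k)
    P[i, states] <- 1
  }
  if (any(rowSums(P) == 0)) stop2("a tip has an empty state set")
  P
}

root_frequencies <- function(root_mode, k, Q = NULL, root_freq = NULL,
                             tipp = NULL) {
  switch(root_mode,
    flat = rep(1 / k, k),
    observed = {
      obs <- which(colSums(tipp) > 0 & colSums(tipp) < nrow(tipp))
      if (length(obs) == 0L) obs <- seq_len(k)
      f <- rep(0, k); f[obs] <- 1 / length(obs); f
    },
    stationary = stationary_dist(Q),
    given = {
      if (is.null(root_freq) || length(root_freq) != k ||
          abs(sum(root_freq) - 1) > 1e-8)
        stop2("root_freq must be a length-k probability vector")
      root_freq
    },
    stop2("unknown root_mode '%s'", root_mode))
}

## Tree pieces in the form the C++ core expects.
tree_arrays <- function(tree) {
  tr <- reorder(tree, "postorder")
  list(edge = tr$edge, el = tr$edge.length,
       ntip = length(tr$tip.label), nnode = tr$Nnode, tree = tr)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' Post-order pruning with per-edge transition probabilities exp(Qt);
#' root partials combined with the chosen root frequencies. Impossible data
#' return `-Inf` (a typed sentinel, never an error).
#'
#' @param tree a `phylo` with branch lengths.
#' @param tip_states named vector of states (1..k), ambiguity sets as
#'   `"1/2"`, or NA for fully ambiguous.
#' @param Q a k x k rate matrix.
#' @param root_mode `"flat"` (uniform over all k states; default),
#'   `"observed"` (uniform over observed states), `"stationary"`, or
#'   `"given"` with `root_freq`.
#' @param root_freq optional probability vector for `root_mode = "given"`.
#' @return the log-likelihood (possibly `-Inf`).
#' @export
mk_loglik <- function(tree, tip_states, Q,
                      root_mode = c("flat", "observed", "stationary", "given"),
                      root_freq = NULL) {
  root_mode <- match.arg(root_mode)
  validate_rate_matrix(Q)
  k <- nrow(Q)
  ta <- tree_arrays(tree)
  tipp <- build_tip_partials(ta$tree, tip_states, k)
  rf <- root_frequencies(root_mode, k, Q, root_freq, tipp)
  mk_loglik_cpp(ta$edge, ta$el, ta$ntip, ta$nnode, tipp, Q, rf)
}

#' Brute-force Mk likelihood by enumerating internal node states
#'
#' The engine's master test oracle: sums the probability of every explicit
#' assignment of states to internal nodes. Transition probabilities use
#' `Matrix::expm` (Pade scaling-and-squaring), an independent path from the
#' spectral decomposition used by the pruning core.
#'
#' @inheritParams mk_loglik
#' @param max_internal refuse enumeration beyond this many internal nodes.
#' @export
brute_force_loglik <- function(tree, tip_states, Q,
                               root_mode = c("flat", "observed", "stationary",
                                             "given"),
                               root_freq = NULL, max_internal = 8L) {
  root_mode <- match.arg(root_mode)
  validate_rate_matrix(Q)
  k <- nrow(Q)
  if (tree$Nnode > max_internal)
    stop2("too many internal nodes (%d > %d) for enumeration", tree$Nnode,
          max_internal)
  ta <- tree_arrays(tree)
  tr <- ta$tree
  tipp <- build_tip_partials(tr, tip_states, k)
  rf <- root_frequencies(root_mode, k, Q, root_freq, tipp)
  ntip <- ta$ntip
  Pmats <- lapply(ta$el, function(t) expm_mat(Q * t))
  root <- ntip + 1L
  m <- tr$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    assign <- grid[r, ]
    state_of <- function(node) assign[node - ntip]
    p <- rf[state_of(root)]
    for (e in seq_len(nrow(ta$edge))) {
      par <- ta$edge[e, 1]; child <- ta$edge[e, 2]
      sp <- state_of(par)
      if (child <= ntip) {
        p <- p * sum(Pmats[[e]][sp, ] * tipp[child, ])
      } else {
        p <- p * Pmats[[e]][sp, state_of(child)]
      }
      if (p == 0) break
    }
    total <- total + p
  }
  if (total <= 0) -Inf else log(total)
}

#' Fit an Mk model by maximum likelihood
#'
#' Box-constrained multi-start optimization over nonnegative rates (on the
#' log scale). AIC = 2 p - 2 logL with p the number of free rate groups.
#'
#' @inheritParams mk_loglik
#' @param constraint a `constraint_map`.
#' @param n_starts number of random restarts.
#' @param seed optional seed for the restarts.
#' @return list(params, logL, AIC, n_free, convergence).
#' @export
fit_mk_ml <- function(tree, tip_states, constraint,
                      root_mode = "flat", root_freq = NULL,
                      n_starts = 3L, seed = NULL) {
  cg <- constraint_groups(constraint)
  G <- length(cg$groups)
  if (G == 0L) stop2("constraint has no free parameters")
  k <- constraint$k
  obs <- unique(na.omit(unlist(lapply(tip_states, function(s)
    if (is.character(s)) as.integer(strsplit(s, "/")[[1]]) else s))))
  if (length(obs) < 2L) stop2("need >= 2 observed distinct states")
  ta <- tree_arrays(tree)
  tipp <- build_tip_partials(ta$tree, tip_states, k)
  nll <- function(logr) {
    rates <- exp(logr)
    Q <- matrix(0, k, k); nz <- cg$map > 0
    Q[nz] <- rates[cg$map[nz]]; diag(Q) <- -rowSums(Q)
    rf <- root_frequencies(root_mode, k, Q, root_freq, tipp)
    ll <- mk_loglik_cpp(ta$edge, ta$el, ta$ntip, ta$nnode, tipp, Q, rf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  if (!is.null(seed)) set.seed(seed)
  ## characteristic rate scale: one expected change over the tree
  scale0 <- 1 / max(sum(ta$el), .Machine$double.eps)
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- log(scale0 * exp(runif(G, log(0.5), log(20))))
    fit <- tryCatch(
      optim(init, nll, method = "L-BFGS-B", lower = log(1e-9),
            upper = log(1e4), control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop2("ML optimization failed after %d restarts", n_starts)
  params <- setNames(exp(best$par), cg$groups)
  logL <- -best$value
  list(params = params, logL = logL, AIC = 2 * G - 2 * logL, n_free = G,
       convergence = best$convergence)
}

#' Prior specification for Mk rates
#'
#' Each rate has an exponential prior whose mean is itself drawn from a
#' uniform hyperprior on (0, `hyper_upper`); the default 0.1 suits trees
#' scaled to mean branch length 0.1.
#'
#' @param hyper_upper upper bound of the uniform hyperprior (> 0).
#' @export
prior_spec <- function(hyper_upper = 0.1) {
  if (hyper_upper <= 0) stop2("hyper_upper must be > 0")
  structure(list(hyper_upper = hyper_upper), class = "prior_spec")
}

#' MCMC settings
#'
#' Desk-scale defaults; `paper_scale = TRUE` switches to the 30M-iteration
#' schedule used for full-size analyses.
#'
#' @param iterations,burn_in,thinning,n_chains,seed schedule parameters.
#' @param paper_scale use the full-scale schedule.
#' @export
mcmc_settings <- function(iterations = 200000L, burn_in = 20000L,
                          thinning = 50L, n_chains = 2L, seed = NULL,
                          paper_scale = FALSE) {
  if (paper_scale) { iterations <- 3e7; burn_in <- 3e6; thinning <- 1e4 }
  if (burn_in >= iterations) stop2("burn_in must be < iterations")
  if (thinning < 1) stop2("thinning must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 n_chains = as.integer(n_chains), seed = seed),
            class = "mcmc_settings")
}

#' Stepping-stone settings
#'
#' Defaults follow common practice: 100 stones of 10,000 iterations with
#' powers placed at quantiles of Beta(alpha = 0.4, beta = 1).
#'
#' @param n_stones,iterations,alpha,beta,burn_frac sampler controls.
#' @export
ss_settings <- function(n_stones = 100L, iterations = 10000L, alpha = 0.4,
                        beta = 1, burn_frac = 0.1) {
  if (n_stones < 2L) stop2("need at least 2 stones")
  structure(list(n_stones = as.integer(n_stones),
                 iterations = as.integer(iterations), alpha = alpha,
                 beta = beta, burn_frac = burn_frac),
            class = "ss_settings")
}

ss_betas <- function(ss) {
  stats::qbeta(seq(0, 1, length.out = ss$n_stones + 1L), ss$alpha, ss$beta)
}

#' Posterior MCMC over constrained Mk rates and a tree set
#'
#' Metropolis-Hastings with log-scale rate proposals, an update of the
#' exponential-prior mean hyperparameter, and uniform tree-index switching
#' across the supplied tree set.
#'
#' @param trees a `tree_set` or single `phylo`.
#' @inheritParams fit_mk_ml
#' @param prior a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @param prop_sd log-scale proposal standard deviation.
#' @return list with `samples` (data.frame: rates, hyper_mean, logL,
#'   tree_index 0-based), acceptance rates, per-parameter effective sample
#'   sizes, and the settings.
#' @export
mcmc_sample <- function(trees, tip_states, constraint, prior = prior_spec(),
                        settings = mcmc_settings(), root_mode = "flat",
                        root_freq = NULL, prop_sd = 0.6) {
  if (inherits(trees, "phylo")) trees <- tree_set(trees)
  cg <- constraint_groups(constraint)
  if (length(cg$groups) == 0L) stop2("constraint has no free parameters")
  k <- constraint$k
  if (root_mode == "stationary")
    stop2("stationary root frequencies vary with the sampled rates; use flat, observed or given in samplers")
  tas <- lapply(trees$trees, tree_arrays)
  tipps <- lapply(tas, function(ta) build_tip_partials(ta$tree, tip_states, k))
  rf <- root_frequencies(root_mode, k, NULL, root_freq, tipps[[1]])
  if (!is.null(settings$seed)) set.seed(settings$seed)
  res <- mcmc_run_cpp(lapply(tas, `[[`, "edge"), lapply(tas, `[[`, "el"),
                      tipps, vapply(tas, `[[`, 0L, "ntip"),
                      vapply(tas, `[[`, 0L, "nnode"), cg$map,
                      length(cg$groups), prior$hyper_upper,
                      settings$iterations, settings$burn_in,
                      settings$thinning, prop_sd, rf)
  if (res$acceptance_rate <= 0)
    stop2("zero MCMC acceptance: adjust the proposal scale (prop_sd)")
  sm <- as.data.frame(res$samples)
  names(sm) <- c(cg$groups, "hyper_mean", "logL", "tree_index")
  list(samples = sm, acceptance_rate = res$acceptance_rate,
       tree_acceptance_rate = res$tree_acceptance_rate,
       ess = vapply(sm[c(cg$groups, "logL")], ess, 0), settings = settings)
}

#' Stepping-stone estimate of the log marginal likelihood
#'
#' Power-posterior chains at powers beta_j placed at Beta(alpha, beta)
#' quantiles of j/K; the log marginal likelihood is the sum over stones of
#' the log mean importance ratio between adjacent powers.
#'
#' @inheritParams mcmc_sample
#' @param tree a single `phylo` (model comparison repeats over trees at the
#'   suite level).
#' @param ss an [ss_settings()].
#' @param seed optional integer seed.
#' @param fixed_Q optional fixed rate matrix: with no free parameters the
#'   marginal likelihood is the likelihood itself and is returned exactly.
#' @return list(log_marginal, stone_contributions, acceptance_rate, settings,
#'   seed) of class `marginal_likelihood`.
#' @export
stepping_stone_log_marginal <- function(tree, tip_states, constraint = NULL,
                                        prior = prior_spec(),
                                        ss = ss_settings(), root_mode = "flat",
                                        root_freq = NULL, seed = NULL,
                                        fixed_Q = NULL, prop_sd = 0.6) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(fixed_Q)) {
    ll <- mk_loglik(tree, tip_states, fixed_Q, root_mode, root_freq)
    return(structure(list(log_marginal = ll, stone_contributions = numeric(0),
                          acceptance_rate = NA_real_, settings = ss,
                          seed = seed), class = "marginal_likelihood"))
  }
  if (root_mode == "stationary")
    stop2("stationary root frequencies vary with the sampled rates; use flat, observed or given in samplers")
  cg <- constraint_groups(constraint)
  k <- constraint$k
  ta <- tree_arrays(tree)
  tipp <- build_tip_partials(ta$tree, tip_states, k)
  rf <- root_frequencies(root_mode, k, NULL, root_freq, tipp)
  res <- ss_run_cpp(ta$edge, ta$el, ta$ntip, ta$nnode, tipp, cg$map,
                    length(cg$groups), prior$hyper_upper, ss_betas(ss),
                    ss$iterations, ss$burn_frac, prop_sd, rf)
  structure(list(log_marginal = res$log_marginal,
                 stone_contributions = as.numeric(res$stone_contributions),
                 acceptance_rate = res$acceptance_rate, settings = ss,
                 seed = seed), class = "marginal_likelihood")
}

#' Bayes factor from two log marginal likelihoods
#'
#' BF = 2 (lnML_complex - lnML_simple), interpreted on the conventional
#' scale: below 2 minimal, 2-6 positive, 6-10 strong, above 10 very strong
#' support for the complex model.
#'
#' @param lnml_complex,lnml_simple finite log marginal likelihoods (numbers
#'   or `marginal_likelihood` objects).
#' @return list(BF, label).
#' @export
bayes_factor <- function(lnml_complex, lnml_simple) {
  val <- function(x) if (inherits(x, "marginal_likelihood")) x$log_marginal else x
  a <- val(lnml_complex); b <- val(lnml_simple)
  if (!is.finite(a) || !is.finite(b))
    stop2("both log marginal likelihoods must be finite")
  bf <- 2 * (a - b)
  label <- if (bf < 2) "minimal" else if (bf <= 6) "positive" else
    if (bf <= 10) "strong" else "very strong"
  list(BF = bf, label = label)
}
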