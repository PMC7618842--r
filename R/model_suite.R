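## Assembles the specific model comparisons for the ordered evolution of
## worker reproductive potential (4 categories) and for correlated evolution
## of binary trait pairs, on top of the Mk engine.

#' Constraint maps for the ordered-evolution model suite
#'
#' Four 4-state models of worker reproductive potential (1 full sexual
#' capacity, 2 reduced, 3 male offspring only, 4 sterile):
#' \itemize{
#'   \item FREE: all 12 transition rates free (non-ordinal categories).
#'   \item SEQUENTIAL: only adjacent transitions (1-2, 2-3, 3-4, both
#'     directions; 6 rates) — states as steps on a ladder.
#'   \item SEQUENTIAL_PLUS_1to4: sequential plus a free direct loss
#'     1 -> 4 (7 rates).
#'   \item INTERMEDIATE_SHARED: adjacent rates free, all non-sequential
#'     transitions allowed but forced into a single shared (rare) rate
#'     class (7 parameters).
#' }
#'
#' @return named list of [constraint_map()] objects.
#' @export
multistate_model_specs <- function() {
  k <- 4L
  seq_cells <- rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(3, 4), c(4, 3))
  base <- matrix("zero", k, k)
  for (r in seq_len(nrow(seq_cells)))
    base[seq_cells[r, 1], seq_cells[r, 2]] <- "free"
  seq_plus <- base
  seq_plus[1, 4] <- "free"
  inter <- base
  for (i in 1:4) for (j in 1:4)
    if (i != j && inter[i, j] == "zero") inter[i, j] <- "shared:nonseq"
  list(FREE = constraint_free(k),
       SEQUENTIAL = constraint_map(base),
       SEQUENTIAL_PLUS_1to4 = constraint_map(seq_plus),
       INTERMEDIATE_SHARED = constraint_map(inter))
}

#' Compare transition models for a 4-category trait by Bayes factors
#'
#' Runs a stepping-stone marginal likelihood per model (repeated
#' `n_repeats` times; the median is reported) and compares models pairwise,
#' simpler versus more complex (fewer free parameters = simpler).
#'
#' @param trees a `tree_set` or `phylo`; marginal likelihoods are computed
#'   on `tree_index` (default the first tree).
#' @param categories named integer vector in 1..4.
#' @param prior a [prior_spec()].
#' @param ss an [ss_settings()].
#' @param models named list of constraint maps (default
#'   [multistate_model_specs()]).
#' @param n_repeats stepping-stone repeats per model (median reported).
#' @param seed integer seed.
#' @param tree_index 1-based index into the tree set.
#' @return a `model_comparison` list: models table, pairwise BFs, winner.
#' @export
compare_transition_models <- function(trees, categories,
                                      prior = prior_spec(),
                                      ss = ss_settings(),
                                      models = multistate_model_specs(),
                                      n_repeats = 3L, seed = NULL,
                                      tree_index = 1L) {
  if (inherits(trees, "phylo")) trees <- tree_set(trees)
  tree <- trees[[tree_index]]
  obs <- unique(categories)
  if (length(obs) < 2L) stop2("single-category data carry no information")
  if (!is.null(seed)) set.seed(seed)
  tab <- data.frame(model = names(models),
                    n_free = vapply(models, n_free_params, 0L),
                    lnML = NA_real_, stringsAsFactors = FALSE)
  all_runs <- list()
  for (m in seq_along(models)) {
    reps <- vapply(seq_len(n_repeats), function(r)
      stepping_stone_log_marginal(tree, categories, models[[m]], prior,
                                  ss)$log_marginal, 0)
    all_runs[[names(models)[m]]] <- reps
    tab$lnML[m] <- median(reps)
  }
  ## pairwise: simpler (fewer params) vs complex
  pairs <- utils::combn(seq_along(models), 2)
  bfs <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    if (tab$n_free[i] > tab$n_free[j]) { tmp <- i; i <- j; j <- tmp }
    bf <- bayes_factor(tab$lnML[j], tab$lnML[i])
    data.frame(simple = tab$model[i], complex = tab$model[j],
               BF = bf$BF, label = bf$label, stringsAsFactors = FALSE)
  })
  bf_tab <- do.call(rbind, bfs)
  ## winner: best lnML, but a more complex model must beat the simpler one
  ## by BF >= 2 to displace it
  ord <- order(tab$n_free)
  win <- tab$model[ord[1]]
  for (i in ord[-1]) {
    bf <- 2 * (tab$lnML[i] - tab$lnML[tab$model == win])
    if (bf >= 2) win <- tab$model[i]
  }
  structure(list(models = tab, bayes_factors = bf_tab, winner = win,
                 repeats = all_runs),
            class = "model_comparison")
}

#' @exportS3Method base::print
print.model_comparison <- function(x, ...) {
  cat("Model comparison (stepping-stone marginal likelihoods)\n")
  print(x$models, row.names = FALSE)
  cat("\nPairwise Bayes factors (complex vs simple):\n")
  print(x$bayes_factors, row.names = FALSE)
  cat(sprintf("\nWinning model: %s\n", x$winner))
  invisible(x)
}

## Product-chain state coding for two binary traits:
## 1 = (0,0), 2 = (0,1), 3 = (1,0), 4 = (1,1); first digit = trait A.
pagel_constraints <- function() {
  dep <- matrix("zero", 4, 4)
  single <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1),
                  c(2, 4), c(4, 2), c(3, 4), c(4, 3))
  for (r in seq_len(nrow(single))) dep[single[r, 1], single[r, 2]] <- "free"
  ind <- matrix("zero", 4, 4)
  ind[1, 3] <- ind[2, 4] <- "shared:A_gain"
  ind[3, 1] <- ind[4, 2] <- "shared:A_loss"
  ind[1, 2] <- ind[3, 4] <- "shared:B_gain"
  ind[2, 1] <- ind[4, 3] <- "shared:B_loss"
  list(dependent = constraint_map(dep), independent = constraint_map(ind))
}

#' Pagel's test of correlated evolution for two binary traits
#'
#' Builds the 4-state product chain (00, 01, 10, 11) with simultaneous
#' double transitions structurally zero; the independent model ties each
#' trait's gain/loss rates across the other trait's states (4 rates), the
#' dependent model frees all 8 single-change rates. Support is the Bayes
#' factor of dependent over independent from stepping-stone marginal
#' likelihoods.
#'
#' @param trees `tree_set` or `phylo`.
#' @param traitA,traitB `binary_trait` objects or named 0/1 vectors.
#' @inheritParams compare_transition_models
#' @param rate_mcmc optionally run a short posterior MCMC for rate
#'   summaries (`NULL` to skip).
#' @return list(BF, label, lnML_dependent, lnML_independent, n_species,
#'   rate_summaries).
#' @export
pagel_discrete_test <- function(trees, traitA, traitB, prior = prior_spec(),
                                ss = ss_settings(), n_repeats = 3L,
                                seed = NULL, tree_index = 1L,
                                rate_mcmc = NULL) {
  if (inherits(trees, "phylo")) trees <- tree_set(trees)
  a <- if (inherits(traitA, "binary_trait")) traitA$values else traitA
  b <- if (inherits(traitB, "binary_trait")) traitB$values else traitB
  shared <- intersect(intersect(names(a), names(b)),
                      trees[[tree_index]]$tip.label)
  if (length(shared) < 4L) stop2("fewer than 4 shared species")
  a <- a[shared]; b <- b[shared]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    stop2("a trait is constant after species matching")
  tree <- ape::keep.tip(trees[[tree_index]], shared)
  states <- setNames(1L + 2L * as.integer(a) + as.integer(b), shared)
  cms <- pagel_constraints()
  if (!is.null(seed)) set.seed(seed)
  ln <- lapply(cms, function(cm)
    median(vapply(seq_len(n_repeats), function(r)
      stepping_stone_log_marginal(tree, states, cm, prior, ss)$log_marginal,
      0)))
  bf <- bayes_factor(ln$dependent, ln$independent)
  rates <- NULL
  if (!is.null(rate_mcmc)) {
    ch <- mcmc_sample(tree_set(tree), states, cms$dependent, prior, rate_mcmc)
    rates <- colMeans(ch$samples[, seq_len(8), drop = FALSE])
  }
  list(BF = bf$BF, label = bf$label, lnML_dependent = ln$dependent,
       lnML_independent = ln$independent, n_species = length(shared),
       rate_summaries = rates)
}

## Hidden-rate constraint map: k_obs observed states x n_cats rate classes.
## State index: (class - 1) * k_obs + obs_state. Within-class transitions
## follow ER (one rate per class) or ARD (each cell free per class);
## class switching shares one global rate; no simultaneous switches.
hidden_rate_constraint <- function(k_obs, n_cats, structure = c("ER", "ARD")) {
  structure <- match.arg(structure)
  k <- k_obs * n_cats
  lab <- matrix("zero", k, k)
  for (cl in seq_len(n_cats)) {
    off <- (cl - 1L) * k_obs
    for (i in seq_len(k_obs)) for (j in seq_len(k_obs)) {
      if (i == j) next
      lab[off + i, off + j] <- if (structure == "ER")
        sprintf("shared:rate_c%d", cl) else "free"
    }
  }
  if (n_cats > 1L) {
    for (cl1 in seq_len(n_cats)) for (cl2 in seq_len(n_cats)) {
      if (abs(cl1 - cl2) != 1L) next
      for (i in seq_len(k_obs))
        lab[(cl1 - 1L) * k_obs + i, (cl2 - 1L) * k_obs + i] <- "shared:switch"
    }
  }
  constraint_map(lab)
}

## Observed tip states expanded to the hidden space: ambiguous over classes.
expand_hidden_states <- function(tip_states, k_obs, n_cats) {
  vapply(tip_states, function(s) {
    base <- if (is.character(s)) as.integer(strsplit(s, "/")[[1]]) else
      as.integer(s)
    paste(as.vector(outer(base, (seq_len(n_cats) - 1L) * k_obs, `+`)),
          collapse = "/")
  }, character(1))
}

#' Scan hidden-rate-category models and rank by AIC
#'
#' Expands the state space to observed states x rate classes (1 to 3) with
#' class-switching rates, under ER (equal within-class rates) or ARD
#' (all-rates-different) structures; each candidate is fitted by ML and the
#' table is ranked by AIC.
#'
#' @param tree a `phylo`.
#' @param states named observed states (1..k_obs).
#' @param k_obs number of observed states.
#' @param rate_cats vector of class counts to try.
#' @param structures subset of `c("ER", "ARD")`.
#' @param seed optional seed for optimizer restarts.
#' @return list(table ranked by AIC, best, fits).
#' @export
hidden_rate_scan <- function(tree, states, k_obs = length(unique(states)),
                             rate_cats = 1:3, structures = c("ER", "ARD"),
                             seed = NULL) {
  grid <- expand.grid(cats = rate_cats, structure = structures,
                      stringsAsFactors = FALSE)
  fits <- list()
  rows <- list()
  for (r in seq_len(nrow(grid))) {
    nc <- grid$cats[r]; stc <- grid$structure[r]
    cm <- hidden_rate_constraint(k_obs, nc, stc)
    st <- expand_hidden_states(states, k_obs, nc)
    fit <- fit_mk_ml(tree, st, cm, seed = seed)
    nm <- sprintf("%s_%dcat", stc, nc)
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(model = nm, structure = stc, rate_cats = nc,
                             n_free = fit$n_free, logL = fit$logL,
                             AIC = fit$AIC, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  list(table = tab, best = tab$model[1], fits = fits)
}
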