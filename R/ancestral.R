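## Ancestral state reconstruction, transition counting across tree sets,
## Brownian-motion ancestral estimates for continuous traits, and the
## transition-point contrasts of a continuous trait.

## Resolve a "model" argument: a rate matrix, or a fit from fit_mk_ml paired
## with its constraint (list(params=, constraint=)).
resolve_Q <- function(model) {
  if (is.matrix(model)) return(validate_rate_matrix(model))
  if (is.list(model) && !is.null(model$params) && !is.null(model$constraint))
    return(build_rate_matrix(model$params, model$constraint))
  stop2("model must be a fitted rate matrix or list(params, constraint)")
}

#' Marginal ancestral state probabilities
#'
#' Combined post-order (down) and pre-order (up) pruning passes give each
#' internal node its marginal posterior state distribution under the fitted
#' model. With a hidden-rate model, set `collapse_classes` to the number of
#' rate classes to sum probabilities over classes and report observed
#' states.
#'
#' @param tree a `phylo`.
#' @param tip_states named states (1..k, `"1/2"` ambiguity, NA).
#' @param model a rate matrix or `list(params, constraint)` from
#'   [fit_mk_ml()].
#' @param root_mode,root_freq as in [mk_loglik()].
#' @param collapse_classes optional number of hidden rate classes to
#'   marginalize out.
#' @return matrix (internal nodes x states) of probabilities; rownames are
#'   node ids (ape numbering, root first); attribute `"root"` holds the
#'   root row.
#' @export
marginal_asr <- function(tree, tip_states, model, root_mode = "flat",
                         root_freq = NULL, collapse_classes = NULL) {
  Q <- resolve_Q(model)
  k <- nrow(Q)
  ta <- tree_arrays(tree)
  tr <- ta$tree
  ntip <- ta$ntip
  tipp <- build_tip_partials(tr, tip_states, k)
  rf <- root_frequencies(root_mode, k, Q, root_freq, tipp)
  nnode_total <- ntip + tr$Nnode
  Pm <- lapply(seq_len(nrow(tr$edge)), function(e)
    expm_mat(Q * tr$edge.length[e]))

  ## down pass (postorder edges): D[v] = conditional likelihood of data
  ## below v; W[[e]] = P_e %*% D[child(e)] indexed by parent state
  D <- matrix(1, nnode_total, k)
  D[seq_len(ntip), ] <- tipp
  W <- vector("list", nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; c <- tr$edge[e, 2]
    W[[e]] <- as.numeric(Pm[[e]] %*% D[c, ])
    D[p, ] <- D[p, ] * W[[e]]
    m <- max(D[p, ])
    if (m > 0) D[p, ] <- D[p, ] / m else stop2("impossible data under model")
  }

  ## up pass (preorder edges): U[v] = likelihood contribution from the rest
  ## of the tree above v, including root frequencies
  U <- matrix(0, nnode_total, k)
  root <- ntip + 1L
  U[root, ] <- rf
  children_of <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  for (e in rev(seq_len(nrow(tr$edge)))) {  # reverse postorder = preorder
    p <- tr$edge[e, 1]; c <- tr$edge[e, 2]
    sibs <- setdiff(children_of[[as.character(p)]], e)
    M <- U[p, ]
    for (s in sibs) M <- M * W[[s]]
    U[c, ] <- as.numeric(M %*% Pm[[e]])
    m <- max(U[c, ])
    if (m > 0) U[c, ] <- U[c, ] / m
  }

  post <- U * D
  post <- post / rowSums(post)
  out <- post[(ntip + 1L):nnode_total, , drop = FALSE]
  rownames(out) <- (ntip + 1L):nnode_total
  if (!is.null(collapse_classes) && collapse_classes > 1L) {
    k_obs <- k / collapse_classes
    out <- vapply(seq_len(k_obs), function(s)
      rowSums(out[, s + (seq_len(collapse_classes) - 1L) * k_obs,
                  drop = FALSE]),
      numeric(nrow(out)))
    out <- matrix(out, ncol = k_obs,
                  dimnames = list((ntip + 1L):nnode_total, NULL))
  }
  attr(out, "root") <- out[1, ]
  attr(out, "tree") <- tr
  out
}

#' Summarize root-state probabilities across a tree set
#'
#' @param root_vectors matrix (trees x states) of per-tree root
#'   probabilities.
#' @param level credible level for the quantile interval.
#' @return data.frame(state, mean, lower, upper).
#' @export
summarize_root <- function(root_vectors, level = 0.95) {
  if (is.null(dim(root_vectors))) root_vectors <- rbind(root_vectors)
  a <- (1 - level) / 2
  data.frame(state = seq_len(ncol(root_vectors)),
             mean = colMeans(root_vectors),
             lower = apply(root_vectors, 2, quantile, a),
             upper = apply(root_vectors, 2, quantile, 1 - a))
}

## Endpoint-conditioned CTMC path sampling by uniformization. Returns the
## sequence of real (state-changing) transitions on one edge.
sample_path_uniformized <- function(a, b, t, Q, Pt, max_jumps = 60L) {
  k <- nrow(Q)
  mu <- max(-diag(Q))
  if (mu <= 0) return(matrix(integer(0), 0, 2))
  R <- diag(k) + Q / mu
  ## R powers
  Rpow <- vector("list", max_jumps + 1L)
  Rpow[[1]] <- diag(k)
  for (m in seq_len(max_jumps)) Rpow[[m + 1L]] <- Rpow[[m]] %*% R
  pab <- Pt[a, b]
  if (pab <= 0) return(matrix(integer(0), 0, 2))
  wn <- vapply(0:max_jumps, function(n)
    stats::dpois(n, mu * t) * Rpow[[n + 1L]][a, b] / pab, 0)
  wn[!is.finite(wn)] <- 0
  if (sum(wn) <= 0) return(matrix(integer(0), 0, 2))
  n <- sample(0:max_jumps, 1L, prob = wn)
  if (n == 0L) return(matrix(integer(0), 0, 2))
  states <- integer(n + 1L)
  states[1] <- a; states[n + 1L] <- b
  if (n > 1L) for (m in 2:n) {
    prev <- states[m - 1L]
    pr <- R[prev, ] * Rpow[[n - m + 2L]][, b]
    if (sum(pr) <= 0) pr <- rep(1, k)
    states[m] <- sample.int(k, 1L, prob = pr)
  }
  ch <- which(diff(states) != 0)
  cbind(from = states[ch], to = states[ch + 1L])
}

## Sample one full history (node states + per-edge paths) conditional on the
## tips, using the down-pass partials. Returns a k x k count matrix.
sample_history_counts <- function(tr, ntip, Pm, W, D, rf, Q,
                                  children_of) {
  nnode_total <- nrow(D)
  state <- integer(nnode_total)
  root <- ntip + 1L
  pr <- rf * D[root, ]
  state[root] <- sample.int(ncol(D), 1L, prob = pr)
  counts <- matrix(0L, nrow(Q), ncol(Q))
  for (e in rev(seq_len(nrow(tr$edge)))) {  # preorder
    p <- tr$edge[e, 1]; c <- tr$edge[e, 2]
    pc <- Pm[[e]][state[p], ] * D[c, ]
    state[c] <- sample.int(ncol(D), 1L, prob = pc)
    path <- sample_path_uniformized(state[p], state[c], tr$edge.length[e], Q,
                                    Pm[[e]])
    if (nrow(path)) for (r in seq_len(nrow(path)))
      counts[path[r, 1], path[r, 2]] <- counts[path[r, 1], path[r, 2]] + 1L
  }
  counts
}

#' Count state transitions across a tree set
#'
#' Per tree, either (`"joint"`) assign every node its maximum-marginal state
#' and count parent-child discordant edges by type, or (`"stochastic"`)
#' sample `n_maps` full character histories conditional on the tips
#' (stochastic mapping via uniformization) and average the event counts.
#' Counts are averaged across trees.
#'
#' @param trees `tree_set` or `phylo`.
#' @param tip_states named states.
#' @param model rate matrix or `list(params, constraint)`.
#' @param method `"joint"` or `"stochastic"`.
#' @param n_maps stochastic maps per tree.
#' @param seed optional integer seed.
#' @param root_mode,root_freq root treatment.
#' @return a `transition_counts` object: summary data.frame (from, to,
#'   mean, lower, upper), per-tree counts, node state assignments (joint),
#'   and per-tree transition edge lists.
#' @export
count_transitions <- function(trees, tip_states, model,
                              method = c("joint", "stochastic"), n_maps = 10L,
                              seed = NULL, root_mode = "flat",
                              root_freq = NULL) {
  method <- match.arg(method)
  if (inherits(trees, "phylo")) trees <- tree_set(trees)
  Q <- resolve_Q(model)
  k <- nrow(Q)
  if (!is.null(seed)) set.seed(seed)
  per_tree <- list()
  transitions <- list()
  for (ti in seq_along(trees$trees)) {
    tree <- trees[[ti]]
    ta <- tree_arrays(tree)
    tr <- ta$tree
    ntip <- ta$ntip
    tipp <- build_tip_partials(tr, tip_states, k)
    rf <- root_frequencies(root_mode, k, Q, root_freq, tipp)
    if (method == "joint") {
      asr <- marginal_asr(tree, tip_states, Q, root_mode, root_freq)
      tr2 <- attr(asr, "tree")
      node_state <- integer(ntip + tr2$Nnode)
      ## tips: a determinate state if unambiguous, else max partial
      tipp2 <- build_tip_partials(tr2, tip_states, k)
      node_state[seq_len(ntip)] <- apply(tipp2, 1, which.max)
      node_state[(ntip + 1L):(ntip + tr2$Nnode)] <- apply(asr, 1, which.max)
      counts <- matrix(0L, k, k)
      edges <- list()
      for (e in seq_len(nrow(tr2$edge))) {
        a <- node_state[tr2$edge[e, 1]]; b <- node_state[tr2$edge[e, 2]]
        if (a != b) {
          counts[a, b] <- counts[a, b] + 1L
          edges[[length(edges) + 1L]] <-
            data.frame(tree_index = ti - 1L, parent = tr2$edge[e, 1],
                       child = tr2$edge[e, 2], from = a, to = b)
        }
      }
      per_tree[[ti]] <- counts
      transitions[[ti]] <- if (length(edges)) do.call(rbind, edges) else
        data.frame(tree_index = integer(0), parent = integer(0),
                   child = integer(0), from = integer(0), to = integer(0))
    } else {
      Pm <- lapply(seq_len(nrow(tr$edge)), function(e)
        expm_mat(Q * tr$edge.length[e]))
      D <- matrix(1, ntip + tr$Nnode, k)
      D[seq_len(ntip), ] <- tipp
      W <- vector("list", nrow(tr$edge))
      for (e in seq_len(nrow(tr$edge))) {
        p <- tr$edge[e, 1]; c <- tr$edge[e, 2]
        W[[e]] <- as.numeric(Pm[[e]] %*% D[c, ])
        D[p, ] <- D[p, ] * W[[e]]
        m <- max(D[p, ]); if (m > 0) D[p, ] <- D[p, ] / m
      }
      children_of <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
      acc <- matrix(0, k, k)
      for (m in seq_len(n_maps))
        acc <- acc + sample_history_counts(tr, ntip, Pm, W, D, rf, Q,
                                           children_of)
      per_tree[[ti]] <- acc / n_maps
      transitions[[ti]] <- NULL
    }
  }
  arr <- simplify2array(per_tree)  # k x k x ntrees
  if (length(dim(arr)) == 2L) arr <- array(arr, c(k, k, 1L))
  rows <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    v <- arr[i, j, ]
    rows[[length(rows) + 1L]] <- data.frame(
      from = i, to = j, mean = mean(v),
      lower = quantile(v, 0.025, names = FALSE),
      upper = quantile(v, 0.975, names = FALSE))
  }
  structure(list(summary = do.call(rbind, rows), per_tree = per_tree,
                 transitions = transitions, method = method,
                 n_trees = length(per_tree)),
            class = "transition_counts")
}

#' @exportS3Method base::print
print.transition_counts <- function(x, ...) {
  cat(sprintf("Transition counts (%s) across %d tree(s):\n", x$method,
              x$n_trees))
  print(x$summary[x$summary$mean > 0, ], row.names = FALSE)
  invisible(x)
}

#' Brownian-motion ancestral estimates for a continuous trait
#'
#' Generalized-least-squares estimates of internal node values under
#' Brownian motion: the phylogenetic mean at the root, conditional
#' expectations elsewhere, with a REML-style rate estimate and standard
#' errors that account for uncertainty in the mean.
#'
#' @param tree a `phylo`.
#' @param tip_values named numeric vector covering the tips.
#' @return data.frame(node, estimate, se); the first row is the root.
#' @export
ancestral_continuous <- function(tree, tip_values) {
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop2("need at least 3 tips")
  y <- tip_values[tree$tip.label]
  if (anyNA(y)) stop2("tip_values must cover every tip")
  nd <- ape::node.depth.edgelength(tree)
  DN <- ape::dist.nodes(tree)
  ntot <- ntip + tree$Nnode
  ## shared path length from root: C[u, v] = (d_u + d_v - dist(u, v)) / 2
  Cfull <- (outer(nd, nd, `+`) - DN) / 2
  C <- Cfull[seq_len(ntip), seq_len(ntip)]
  if (min(diag(C)) <= 0) stop2("degenerate tree: zero root-to-tip distance")
  Ci <- solve(C)
  one <- rep(1, ntip)
  denom <- as.numeric(t(one) %*% Ci %*% one)
  mu <- as.numeric(t(one) %*% Ci %*% y) / denom
  resid <- y - mu
  sigma2 <- as.numeric(t(resid) %*% Ci %*% resid) / (ntip - 1)
  nodes <- (ntip + 1L):ntot
  est <- numeric(length(nodes)); se <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    u <- nodes[i]
    cu <- Cfull[u, seq_len(ntip)]
    w <- Ci %*% cu
    est[i] <- mu + sum(w * resid)
    condvar <- Cfull[u, u] - sum(cu * w) + (1 - sum(w))^2 / denom
    se[i] <- sqrt(max(0, sigma2 * condvar))
  }
  data.frame(node = nodes, estimate = est, se = se)
}

#' Compare a continuous trait around discrete-state transitions
#'
#' Mode `"origin-vs-nonorigin"` compares the continuous trait at parent
#' nodes of transition edges against all other internal nodes; mode
#' `"before-vs-after"` compares parent-node against child-node values along
#' transition edges. Per-tree contrasts are aggregated across trees with a
#' mean difference and 95% quantile interval.
#'
#' @param trees `tree_set` or `phylo`.
#' @param transitions_by_tree list (one per tree) of data.frames with
#'   `parent` and `child` node columns (e.g. from [count_transitions()]
#'   with `method = "joint"`).
#' @param values_by_tree list (one per tree) of numeric vectors indexed by
#'   node id (tips and internals).
#' @param mode contrast mode.
#' @return list(mode, n_transitions, per_tree, mean_difference, lower,
#'   upper, empty).
#' @export
transition_context_compare <- function(trees, transitions_by_tree,
                                       values_by_tree,
                                       mode = c("origin-vs-nonorigin",
                                                "before-vs-after")) {
  mode <- match.arg(mode)
  if (inherits(trees, "phylo")) trees <- tree_set(trees)
  diffs <- numeric(0)
  ntrans <- 0L
  for (ti in seq_along(trees$trees)) {
    tr <- trees[[ti]]
    ntip <- length(tr$tip.label)
    trans <- transitions_by_tree[[ti]]
    vals <- values_by_tree[[ti]]
    if (is.null(trans) || nrow(trans) == 0L) next
    ntrans <- ntrans + nrow(trans)
    if (mode == "origin-vs-nonorigin") {
      origin <- unique(trans$parent)
      others <- setdiff((ntip + 1L):(ntip + tr$Nnode), origin)
      if (length(others) == 0L) next
      diffs <- c(diffs, mean(vals[origin]) - mean(vals[others]))
    } else {
      diffs <- c(diffs, mean(vals[trans$parent] - vals[trans$child]))
    }
  }
  if (ntrans == 0L || length(diffs) == 0L)
    return(list(mode = mode, n_transitions = 0L, per_tree = numeric(0),
                mean_difference = NA_real_, lower = NA_real_,
                upper = NA_real_, empty = TRUE))
  list(mode = mode, n_transitions = ntrans, per_tree = diffs,
       mean_difference = mean(diffs),
       lower = quantile(diffs, 0.025, names = FALSE),
       upper = quantile(diffs, 0.975, names = FALSE), empty = FALSE)
}
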