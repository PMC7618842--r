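# Shared fixtures, built in code. All tests use fixed seeds.

# Small hand-written trees
newick3 <- "(A:1,(B:0.5,C:0.5):0.5);"
tree3 <- ape::read.tree(text = newick3)

balanced4 <- ape::read.tree(text = "((A:0.3,B:0.3):0.2,(C:0.25,D:0.25):0.25);")

star_tree <- function(n, t = 1) {
  tr <- ape::stree(n, type = "star")
  tr$tip.label <- sprintf("s%02d", seq_len(n))
  tr$edge.length <- rep(t, nrow(tr$edge))
  tr
}

# Named group labels of the free constraint on k states
free_groups <- function(k) {
  g <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    g <- c(g, sprintf("q_%d_%d", i, j))
  g
}

# A random valid rate matrix on k states
random_Q <- function(k, max_rate = 2) {
  cm <- constraint_free(k)
  params <- setNames(runif(k * (k - 1), 0.05, max_rate), free_groups(k))
  build_rate_matrix(params, cm)
}

# Sequential 4-state generator with one shared rate
sequential_Q <- function(rate = 0.2) {
  cm <- multistate_model_specs()$SEQUENTIAL
  groups <- castevol:::constraint_groups(cm)$groups
  build_rate_matrix(setNames(rep(rate, length(groups)), groups), cm)
}

# 2-state symmetric (equal rates) matrix
er2_Q <- function(rate) {
  matrix(c(-rate, rate, rate, -rate), 2, 2, byrow = TRUE)
}

# A small species table
toy_species_table <- function(n = 10) {
  data.frame(
    species_id = sprintf("sp%02d", seq_len(n)),
    repro_potential = rep(1:4, length.out = n),
    realised_repro = "none",
    confidence = "described",
    colony_size = 10^seq(1, 4, length.out = n),
    queen_number = rep(c(1, 3), length.out = n),
    mating_frequency = rep(c(1, 2.5), length.out = n),
    queen_head_widths_mm = "2.0;2.0",
    worker_head_widths_mm = "1.0;1.5",
    excluded_flags = "",
    stringsAsFactors = FALSE)
}

# Enumeration oracle for marginal ancestral probabilities on tiny trees:
# joint probability of every internal assignment, marginalized by node.
enum_asr <- function(tree, tip_states, Q, root_mode = "flat") {
  ta <- castevol:::tree_arrays(tree)
  tr <- ta$tree
  k <- nrow(Q)
  ntip <- ta$ntip
  tipp <- castevol:::build_tip_partials(tr, tip_states, k)
  rf <- castevol:::root_frequencies(root_mode, k, Q, NULL, tipp)
  Pm <- lapply(ta$el, function(t) castevol:::expm_mat(Q * t))
  m <- tr$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  probs <- matrix(0, m, k)
  for (r in seq_len(nrow(grid))) {
    assign <- grid[r, ]
    p <- rf[assign[1]]  # root = ntip + 1 is first internal id
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      sp <- assign[par - ntip]
      p <- p * if (child <= ntip) sum(Pm[[e]][sp, ] * tipp[child, ]) else
        Pm[[e]][sp, assign[child - ntip]]
    }
    for (v in seq_len(m)) probs[v, assign[v]] <- probs[v, assign[v]] + p
  }
  probs / rowSums(probs)
}
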