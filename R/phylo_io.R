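## Tree input/output, validation, scaling and tree/table alignment.
## Trees are ape "phylo" objects throughout; sets of trees are "tree_set"
## objects (a validated list of phylo with provenance metadata).

#' Construct a tree set
#'
#' A `tree_set` is an ordered list of rooted phylogenies sharing (after
#' harmonization) an identical tip-label set, tagged with its provenance
#' (a posterior sample or a set of consensus trees) and the label of the
#' tree-building method that produced it.
#'
#' @param trees a list of `phylo` objects (or a single `phylo` /` multiPhylo`).
#' @param provenance `"posterior-sample"` or `"mcc-consensus"`.
#' @param source_label free-text label of the tree-building method.
#' @return an object of class `tree_set`.
#' @export
tree_set <- function(trees, provenance = c("posterior-sample", "mcc-consensus"),
                     source_label = "unspecified") {
  provenance <- match.arg(provenance)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop2("tree_set: empty tree list")
  for (i in seq_along(trees)) validate_phylogeny(trees[[i]], index = i - 1L)
  structure(list(trees = trees, provenance = provenance,
                 source_label = source_label),
            class = "tree_set")
}

#' @export
length.tree_set <- function(x) length(x$trees)

#' @export
`[[.tree_set` <- function(x, i) x$trees[[i]]

#' @exportS3Method base::print
print.tree_set <- function(x, ...) {
  cat(sprintf("tree_set: %d tree(s), provenance=%s, source=%s, %d tips\n",
              length(x$trees), x$provenance, x$source_label,
              length(x$trees[[1]]$tip.label)))
  invisible(x)
}

## Validate one phylogeny. Tree indices in messages are 0-based.
validate_phylogeny <- function(tree, index = 0L) {
  if (!inherits(tree, "phylo"))
    stop2("tree %d: not a phylogeny", index)
  if (is.null(tree$edge.length))
    stop2("tree %d: branch lengths are missing (required by all likelihoods)",
          index)
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop2("tree %d: negative or missing branch lengths", index)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop2("tree %d: duplicated tip label(s): %s", index,
          paste(unique(dup), collapse = ", "))
  ## exactly one root: a single node with no parent (star trees qualify)
  roots <- unique(setdiff(tree$edge[, 1], tree$edge[, 2]))
  if (length(roots) != 1L)
    stop2("tree %d: tree must have exactly one root (found %d)", index,
          length(roots))
  invisible(tree)
}

#' Read trees from a Newick or NEXUS file
#'
#' Underscores in unquoted labels are preserved verbatim (no conversion to
#' spaces); matching against trait tables is exact-string.
#'
#' @param path file path.
#' @param format `"auto"` (sniff), `"newick"` or `"nexus"`.
#' @param provenance,source_label passed to [tree_set()].
#' @return a [tree_set()].
#' @export
parse_trees <- function(path, format = c("auto", "newick", "nexus"),
                        provenance = "posterior-sample",
                        source_label = "unspecified") {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("tree file not found: %s", path)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else
      ape::read.tree(path, keep.multi = TRUE),
    error = function(e) stop2("failed to parse %s file '%s': %s",
                              format, path, conditionMessage(e)))
  if (is.null(trees)) stop2("no trees found in '%s'", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!inherits(tr, "phylo"))
      stop2("tree %d in '%s' did not parse", i - 1L, path)
    validate_phylogeny(tr, index = i - 1L)
  }
  tree_set(trees, provenance = provenance, source_label = source_label)
}

#' Write trees to Newick
#'
#' @param trees a `tree_set`, `phylo` or list of `phylo`.
#' @param path output file path.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "tree_set")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Rescale branch lengths to a target mean
#'
#' Multiplies every branch by one constant so that the mean branch length
#' equals `target_mean` (the conventional 0.1 keeps transition rates in a
#' numerically comfortable range; the likelihood is invariant when rates are
#' rescaled by the inverse constant).
#'
#' @param tree a `phylo`.
#' @param target_mean positive real; requested mean branch length.
#' @return the rescaled `phylo`, with attribute `"scale_factor"`.
#' @export
scale_branch_lengths <- function(tree, target_mean = 0.1) {
  validate_phylogeny(tree)
  if (target_mean <= 0) stop2("target_mean must be positive")
  m <- mean(tree$edge.length)
  if (m == 0) stop2("all branch lengths are zero: no valid scaling constant")
  f <- target_mean / m
  tree$edge.length <- tree$edge.length * f
  attr(tree, "scale_factor") <- f
  tree
}

#' Prune a tree and trait table to their shared taxa
#'
#' Retains exactly the tips present in both inputs; degree-2 nodes created
#' by pruning are suppressed with branch lengths summed, so patristic
#' distances among retained tips are unchanged.
#'
#' @param tree a `phylo`.
#' @param table a species trait `data.frame` with a `species_id` column.
#' @param min_tips smallest usable overlap (default 3).
#' @return `list(tree=, table=, n_retained=)`.
#' @export
prune_to_shared_taxa <- function(tree, table, min_tips = 3L) {
  validate_phylogeny(tree)
  if (!is.data.frame(table) || !"species_id" %in% names(table))
    stop2("table must be a data.frame with a species_id column")
  shared <- intersect(tree$tip.label, table$species_id)
  if (length(shared) == 0L) stop2("tree and table share no species")
  if (length(shared) < min_tips)
    stop2("only %d shared species (need >= %d for comparative analysis)",
          length(shared), min_tips)
  tree2 <- ape::keep.tip(tree, shared)
  table2 <- table[match(tree2$tip.label, table$species_id), , drop = FALSE]
  rownames(table2) <- NULL
  list(tree = tree2, table = table2, n_retained = length(shared))
}
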