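## End-to-end orchestration: configuration, stage wiring, provenance
## logging and a plain-text report mirroring the analysis structure
## (category distribution, model comparison, gains/losses, regressions,
## path ranking, transition-context contrasts).

#' Pipeline configuration
#'
#' Either supply input paths (`tree_file`, `species_csv`) or leave both
#' NULL to run in simulate mode from `sim_config`. The desk-scale profile
#' shrinks tree counts and chain lengths so a full run finishes on a
#' laptop; `profile = "paper"` restores full-scale schedules.
#'
#' @param tree_file,species_csv input paths (NULL = simulate).
#' @param sim_config a [simulation_config()] for simulate mode.
#' @param out_dir output directory.
#' @param seed master seed; stage seeds derive from it by name.
#' @param stages character vector of stages to run, in dependency order.
#' @param profile `"desk"` or `"paper"`.
#' @export
pipeline_config <- function(tree_file = NULL, species_csv = NULL,
                            sim_config = simulation_config(),
                            out_dir = "castevol_out", seed = 1L,
                            stages = c("prep", "models", "asr",
                                       "regressions", "paths", "context"),
                            profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (xor(is.null(tree_file), is.null(species_csv)))
    stop2("supply both tree_file and species_csv, or neither (simulate mode)")
  if (!is.null(tree_file) && !file.exists(tree_file))
    stop2("tree file not found: %s", tree_file)
  if (!is.null(species_csv) && !file.exists(species_csv))
    stop2("species CSV not found: %s", species_csv)
  structure(list(tree_file = tree_file, species_csv = species_csv,
                 sim_config = sim_config, out_dir = out_dir,
                 seed = as.integer(seed), stages = stages,
                 profile = profile),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order and writes every
#' artifact with provenance (seed, package version, per-stage species
#' counts). A stage failure halts the run with the stage name; completed
#' artifacts persist.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a named list of stage results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop2("config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  desk <- config$profile == "desk"
  ss <- if (desk) ss_settings(n_stones = 20L, iterations = 400L) else
    ss_settings()
  results <- list()
  report <- c(sprintf("castevol pipeline report"),
              sprintf("package version: %s",
                      as.character(utils::packageVersion("castevol"))),
              sprintf("master seed: %d", config$seed),
              sprintf("profile: %s", config$profile), "")
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e)
      stop2("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    results[[name]] <<- res
    res
  }

  ## --- inputs -----------------------------------------------------------
  if (is.null(config$tree_file)) {
    sc <- config$sim_config
    sc$seed <- derive_seed(config$seed, "simulate")
    sim <- generate_study_like_dataset(sc)
    trees <- sim$trees
    table <- sim$table
    write_trees(trees, file.path(config$out_dir, "trees.nwk"))
    write.csv(table, file.path(config$out_dir, "species.csv"),
              row.names = FALSE)
    results$simulate <- sim
  } else {
    trees <- parse_trees(config$tree_file)
    table <- read_species_table(config$species_csv)
  }

  ## --- prep -------------------------------------------------------------
  run_stage("prep", function() {
    filt <- filter_species(table, required_fields = c("repro_potential",
                                                      "colony_size"))
    pruned <- prune_to_shared_taxa(trees[[1]], filt)
    dist <- table(factor(pruned$table$repro_potential, levels = 1:4))
    report <<- c(report, "== Category distribution ==",
                 paste(sprintf("category %d: %d (%.0f%%)", 1:4, dist,
                               100 * dist / sum(dist)), collapse = "\n"),
                 sprintf("n species retained: %d", pruned$n_retained), "")
    list(table = filt, pruned = pruned,
         filter_report = attr(filt, "filter_report"))
  })
  prep <- results$prep
  if (is.null(prep)) stop2("the prep stage is required by all later stages")
  cats <- setNames(prep$pruned$table$repro_potential,
                   prep$pruned$table$species_id)
  tree1 <- scale_branch_lengths(prep$pruned$tree, 0.1)

  ## --- model comparison -------------------------------------------------
  run_stage("models", function() {
    set.seed(derive_seed(config$seed, "models"))
    cmp <- compare_transition_models(tree1, cats, ss = ss,
                                     n_repeats = if (desk) 1L else 3L)
    write.csv(cmp$models, file.path(config$out_dir, "model_comparison.csv"),
              row.names = FALSE)
    report <<- c(report, "== Transition model comparison ==",
                 utils::capture.output(print(cmp)), "")
    cmp
  })

  ## --- ASR + transition counts -----------------------------------------
  run_stage("asr", function() {
    set.seed(derive_seed(config$seed, "asr"))
    sterile <- binarize_repro_potential(cats, "sterility") + 1L
    fit <- fit_mk_ml(tree1, sterile, constraint_free(2))
    Q <- build_rate_matrix(fit$params, constraint_free(2))
    nt <- min(length(trees), if (desk) 5L else length(trees))
    roots <- t(vapply(seq_len(nt), function(i) {
      tr <- scale_branch_lengths(
        prune_to_shared_taxa(trees[[i]], prep$pruned$table)$tree, 0.1)
      attr(marginal_asr(tr, sterile, Q), "root")
    }, numeric(2)))
    root_sum <- summarize_root(roots)
    sub_trees <- tree_set(lapply(seq_len(nt), function(i)
      scale_branch_lengths(
        prune_to_shared_taxa(trees[[i]], prep$pruned$table)$tree, 0.1)))
    counts <- count_transitions(sub_trees, sterile, Q, method = "joint")
    write.csv(counts$summary, file.path(config$out_dir,
                                        "transition_counts.csv"),
              row.names = FALSE)
    report <<- c(report, "== Root state (sterility, binary) ==",
                 utils::capture.output(print(root_sum)),
                 "", "== Gains / losses of sterility ==",
                 utils::capture.output(print(counts)), "")
    list(fit = fit, Q = Q, root = root_sum, counts = counts,
         trees = sub_trees, states = sterile)
  })

  ## --- regressions ------------------------------------------------------
  run_stage("regressions", function() {
    set.seed(derive_seed(config$seed, "regressions"))
    tab <- prep$pruned$table
    y <- setNames(as.numeric(tab$repro_potential), tab$species_id)
    X <- data.frame(log_colony = log10_transform(tab$colony_size),
                    row.names = tab$species_id)
    fit <- bpmm_fit(y, X, tree1, family = "gaussian",
                    settings = mcmc_settings(
                      iterations = if (desk) 4000L else 11e6,
                      burn_in = if (desk) 1000L else 1e6,
                      thinning = if (desk) 3L else 5000L, n_chains = 2L))
    write.csv(fit$coefficients, file.path(config$out_dir, "regression.csv"),
              row.names = FALSE)
    report <<- c(report, "== BPMM: reproductive potential ~ log10 colony size ==",
                 utils::capture.output(print(fit)), "")
    fit
  })

  ## --- path analysis ----------------------------------------------------
  run_stage("paths", function() {
    set.seed(derive_seed(config$seed, "paths"))
    tab <- prep$pruned$table
    pt <- data.frame(potential = as.numeric(tab$repro_potential),
                     colony = log10_transform(tab$colony_size),
                     queens = log(tab$queen_number),
                     row.names = tab$species_id)
    dags <- list(
      size_drives = causal_dag(c("potential", "colony", "queens"),
                               rbind(c("colony", "potential"),
                                     c("queens", "potential"))),
      independent = causal_dag(c("potential", "colony", "queens"),
                               rbind(c("queens", "colony"))),
      potential_drives = causal_dag(c("potential", "colony", "queens"),
                                    rbind(c("potential", "colony"),
                                          c("queens", "colony"))))
    cmp <- compare_path_models(dags, pt, tree1)
    write.csv(cmp$combined, file.path(config$out_dir, "path_models.csv"),
              row.names = FALSE)
    report <<- c(report, "== Path analysis ==",
                 utils::capture.output(print(cmp)), "")
    cmp
  })

  ## --- transition context ----------------------------------------------
  run_stage("context", function() {
    asr <- results$asr
    if (is.null(asr)) return(NULL)
    tab <- prep$pruned$table
    colony <- setNames(log10_transform(tab$colony_size), tab$species_id)
    vals <- lapply(seq_along(asr$trees$trees), function(i) {
      tr <- asr$trees[[i]]
      anc <- ancestral_continuous(tr, colony)
      v <- numeric(length(tr$tip.label) + tr$Nnode)
      v[seq_along(tr$tip.label)] <- colony[tr$tip.label]
      v[anc$node] <- anc$estimate
      v
    })
    ctx <- transition_context_compare(asr$trees, asr$counts$transitions,
                                      vals, mode = "origin-vs-nonorigin")
    report <<- c(report, "== Colony size at transition origins ==",
                 sprintf("n transitions: %d; mean difference %.3f [%.3f, %.3f]",
                         ctx$n_transitions, ctx$mean_difference, ctx$lower,
                         ctx$upper), "")
    ctx
  })

  writeLines(report, file.path(config$out_dir, "report.txt"))
  jsonlite::write_json(list(seed = config$seed,
                            version = as.character(
                              utils::packageVersion("castevol")),
                            stages = config$stages, profile = config$profile),
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(results)
}
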