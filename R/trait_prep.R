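## Trait schema, the dimorphism statistic, transformations, filtering and
## every binarization rule used downstream.
##
## A species table is a plain data.frame with (at least) these columns:
##   species_id        character, unique
##   repro_potential   integer 1..4 (1 full sexual capacity ... 4 sterile)
##   realised_repro    "sexual" | "male_only" | "none"
##   confidence        "described" | "inferred"
##   colony_size       positive real (workers per colony, all nests)
##   queen_number      positive real (queens per colony)
##   mating_frequency  positive real (effective mates, sire-share weighted)
##   queen_head_widths_mm / worker_head_widths_mm  ";"-separated positive reals
##   excluded_flags    ""-or-";"-separated subset of
##                     {supercolonial, social_parasite, clonal, hybrid}

EXCLUDE_FLAGS <- c("supercolonial", "social_parasite", "clonal", "hybrid")

#' Read a species trait table from CSV
#'
#' @param path CSV path.
#' @return a validated species `data.frame`.
#' @export
read_species_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_species_table(tab)
}

#' @rdname read_species_table
#' @param table a data.frame to validate in place.
#' @export
validate_species_table <- function(table) {
  if (!"species_id" %in% names(table)) stop2("missing species_id column")
  if (anyDuplicated(table$species_id))
    stop2("duplicated species_id: %s",
          paste(unique(table$species_id[duplicated(table$species_id)]),
                collapse = ", "))
  if ("repro_potential" %in% names(table)) {
    bad <- !is.na(table$repro_potential) &
      !table$repro_potential %in% 1:4
    if (any(bad))
      stop2("repro_potential outside 1..4 for: %s",
            paste(table$species_id[bad], collapse = ", "))
  }
  for (col in c("colony_size", "queen_number", "mating_frequency")) {
    if (col %in% names(table)) {
      bad <- !is.na(table[[col]]) & table[[col]] <= 0
      if (any(bad)) stop2("%s must be > 0 (violations: %s)", col,
                          paste(table$species_id[bad], collapse = ", "))
    }
  }
  table
}

## Parse a ";"-separated measurement list column entry.
parse_widths <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

has_flag <- function(flags, which) {
  vapply(strsplit(ifelse(is.na(flags), "", flags), ";", fixed = TRUE),
         function(f) any(trimws(f) %in% which), logical(1))
}

#' Filter a species table for analysis
#'
#' Removes species carrying any exclusion flag (supercolonial, socially
#' parasitic, clonal, hybrid — lineages with incomparable life histories)
#' and species missing any required field. The removal counts per reason are
#' attached as attribute `"filter_report"`.
#'
#' @param table species data.frame.
#' @param required_fields character vector of column names that must be
#'   non-missing.
#' @param include_supercolonial keep supercolonial species (robustness
#'   re-runs).
#' @param confidence_subset `"all"` or `"described"` (high-confidence only).
#' @return the filtered table with a `filter_report` attribute.
#' @export
filter_species <- function(table, required_fields = character(0),
                           include_supercolonial = FALSE,
                           confidence_subset = c("all", "described")) {
  confidence_subset <- match.arg(confidence_subset)
  validate_species_table(table)
  flags <- table$excluded_flags %||% rep("", nrow(table))
  drop_flags <- EXCLUDE_FLAGS
  if (include_supercolonial)
    drop_flags <- setdiff(drop_flags, "supercolonial")
  report <- list()
  keep <- rep(TRUE, nrow(table))
  for (fl in drop_flags) {
    hit <- has_flag(flags, fl) & keep
    report[[fl]] <- sum(hit)
    keep <- keep & !hit
  }
  if (length(required_fields)) {
    miss <- rep(FALSE, nrow(table))
    for (col in required_fields) {
      if (!col %in% names(table)) stop2("required field absent: %s", col)
      miss <- miss | is.na(table[[col]])
    }
    hit <- miss & keep
    report[["missing"]] <- sum(hit)
    keep <- keep & !hit
  }
  if (confidence_subset == "described" && "confidence" %in% names(table)) {
    hit <- keep & table$confidence != "described"
    report[["not_described"]] <- sum(hit)
    keep <- keep & !hit
  }
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop2("no species remain after filtering")
  rownames(out) <- NULL
  attr(out, "filter_report") <- report
  out
}

#' Queen-worker size dimorphism
#'
#' Maximum reproductive size dimorphism within a species: mean queen head
#' width divided by the minimum worker head width (the smallest individual
#' worker). A value of 1.0 means queens and workers are the same size;
#' values above 1 mean queens are larger. Unit-free (scale invariant).
#'
#' @param queen_widths_mm,worker_widths_mm nonempty vectors of positive
#'   head widths (any common unit).
#' @return positive real dimorphism ratio.
#' @export
compute_dimorphism <- function(queen_widths_mm, worker_widths_mm) {
  if (length(queen_widths_mm) == 0L || length(worker_widths_mm) == 0L)
    stop2("both queen and worker width lists must be nonempty")
  if (any(queen_widths_mm <= 0) || any(worker_widths_mm <= 0))
    stop2("head widths must be positive")
  mean(queen_widths_mm) / min(worker_widths_mm)
}

#' Base-10 logarithm for positive trait values
#'
#' @param value positive real (vectorized).
#' @export
log10_transform <- function(value) {
  if (any(is.na(value)) || any(value <= 0))
    stop2("log10_transform requires strictly positive values")
  log10(value)
}

#' Binarize a continuous trait around its median or mean with a buffer zone
#'
#' Species falling in the central `buffer_fraction` of the rank-ordered
#' values around the center statistic are dropped (a "buffer zone" guards
#' the dichotomy against species essentially at the threshold); remaining
#' species score 1 above the center and 0 at-or-below it. The number
#' dropped is exactly `round(buffer_fraction * n)`, split as evenly as rank
#' order allows around the center (ties broken by rank).
#'
#' @param values named numeric vector (names = species ids); NAs dropped
#'   with a record.
#' @param center `"median"` or `"mean"`.
#' @param buffer_fraction fraction in [0, 0.5) of species to drop centrally.
#' @return a `binary_trait`: list(values = named 0/1 vector, dropped =
#'   character, center_stat, center_value, buffer_fraction).
#' @export
binarize_by_center <- function(values, center = c("median", "mean"),
                               buffer_fraction = 0) {
  center <- match.arg(center)
  if (buffer_fraction < 0 || buffer_fraction >= 0.5)
    stop2("buffer_fraction must be in [0, 0.5)")
  if (is.null(names(values))) stop2("values must be named by species")
  values <- values[!is.na(values)]
  if (length(values) < 4L) stop2("need at least 4 non-missing values")
  if (length(unique(values)) == 1L)
    stop2("all values identical: nothing to binarize")
  cval <- if (center == "median") median(values) else mean(values)
  n <- length(values)
  ndrop <- round(buffer_fraction * n)
  ord <- order(values)  # ties broken by input (rank) order
  dropped <- character(0)
  if (ndrop > 0) {
    ## ranks nearest the center value, symmetric by rank
    dist_to_center <- abs(values[ord] - cval)
    drop_idx <- ord[order(dist_to_center, seq_len(n))[seq_len(ndrop)]]
    dropped <- names(values)[drop_idx]
  }
  kept <- setdiff(names(values), dropped)
  assigned <- ifelse(values[kept] > cval, 1L, 0L)
  names(assigned) <- kept
  structure(list(values = assigned, dropped = dropped,
                 center_stat = center, center_value = cval,
                 buffer_fraction = buffer_fraction),
            class = "binary_trait")
}

#' Binarize at the threshold of two
#'
#' The polygyny / polyandry rule: two or more queens per colony (or two or
#' more effective matings) scores 1; fewer scores 0. No buffer, no drops.
#'
#' @param values named numeric vector.
#' @return a `binary_trait`.
#' @export
binarize_at_two <- function(values) {
  if (is.null(names(values))) stop2("values must be named by species")
  keep <- !is.na(values)
  assigned <- ifelse(values[keep] >= 2, 1L, 0L)
  names(assigned) <- names(values)[keep]
  structure(list(values = assigned, dropped = character(0),
                 center_stat = "fixed-two", center_value = 2,
                 buffer_fraction = 0),
            class = "binary_trait")
}

#' Binarize worker reproductive potential categories
#'
#' Two schemes: `"sex"` contrasts workers able to produce female (sexual)
#' offspring (categories 1, 2 -> 0) with those that cannot (3, 4 -> 1);
#' `"sterility"` contrasts any reproductive capacity (1, 2, 3 -> 0) with
#' complete sterility (4 -> 1).
#'
#' @param category integer vector in 1..4.
#' @param scheme `"sex"` or `"sterility"`.
#' @return integer 0/1 vector (names preserved).
#' @export
binarize_repro_potential <- function(category, scheme = c("sex", "sterility")) {
  scheme <- match.arg(scheme)
  if (any(is.na(category)) || !all(category %in% 1:4))
    stop2("categories must be in 1..4")
  out <- if (scheme == "sex") as.integer(category >= 3) else
    as.integer(category == 4)
  names(out) <- names(category)
  out
}

#' @exportS3Method base::print
print.binary_trait <- function(x, ...) {
  cat(sprintf(
    "binary_trait: %d species (%d ones / %d zeros), %d dropped; center=%s (%.4g), buffer=%.2f\n",
    length(x$values), sum(x$values == 1), sum(x$values == 0),
    length(x$dropped), x$center_stat, x$center_value, x$buffer_fraction))
  invisible(x)
}

#' Write binarization metadata as a JSON sidecar report
#'
#' @param trait a `binary_trait`.
#' @param path output path.
#' @export
write_binarization_report <- function(trait, path) {
  jsonlite::write_json(
    list(center_stat = trait$center_stat,
         center_value = trait$center_value,
         buffer_fraction = trait$buffer_fraction,
         n_assigned = length(trait$values),
         n_dropped = length(trait$dropped),
         dropped = trait$dropped),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
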