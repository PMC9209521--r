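#' Exposure schema entry
#'
#' Describes one exposure in the cohort: its measurement type, the rounds in
#' which it was measured, and - for categorical exposures - the category
#' labels plus the state sets that define its summary features (occupancy
#' proportions and reference-to-target transition indicators).
#'
#' @param exposure_id Short unique identifier (used in feature names).
#' @param var_type `"continuous"` or `"categorical"`.
#' @param rounds_measured Integer vector of measurement rounds (1-based),
#'   strictly positive. A single round flags the exposure as pass-through:
#'   its latest observed value enters the feature table unchanged and no
#'   AUE/TOE summaries are formed.
#' @param domain One of `"demographic"`, `"lifestyle"`, `"environmental"`,
#'   `"biological"`.
#' @param label Human-readable label (defaults to `exposure_id`).
#' @param categories Ordered character vector of category labels
#'   (categorical only).
#' @param aue_states List of character vectors, each a set of states whose
#'   occupancy proportion becomes one AUE feature. Defaults to the first
#'   category as a single state set.
#' @param reference_states,target_states Disjoint subsets of `categories`
#'   defining the transition indicator (TOE) for categorical exposures:
#'   the feature is 1 when a reference-state observation is later followed
#'   by a target-state observation.
#'
#' @return An object of class `exposure_schema_entry`.
#' @export
schema_entry <- function(exposure_id, var_type, rounds_measured, domain,
                         label = exposure_id, categories = NULL,
                         aue_states = NULL, reference_states = NULL,
                         target_states = NULL) {
  var_type <- match.arg(var_type, c("continuous", "categorical"))
  domain <- match.arg(domain, c("demographic", "lifestyle",
                                "environmental", "biological"))
  rounds_measured <- sort(unique(as.integer(rounds_measured)))
  if (length(rounds_measured) == 0L || any(rounds_measured < 1L))
    stop("schema error: rounds_measured must be a non-empty set of rounds >= 1 for '",
         exposure_id, "'")
  if (var_type == "categorical") {
    if (is.null(categories) || length(categories) < 2L)
      stop("schema error: categorical exposure '", exposure_id,
           "' needs >= 2 categories")
    if (is.null(aue_states)) aue_states <- list(categories[1L])
    if (!is.list(aue_states)) aue_states <- list(aue_states)
    for (s in aue_states)
      if (!all(s %in% categories))
        stop("schema error: aue_states outside categories for '", exposure_id, "'")
    if (length(rounds_measured) > 1L) {
      if (is.null(reference_states)) reference_states <- categories[1L]
      if (is.null(target_states)) target_states <- setdiff(categories, reference_states)[1L]
      if (!all(c(reference_states, target_states) %in% categories))
        stop("schema error: reference/target states outside categories for '",
             exposure_id, "'")
      if (length(intersect(reference_states, target_states)) > 0L)
        stop("schema error: reference_states and target_states overlap for '",
             exposure_id, "'")
    }
  } else {
    categories <- NULL; aue_states <- NULL
    reference_states <- NULL; target_states <- NULL
  }
  structure(list(exposure_id = as.character(exposure_id), label = label,
                 var_type = var_type, rounds_measured = rounds_measured,
                 domain = domain, categories = categories,
                 aue_states = aue_states,
                 reference_states = reference_states,
                 target_states = target_states,
                 single_round = length(rounds_measured) == 1L),
            class = "exposure_schema_entry")
}

#' Read an exposure schema from YAML or JSON
#'
#' The file holds a list of entries; each entry carries the fields of
#' [schema_entry()]. Format is chosen by file extension (`.yaml`/`.yml`
#' or `.json`).
#'
#' @param path Path to the schema file.
#' @return A named list of `exposure_schema_entry` objects (an object of
#'   class `exposure_schema`).
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema error: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  entries <- lapply(raw, function(e) {
    schema_entry(exposure_id = e$exposure_id,
                 var_type = e$var_type,
                 rounds_measured = unlist(e$rounds_measured),
                 domain = e$domain,
                 label = if (is.null(e$label)) e$exposure_id else e$label,
                 categories = if (is.null(e$categories)) NULL else unlist(e$categories),
                 aue_states = if (is.null(e$aue_states)) NULL else
                   lapply(e$aue_states, unlist),
                 reference_states = if (is.null(e$reference_states)) NULL else
                   unlist(e$reference_states),
                 target_states = if (is.null(e$target_states)) NULL else
                   unlist(e$target_states))
  })
  as_schema(entries)
}

#' Assemble schema entries into a schema
#'
#' @param entries List of `exposure_schema_entry` objects.
#' @return Named list of class `exposure_schema`.
#' @export
as_schema <- function(entries) {
  ids <- vapply(entries, `[[`, character(1), "exposure_id")
  if (anyDuplicated(ids))
    stop("schema error: duplicate exposure_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(entries) <- ids
  structure(entries, class = "exposure_schema")
}

#' Write a schema to YAML
#'
#' @param schema An `exposure_schema`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  out <- lapply(unname(schema), function(e) {
    e <- unclass(e)
    e$single_round <- NULL
    e[!vapply(e, is.null, logical(1))]
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
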