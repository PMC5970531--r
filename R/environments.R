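# Environments: named sets of source metabolites seeding network expansion.
# The host is represented solely by the metabolites it provides; the
# host+obligate environment is derived by adding everything the obligate
# symbiont can make from the host-only pool.

#' Construct an environment (named source-metabolite set)
#'
#' @param name Environment name, propagated into every downstream result so
#'   that outputs from different environments can never be silently mixed.
#' @param source_metabolites Character vector of compound ids (duplicates
#'   collapsed; must be non-empty).
#' @return An object of class `environment_set`.
#' @export
environment_set <- function(name, source_metabolites) {
  source_metabolites <- unique(as.character(source_metabolites))
  if (length(source_metabolites) == 0L) {
    stop("environment '", name, "' is empty: environments must contain at ",
         "least one source metabolite")
  }
  structure(list(name = name, source_metabolites = source_metabolites),
            class = "environment_set")
}

#' @export
print.environment_set <- function(x, ...) {
  cat("<environment_set> '", x$name, "': ", length(x$source_metabolites),
      " source metabolites\n", sep = "")
  invisible(x)
}

read_compound_lines <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(sub("#.*$", "", readLines(path)))
  unique(lines[nzchar(lines)])
}

#' Read an environment file (one compound id per line, '#' comments allowed)
#'
#' @param path Path to the environment file.
#' @param name Environment name; defaults to the file stem.
#' @param universe Optional [reaction_universe()] used to validate that all
#'   ids resolve; an unknown id is an error naming it.
#' @param quiet Suppress the loaded-count message.
#' @return An [environment_set()].
#' @export
load_environment <- function(path, name = NULL, universe = NULL,
                             quiet = FALSE) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  ids <- read_compound_lines(path)
  if (!is.null(universe)) {
    miss <- setdiff(ids, universe$compounds$id)
    if (length(miss)) {
      stop("environment '", name, "' references compound(s) unknown to the ",
           "universe: ", paste(miss, collapse = ", "))
    }
  }
  env <- environment_set(name, ids)
  if (!quiet) {
    message("environment '", name, "': ", length(env$source_metabolites),
            " source metabolites")
  }
  env
}

#' Construct a target (essential metabolite) panel
#'
#' @param targets Character vector of compound ids.
#' @return An object of class `target_set`.
#' @export
target_set <- function(targets) {
  structure(list(targets = unique(as.character(targets))),
            class = "target_set")
}

#' Read a target panel file (one compound id per line)
#'
#' @inheritParams load_environment
#' @return A [target_set()].
#' @export
load_targets <- function(path, universe = NULL) {
  ids <- read_compound_lines(path)
  if (!is.null(universe)) {
    miss <- setdiff(ids, universe$compounds$id)
    if (length(miss)) {
      stop("target panel references compound(s) unknown to the universe: ",
           paste(miss, collapse = ", "))
    }
  }
  target_set(ids)
}

#' Write an environment or target panel file
#'
#' @param x An `environment_set` or `target_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compound_set <- function(x, path) {
  ids <- if (inherits(x, "environment_set")) x$source_metabolites else
    if (inherits(x, "target_set")) x$targets else as.character(x)
  writeLines(sort(ids), path)
  invisible(path)
}

#' Derive the host+obligate environment from the host-only environment
#'
#' The obligate symbiont's metabolic activity is simulated in the host-only
#' environment and the full resulting scope — host metabolites plus
#' everything the symbiont can make from them — becomes the enriched
#' environment.  (Since seeds are part of the scope, including the whole
#' scope and adding only the new compounds are the same set.)  The derived
#' name records the provenance: `"<host name>+<organism id>"`.
#'
#' @param host_env The host-only [environment_set()].
#' @param obligate The obligate symbiont's `metabolic_network` (derived from
#'   the same universe as all other networks under analysis).
#' @return An enriched [environment_set()]; always a superset of
#'   `host_env`, and idempotent under re-application with the same network.
#' @export
derive_host_obligate_env <- function(host_env, obligate) {
  res <- expand_scope(host_env, obligate)
  environment_set(paste0(host_env$name, "+", obligate$organism_id),
                  res$scope)
}
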