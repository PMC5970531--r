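# Network expansion (scope): the fixed point of "if all substrates of a
# reaction are available, its products become available".

#' Expand a metabolic network from a seed set
#'
#' Computes the scope of a seed set: the smallest superset of the seeds
#' closed under firing every reaction whose substrates are all present.
#' The model is purely qualitative reachability — no stoichiometric
#' balancing, fluxes or quantities — and the result is the unique least
#' fixed point, independent of the order in which reactions are considered.
#'
#' The implementation keeps, for every reaction, a count of substrates not
#' yet in scope and processes a worklist of newly satisfied reactions, so
#' each reaction fires at most once and each compound is inserted once.
#' A reaction producing one of its own substrates is legal; fixed-point
#' semantics handles autocatalysis with no special casing.
#'
#' @param seeds Character vector of seed compound ids (an `environment_set`
#'   is also accepted).
#' @param network A `metabolic_network`.
#' @param universe Optional [reaction_universe()]; when supplied, seeds not
#'   present in the universe raise an error listing the offenders.
#' @param environment_name Name recorded in the result (defaults to the
#'   environment's name, or `"ad_hoc"` for bare seed vectors).
#' @return An object of class `expansion_result` with fields `scope`
#'   (compound ids, includes the seeds), `active_reactions` (ids of
#'   reactions that fired), `organism_id` and `environment_name`.
#' @examples
#' u <- make_linear_pathway(3, "demo")
#' net <- network_from_ecs(u, universe_ecs(u), quiet = TRUE)
#' expand_scope("demo_c0", net)$scope
#' @export
expand_scope <- function(seeds, network, universe = NULL,
                         environment_name = NULL) {
  if (inherits(seeds, "environment_set")) {
    if (is.null(environment_name)) environment_name <- seeds$name
    seeds <- seeds$source_metabolites
  }
  if (is.null(environment_name)) environment_name <- "ad_hoc"
  seeds <- unique(as.character(seeds))
  if (!is.null(universe)) {
    miss <- setdiff(seeds, universe$compounds$id)
    if (length(miss)) {
      stop("seed compound(s) not in universe: ", paste(miss, collapse = ", "))
    }
  }
  rxns <- network$reactions
  n <- length(rxns)
  scope <- seeds
  active <- character()
  if (n > 0L) {
    subs <- lapply(rxns, `[[`, "substrates")
    sub2rxn <- split(rep(seq_len(n), lengths(subs)), unlist(subs))
    in_scope <- new.env(parent = emptyenv())
    for (s in seeds) assign(s, TRUE, envir = in_scope)
    unmet <- vapply(subs, function(s) sum(!s %in% seeds), 0L)
    fired <- logical(n)
    queue <- which(unmet == 0L)
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      if (fired[i]) next
      fired[i] <- TRUE
      for (p in rxns[[i]]$products) {
        if (!exists(p, envir = in_scope, inherits = FALSE)) {
          assign(p, TRUE, envir = in_scope)
          scope <- c(scope, p)
          waiting <- sub2rxn[[p]]
          if (!is.null(waiting)) {
            for (j in waiting) {
              unmet[j] <- unmet[j] - 1L
              if (unmet[j] == 0L && !fired[j]) queue <- c(queue, j)
            }
          }
        }
      }
    }
    active <- names(rxns)[fired]
  }
  structure(list(scope = scope, active_reactions = active,
                 organism_id = network$organism_id,
                 environment_name = environment_name),
            class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat("<expansion_result> ", x$organism_id, " in '", x$environment_name,
      "': scope ", length(x$scope), " compounds, ",
      length(x$active_reactions), " active reactions\n", sep = "")
  invisible(x)
}

#' Assess growth capacity as target-panel coverage
#'
#' Growth capacity in an environment is proxied by the number of target
#' (essential) metabolites — amino acids, nucleotides, cofactors — present
#' in the expanded scope.
#'
#' @param result An `expansion_result` (or a bare character scope).
#' @param targets A `target_set` or character vector of target compound ids.
#' @return An object of class `growth_assessment` with `produced_targets`,
#'   `n_produced` and `environment_name`.
#' @export
assess_growth <- function(result, targets) {
  if (inherits(targets, "target_set")) targets <- targets$targets
  scope <- if (inherits(result, "expansion_result")) result$scope else result
  env_name <- if (inherits(result, "expansion_result")) {
    result$environment_name
  } else "ad_hoc"
  produced <- sort(intersect(scope, targets))
  structure(list(produced_targets = produced, n_produced = length(produced),
                 environment_name = env_name),
            class = "growth_assessment")
}

#' List all ECs present in a universe (convenience for whole-universe networks)
#'
#' @param universe A [reaction_universe()].
#' @return Character vector of EC numbers.
#' @export
universe_ecs <- function(universe) {
  names(universe$ec_index)
}
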