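# Topology-derived seed sets and effective metabolic overlap (competition),
# plus single-source-metabolite dependency scans in a fixed environment.

#' Predict a network's seed set from its topology
#'
#' Builds the directed compound graph (an edge substrate -> product for
#' every reaction), condenses it into strongly connected components, and
#' takes as seeds all compounds lying in source components — components
#' with no incoming edge from outside themselves.  Seeds are the
#' topology-predicted exogenously required resources of the organism.
#' Components of size > 1 contribute all their members, unweighted.
#'
#' @param network A `metabolic_network`.
#' @return An object of class `seed_set` with fields `organism_id`,
#'   `seeds` (compound ids) and `seed_components` (list partitioning the
#'   seeds into their source components).  An empty network yields an
#'   empty seed set with a warning.
#' @export
seed_set <- function(network) {
  if (length(network$reactions) == 0L) {
    warning("network for ", network$organism_id,
            " is empty: empty seed set", call. = FALSE)
    return(structure(list(organism_id = network$organism_id,
                          seeds = character(), seed_components = list()),
                     class = "seed_set"))
  }
  edges <- do.call(rbind, lapply(network$reactions, function(r) {
    expand.grid(from = r$substrates, to = r$products,
                stringsAsFactors = FALSE)
  }))
  verts <- network_compounds(network)
  g <- igraph::graph_from_data_frame(unique(edges), directed = TRUE,
                                     vertices = verts)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  el <- igraph::as_edgelist(g, names = TRUE)
  cross <- memb[el[, 1]] != memb[el[, 2]]
  has_incoming <- unique(memb[el[cross, 2]])
  source_comps <- setdiff(seq_len(comp$no), has_incoming)
  seeds <- names(memb)[memb %in% source_comps]
  parts <- split(names(memb), memb)[as.character(source_comps)]
  structure(list(organism_id = network$organism_id,
                 seeds = sort(seeds),
                 seed_components = unname(lapply(parts, sort))),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("<seed_set> ", x$organism_id, ": ", length(x$seeds), " seeds in ",
      length(x$seed_components), " source component(s)\n", sep = "")
  invisible(x)
}

#' Effective metabolic overlap of one organism with another
#'
#' Asymmetric competition score: the fraction of the row organism's
#' producible targets lost when the resources it shares with the column
#' organism are withheld.  The row organism is first expanded in its
#' "optimal" environment — its own topology-predicted seed set — and then
#' in the reduced environment from which seeds shared with the column
#' organism's seed set are excluded; the score is
#' `(T_opt - T_red) / T_opt`, or 0 when `T_opt` is 0 (an organism that
#' produces nothing cannot be outcompeted in this metric).  The score is
#' the effect of the COLUMN organism on the ROW organism and lies in
#' `[0, 1]`.
#'
#' @param row,col `metabolic_network` objects from the same universe.
#' @param targets A `target_set` of essential metabolites.
#' @return A single numeric score in `[0, 1]`.
#' @export
competition_score <- function(row, col, targets) {
  s_row <- if (inherits(row, "seed_set")) row else seed_set(row)
  s_col <- if (inherits(col, "seed_set")) col else seed_set(col)
  net <- if (inherits(row, "seed_set")) {
    stop("`row` must be a metabolic_network (its seed set is derived ",
         "internally)")
  } else row
  compete_from_seeds(net, s_row$seeds, s_col$seeds, targets)
}

compete_from_seeds <- function(row_net, row_seeds, col_seeds, targets) {
  if (length(row_seeds) == 0L) return(0)
  t_opt <- assess_growth(expand_scope(row_seeds, row_net,
                                      environment_name = "optimal"),
                         targets)$n_produced
  if (t_opt == 0L) return(0)
  reduced <- setdiff(row_seeds, col_seeds)
  t_red <- assess_growth(expand_scope(reduced, row_net,
                                      environment_name = "reduced"),
                         targets)$n_produced
  (t_opt - t_red) / t_opt
}

#' All-pairs competition matrix
#'
#' Computes [competition_score()] for every ordered pair of networks;
#' asymmetry is preserved.  Cell `[i, j]` is the effect of organism `j`
#' (column) on organism `i` (row).  The diagonal is `NA` by convention and
#' excluded from summaries.
#'
#' @param networks List of at least two `metabolic_network` objects.
#' @param targets A `target_set`.
#' @return An object of class `competition_matrix`: a numeric matrix with
#'   organism ids as dimnames and attribute `environment_basis = "optimal"`.
#' @export
competition_matrix <- function(networks, targets) {
  if (length(networks) < 2L) stop("need at least 2 networks")
  ids <- vapply(networks, `[[`, "", "organism_id")
  if (anyDuplicated(ids)) stop("duplicate organism ids")
  seeds <- lapply(networks, seed_set)
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      m[i, j] <- compete_from_seeds(networks[[i]], seeds[[i]]$seeds,
                                    seeds[[j]]$seeds, targets)
    }
  }
  structure(m, class = c("competition_matrix", "matrix"),
            environment_basis = "optimal")
}

#' Single-source-metabolite dependency scan
#'
#' Quantifies how much each environment component matters to an organism:
#' for every source metabolite, the environment is reduced by that single
#' metabolite and the number of target metabolites that can no longer be
#' produced is recorded.  By monotonicity of expansion the count is always
#' non-negative, and a source not consumed (directly or indirectly) by the
#' network scores 0.
#'
#' @param network A `metabolic_network`.
#' @param env A non-empty [environment_set()] (the reference
#'   bacteriocyte-like environment).
#' @param targets A `target_set`.
#' @return Named integer vector over the environment's source metabolites:
#'   targets lost upon each single removal.
#' @export
dependency_scan <- function(network, env, targets) {
  src <- env$source_metabolites
  baseline <- assess_growth(expand_scope(src, network), targets)$n_produced
  losses <- vapply(src, function(s) {
    baseline - assess_growth(expand_scope(setdiff(src, s), network),
                             targets)$n_produced
  }, 0L)
  stats::setNames(as.integer(losses), src)
}

#' Dependency table over several organisms
#'
#' Runs [dependency_scan()] for each network; rows are organisms, columns
#' the environment's source metabolites.
#'
#' @inheritParams dependency_scan
#' @param networks List of `metabolic_network` objects.
#' @return Integer matrix (organisms x source metabolites) of class
#'   `dependency_table`.
#' @export
dependency_table <- function(networks, env, targets) {
  rows <- lapply(networks, dependency_scan, env = env, targets = targets)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(networks, `[[`, "", "organism_id")
  structure(m, class = c("dependency_table", "matrix"))
}
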