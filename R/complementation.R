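# Complementary (synergistic) metabolites: compounds producible by a
# combination of genomes but by none of its members alone, in a given
# environment.  Three stages: merge the reaction sets, co-expand in the
# environment, subtract what the individual members reach.

scope_of <- function(network, env) {
  expand_scope(env, network)$scope
}

#' Detect pairwise complementary metabolites
#'
#' A metabolite is complementary for a pair if the merged network produces
#' it from the environment while neither member alone does:
#' `scope(a+b) \ (scope(a) U scope(b))`.  The result is symmetric in the
#' two members.
#'
#' @param a,b `metabolic_network` objects derived from the same universe,
#'   with distinct organism ids.
#' @param env An [environment_set()] supplying the source metabolites.
#' @return An object of class `complementation_result` with fields
#'   `member_ids`, `environment_name` and `complementary` (sorted compound
#'   ids).
#' @export
complementary_metabolites <- function(a, b, env) {
  if (identical(a$organism_id, b$organism_id)) {
    stop("pair members must have distinct organism ids")
  }
  kwise_complementary(list(a, b), env)
}

#' Detect k-wise complementary metabolites
#'
#' Generalizes the pairwise definition: the k-combination's complementary
#' set is what the full merged network produces beyond the union of the
#' scopes of every proper non-empty sub-combination.  For k = 2 this
#' reduces exactly to [complementary_metabolites()].
#'
#' @param members List of at least two `metabolic_network` objects.
#' @param env An [environment_set()].
#' @return A `complementation_result`.
#' @export
kwise_complementary <- function(members, env) {
  k <- length(members)
  if (k < 2L) stop("need at least 2 member networks")
  full <- scope_of(merge_networks(members), env)
  covered <- character()
  for (m in seq_len(k - 1L)) {
    for (idx in utils::combn(k, m, simplify = FALSE)) {
      covered <- union(covered,
                       scope_of(merge_networks(members[idx]), env))
    }
  }
  structure(list(member_ids = vapply(members, `[[`, "", "organism_id"),
                 environment_name = env$name,
                 complementary = sort(setdiff(full, covered))),
            class = "complementation_result")
}

#' @export
print.complementation_result <- function(x, ...) {
  cat("<complementation_result> ", paste(x$member_ids, collapse = " + "),
      " in '", x$environment_name, "': ", length(x$complementary),
      " complementary metabolite(s)\n", sep = "")
  invisible(x)
}

#' Classify environment masking of pairwise complementary metabolites
#'
#' A pairwise complementary metabolite found in the host-only environment
#' may disappear once the environment is enriched by the obligate
#' symbiont's products — it is then "masked": an alternative production
#' route through the obligate symbiont exists.  Each metabolite that is
#' complementary in at least one environment is labelled `both_envs`,
#' `host_only`, or `host_obligate_only`.
#'
#' @param a,b `metabolic_network` objects.
#' @param env_host Host-only [environment_set()].
#' @param env_hp Enriched environment derived from `env_host` (see
#'   [derive_host_obligate_env()]).
#' @return Named character vector: metabolite id -> label.  Empty when both
#'   complementary sets are empty.
#' @export
masking_classify <- function(a, b, env_host, env_hp) {
  ch <- complementary_metabolites(a, b, env_host)$complementary
  cp <- complementary_metabolites(a, b, env_hp)$complementary
  all_ids <- sort(union(ch, cp))
  labels <- ifelse(all_ids %in% ch & all_ids %in% cp, "both_envs",
                   ifelse(all_ids %in% ch, "host_only", "host_obligate_only"))
  stats::setNames(labels, all_ids)
}

#' Assemble a combination-by-metabolite complementation profile
#'
#' Builds the binary incidence matrix over the union of all observed
#' complementary metabolites (columns in lexicographic order), one row per
#' combination/environment.  Row sums equal the per-combination
#' complementary counts.
#'
#' @param results List of `complementation_result` objects.
#' @return An object of class `complementation_profile` with fields
#'   `incidence` (binary matrix), `rows` (labels) and `columns`.
#' @export
build_profile <- function(results) {
  if (length(results) == 0L) stop("no complementation results supplied")
  labels <- vapply(results, function(r) {
    paste0(paste(r$member_ids, collapse = "+"), " [", r$environment_name, "]")
  }, "")
  cols <- sort(unique(unlist(lapply(results, `[[`, "complementary"))))
  inc <- matrix(0L, nrow = length(results), ncol = length(cols),
                dimnames = list(labels, cols))
  for (i in seq_along(results)) {
    inc[i, results[[i]]$complementary] <- 1L
  }
  structure(list(incidence = inc, rows = labels, columns = cols),
            class = "complementation_profile")
}

#' @export
print.complementation_profile <- function(x, ...) {
  cat("<complementation_profile> ", nrow(x$incidence), " combinations x ",
      ncol(x$incidence), " metabolites\n", sep = "")
  invisible(x)
}

#' PCA and hierarchical clustering of complementation profiles
#'
#' Principal components of the centered (unscaled) binary incidence
#' matrix, with a fixed sign convention (the largest-magnitude loading of
#' each component is made positive, so results are deterministic), plus
#' hierarchical clustering of the rows on Euclidean distances.
#'
#' @param profile A `complementation_profile` with at least two rows.
#' @param n_components Number of principal components to keep (default 2,
#'   capped at the available rank).
#' @param k Number of clusters to cut the dendrogram into (default
#'   `min(4, rows)`).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return List with `coordinates` (rows x components), `loadings`,
#'   `variance_explained`, `clusters` (named integer vector) and `tree`
#'   (the `hclust` object).  All-identical rows trigger a zero-variance
#'   warning and all-zero coordinates.
#' @export
pca_cluster_profiles <- function(profile, n_components = 2,
                                 k = NULL, linkage = "average") {
  inc <- profile$incidence
  if (nrow(inc) < 2L) stop("need at least 2 profile rows")
  if (is.null(k)) k <- min(4L, nrow(inc))
  centered <- scale(inc, center = TRUE, scale = FALSE)
  zero_var <- all(abs(centered) < .Machine$double.eps^0.5)
  n_components <- min(n_components, nrow(inc) - 1L, max(ncol(inc), 1L))
  if (zero_var) {
    warning("all profile rows are identical: zero variance, coordinates ",
            "set to 0", call. = FALSE)
    coords <- matrix(0, nrow(inc), n_components,
                     dimnames = list(rownames(inc),
                                     paste0("PC", seq_len(n_components))))
    loadings <- matrix(0, ncol(inc), n_components,
                       dimnames = list(colnames(inc),
                                       paste0("PC", seq_len(n_components))))
    varex <- rep(0, n_components)
  } else {
    p <- stats::prcomp(inc, center = TRUE, scale. = FALSE)
    keep <- seq_len(min(n_components, ncol(p$x)))
    coords <- p$x[, keep, drop = FALSE]
    loadings <- p$rotation[, keep, drop = FALSE]
    # sign convention: largest-|loading| entry of each PC is positive
    for (j in seq_along(keep)) {
      m <- which.max(abs(loadings[, j]))
      if (loadings[m, j] < 0) {
        loadings[, j] <- -loadings[, j]
        coords[, j] <- -coords[, j]
      }
    }
    varex <- (p$sdev^2 / sum(p$sdev^2))[keep]
  }
  tree <- stats::hclust(stats::dist(inc, method = "euclidean"),
                        method = linkage)
  clusters <- stats::cutree(tree, k = min(k, nrow(inc)))
  list(coordinates = coords, loadings = loadings,
       variance_explained = varex, clusters = clusters, tree = tree)
}
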