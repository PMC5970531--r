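# End-to-end orchestration: expand -> complement -> compete -> depend ->
# stats, from a single YAML/JSON config, with deterministic TSV outputs
# and a metadata sidecar.

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

#' Run the full reverse-ecology pipeline
#'
#' Loads the universe, per-organism EC lists, environment and target
#' panel; reconstructs the per-organism networks; expands every organism
#' in the host-only environment (and in a second environment, either
#' given explicitly or derived from a named obligate organism); detects
#' pairwise complementary metabolites in both environments and classifies
#' masking; computes the all-pairs competition matrix and the
#' single-metabolite dependency table; and writes all reports plus a
#' metadata sidecar (`run_metadata.json`: inputs, checksums, seed,
#' package version) into the output directory.
#'
#' @param config A YAML/JSON file path or a list with keys:
#'   `universe`, `ec_dir` (directory of one EC list per organism) or
#'   `ec_files`, `environment`, `targets`, `out`; optional
#'   `derive_env2_from` (organism id whose products enrich the second
#'   environment), `env2` (explicit second environment file),
#'   `occurrence` (occurrence table for the association test), `genus`
#'   (named organism -> genus map; defaults to id prefixes), `strict_ec`,
#'   `kmax` (maximum combination size searched, default 2), `seed`.
#' @param overrides Named list merged over the config (flag-over-config
#'   semantics).
#' @return Invisibly, a list with all intermediate objects (`networks`,
#'   `expansions`, `complementation`, `competition`, `dependency`,
#'   `stats`, `files`).
#' @export
run_pipeline <- function(config, overrides = list()) {
  cfg <- utils::modifyList(read_config(config), overrides)
  for (key in c("universe", "environment", "targets", "out")) {
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)
  }
  if (is.null(cfg$ec_dir) && is.null(cfg$ec_files)) {
    stop("config must name ec_dir or ec_files")
  }
  ec_files <- cfg$ec_files
  if (is.null(ec_files)) {
    ec_files <- list.files(cfg$ec_dir, pattern = "\\.(txt|ec|tsv)$",
                           full.names = TRUE)
    if (length(ec_files) == 0L) stop("no EC lists found in ", cfg$ec_dir)
  }
  inputs <- c(cfg$universe, unlist(ec_files), cfg$environment, cfg$targets,
              cfg$env2, cfg$occurrence)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  strict <- isTRUE(cfg$strict_ec)
  kmax <- if (is.null(cfg$kmax)) 2L else as.integer(cfg$kmax)

  uni <- load_universe(cfg$universe)
  annotations <- lapply(ec_files, load_ec_list)
  networks <- lapply(annotations, network_from_ecs, universe = uni,
                     strict_ec = strict, quiet = TRUE)
  names(networks) <- vapply(networks, `[[`, "", "organism_id")
  genus_of <- if (!is.null(cfg$genus)) unlist(cfg$genus) else
    stats::setNames(vapply(annotations, `[[`, "", "genus_label"),
                    names(networks))
  env_host <- load_environment(cfg$environment, universe = uni, quiet = TRUE)
  targets <- load_targets(cfg$targets, universe = uni)

  env2 <- NULL
  if (!is.null(cfg$env2)) {
    env2 <- load_environment(cfg$env2, universe = uni, quiet = TRUE)
  } else if (!is.null(cfg$derive_env2_from)) {
    org <- cfg$derive_env2_from
    if (!org %in% names(networks)) {
      stop("derive_env2_from names unknown organism: ", org)
    }
    env2 <- derive_host_obligate_env(env_host, networks[[org]])
  }

  envs <- c(list(env_host), if (!is.null(env2)) list(env2))
  names(envs) <- c("host", if (!is.null(env2)) "host_obligate")

  expansions <- lapply(envs, function(e) {
    lapply(networks, function(n) expand_scope(e, n))
  })
  growth <- lapply(expansions, function(byorg) {
    lapply(byorg, assess_growth, targets = targets)
  })

  ids <- names(networks)
  comp_results <- list()
  comp_counts <- lapply(envs, function(e) {
    matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  })
  if (length(ids) >= 2L) {
    pairs <- utils::combn(ids, 2L, simplify = FALSE)
    for (env_name in names(envs)) {
      for (p in pairs) {
        r <- complementary_metabolites(networks[[p[1]]], networks[[p[2]]],
                                       envs[[env_name]])
        comp_results[[length(comp_results) + 1L]] <- r
        comp_counts[[env_name]][p[1], p[2]] <-
          comp_counts[[env_name]][p[2], p[1]] <- length(r$complementary)
      }
    }
    if (kmax >= 3L) {
      for (m in 3:min(kmax, length(ids))) {
        for (idx in utils::combn(length(ids), m, simplify = FALSE)) {
          for (env_name in names(envs)) {
            comp_results[[length(comp_results) + 1L]] <-
              kwise_complementary(networks[idx], envs[[env_name]])
          }
        }
      }
    }
  }
  profile <- NULL; pca <- NULL
  nonempty <- Filter(function(r) length(r$complementary) > 0, comp_results)
  if (length(comp_results) >= 2L) {
    profile <- build_profile(comp_results)
    if (length(nonempty) >= 2L && ncol(profile$incidence) > 0L) {
      pca <- pca_cluster_profiles(profile)
    }
  }

  competition <- if (length(ids) >= 2L) {
    competition_matrix(networks, targets)
  } else NULL
  dependency <- dependency_table(networks, env_host, targets)

  stats_out <- list()
  if (!is.null(competition) && length(unique(genus_of[ids])) >= 2L) {
    stats_out$mean_cross_genus <-
      mean_cross_genus_score(competition, genus_of)
    if (!is.null(cfg$occurrence)) {
      occ <- load_occurrence_table(cfg$occurrence)
      stats_out$occurrence_test <- tryCatch(
        occurrence_association_test(competition, occ, genus_of),
        error = function(e) {
          message("occurrence association test skipped: ",
                  conditionMessage(e))
          NULL
        })
    } else {
      message("no occurrence table supplied: association test skipped")
    }
  }

  files <- emit_reports(list(competition = competition,
                             comp_counts = comp_counts,
                             growth = growth, targets = targets,
                             dependency = dependency, pca = pca),
                        cfg$out)
  meta <- list(package = "symbionet",
               version = as.character(utils::packageVersion("symbionet")),
               seed = cfg$seed,
               inputs = as.list(stats::setNames(
                 unname(tools::md5sum(inputs)), inputs)),
               n_organisms = length(ids),
               environments = names(envs),
               n_targets = length(targets$targets))
  meta_path <- file.path(cfg$out, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(universe = uni, networks = networks, environments = envs,
                 expansions = expansions, growth = growth,
                 complementation = comp_results, profile = profile,
                 pca = pca, competition = competition,
                 dependency = dependency, stats = stats_out,
                 files = c(files, meta_path)))
}
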