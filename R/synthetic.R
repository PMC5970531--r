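# Generators for synthetic reaction universes with planted structure:
# linear biosynthetic chains, pathways split across genomes, shared
# limiting seeds with closed-form competition scores, and random universes
# for oracle testing.  All generators are pure functions of their
# parameters and RNG seed.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic small EC namespace per prefix, so fragments don't collide
ec_base_for <- function(id_prefix) {
  h <- sum(utf8ToInt(id_prefix) * seq_along(utf8ToInt(id_prefix)))
  sprintf("%d.%d.%d", 7 + h %% 3, 1 + h %% 89, 1 + (h %/% 89) %% 89)
}

#' Generate a linear biosynthetic pathway fragment
#'
#' Compounds `c0..cL` connected by irreversible reactions `ci -> ci+1`,
#' each carrying a distinct EC, emulating chains such as lysine or
#' branched-chain amino-acid biosynthesis.
#'
#' @param length Number of reactions (>= 1).
#' @param id_prefix Prefix for compound/reaction/EC ids, so that several
#'   fragments can be combined without collisions.
#' @return A [reaction_universe()] fragment; expansion from `<prefix>_c0`
#'   reaches all `length + 1` compounds.
#' @export
make_linear_pathway <- function(length, id_prefix = "lp") {
  if (length < 1L) stop("pathway length must be >= 1")
  cmp <- paste0(id_prefix, "_c", 0:length)
  base <- ec_base_for(id_prefix)
  rxns <- lapply(seq_len(length), function(i) {
    new_reaction(paste0(id_prefix, "_r", i), sprintf("%s.%d", base, i),
                 cmp[i], cmp[i + 1])
  })
  reaction_universe(cmp, rxns)
}

#' Plant a pathway split across genomes, with known complementation
#'
#' Assigns consecutive segments of a linear pathway to different genomes:
#' genome `g` receives the ECs of reactions `(cut[g-1], cut[g]]`.  With
#' the chain head `c0` as the only environment source, the first genome
#' alone reaches the end of its segment while the joint community reaches
#' the chain end, so the complementary set is known by construction.
#'
#' @param universe A linear-pathway [reaction_universe()] from
#'   [make_linear_pathway()].
#' @param cut_points Strictly increasing reaction indices in
#'   `1..length-1`, one fewer than genomes; segment `g` is
#'   `(cut[g-1], cut[g]]`.  Overlapping or non-partitioning cuts are an
#'   error (they would destroy the planted signal).
#' @param genomes Character vector of genome ids (>= 1).
#' @param id_prefix The pathway's id prefix (default `"lp"`).
#' @return List with `annotations` (list of [genome_annotation()]),
#'   `env` (an [environment_set()] holding the chain head),
#'   `expected_all` (complementary set of the full combination versus all
#'   single members: every compound beyond the first cut, empty for a
#'   single genome) and `expected_kwise` (complementary set versus all
#'   proper sub-combinations: compounds beyond the last cut).
#' @export
plant_split_pathway <- function(universe, cut_points, genomes,
                                id_prefix = "lp") {
  L <- length(universe$reactions)
  k <- length(genomes)
  if (k < 1L) stop("need at least one genome")
  if (length(cut_points) != k - 1L) {
    stop("need exactly ", k - 1L, " cut point(s) for ", k, " genomes")
  }
  if (k > 1L && (any(diff(c(0L, cut_points, L)) < 1L) ||
                 is.unsorted(cut_points, strictly = TRUE))) {
    stop("cut points must be strictly increasing and partition 1..", L,
         " into non-empty segments (overlaps would destroy the planted ",
         "signal)")
  }
  bounds <- c(0L, cut_points, L)
  rxn_ids <- paste0(id_prefix, "_r", seq_len(L))
  annotations <- lapply(seq_len(k), function(g) {
    seg <- rxn_ids[(bounds[g] + 1L):bounds[g + 1L]]
    ecs <- unlist(lapply(universe$reactions[seg], `[[`, "ec"))
    genome_annotation(genomes[g], ecs)
  })
  cmp <- paste0(id_prefix, "_c", 0:L)
  expected_all <- if (k == 1L) character() else cmp[(cut_points[1] + 2L):(L + 1L)]
  expected_kwise <- if (k == 1L) character() else
    cmp[(cut_points[k - 1L] + 2L):(L + 1L)]
  list(annotations = annotations,
       env = environment_set("chain_head", cmp[1]),
       expected_all = sort(expected_all),
       expected_kwise = sort(expected_kwise))
}

#' Plant shared limiting seeds with closed-form competition scores
#'
#' Builds a community in which each genome produces `targets_per_genome`
#' target metabolites, each through a single reaction from one seed.  The
#' first `min(shared, targets_per_genome)` targets of every genome draw on
#' community-shared seeds `s1..s_shared`; the remainder draw on
#' genome-private seeds.  Because every genome's topological seed set is
#' exactly its consumed seeds, the expected effective metabolic overlap of
#' any cross pair is `min(shared, targets_per_genome) / targets_per_genome`
#' in closed form.
#'
#' @param genomes Number of genomes (>= 2).
#' @param shared Number of community-shared seed compounds.
#' @param private_per_genome Number of private seeds per genome; must be at
#'   least `targets_per_genome - shared`.
#' @param targets_per_genome Number of targets per genome (>= 1).
#' @param seed RNG seed; fixes the (shuffled) EC assignment so the fixture
#'   is byte-reproducible.
#' @return List with `universe`, `annotations`, `targets` (a
#'   [target_set()] over all genomes' targets), `expected_score` (the
#'   closed-form off-diagonal score) and `expected_matrix`.
#' @export
plant_shared_seeds <- function(genomes, shared, private_per_genome,
                               targets_per_genome, seed = 1L) {
  if (genomes < 2L) stop("need at least 2 genomes")
  if (targets_per_genome < 1L) stop("need at least 1 target per genome")
  n_shared_used <- min(shared, targets_per_genome)
  if (private_per_genome < targets_per_genome - n_shared_used) {
    stop("not enough private seeds to feed the non-shared targets")
  }
  gid <- paste0("g", seq_len(genomes))
  shared_seeds <- if (shared > 0L) paste0("s", seq_len(shared)) else character()
  compounds <- shared_seeds
  reactions <- list()
  annotations <- list()
  all_targets <- character()
  ec_counter <- 0L
  with_local_seed(seed, {
    for (g in seq_len(genomes)) {
      privates <- if (private_per_genome > 0L) {
        paste0(gid[g], "_p", seq_len(private_per_genome))
      } else character()
      tgts <- paste0(gid[g], "_t", seq_len(targets_per_genome))
      compounds <- c(compounds, privates, tgts)
      all_targets <- c(all_targets, tgts)
      ecs <- character()
      for (j in seq_len(targets_per_genome)) {
        src <- if (j <= n_shared_used) shared_seeds[j] else
          privates[j - n_shared_used]
        ec_counter <- ec_counter + 1L
        ec <- sprintf("6.%d.%d.%d", 1L + ec_counter %% 9, 1L + g,
                      sample.int(10000L, 1L))
        reactions[[length(reactions) + 1L]] <-
          new_reaction(paste0(gid[g], "_r", j), ec, src, tgts[j])
        ecs <- c(ecs, ec)
      }
      annotations[[g]] <- genome_annotation(gid[g], ecs)
    }
  })
  expected <- n_shared_used / targets_per_genome
  m <- matrix(expected, genomes, genomes, dimnames = list(gid, gid))
  diag(m) <- NA_real_
  list(universe = reaction_universe(compounds, reactions),
       annotations = annotations, targets = target_set(all_targets),
       expected_score = expected, expected_matrix = m)
}

#' Sample a random reaction universe
#'
#' Substrate and product sets of sizes 1-3 are drawn uniformly from the
#' compound pool; a fraction of reactions is reversible (split into two
#' directions at construction, as [load_universe()] would).  Used as the
#' substrate for brute-force oracle testing of the expansion fixed point.
#'
#' @param n_compounds Number of compounds (>= 2).
#' @param n_reactions Number of reaction records (>= 0).
#' @param reversible_fraction Probability that a record is reversible.
#' @param seed RNG seed; the same seed yields a byte-identical universe.
#' @return A [reaction_universe()].
#' @export
make_random_universe <- function(n_compounds, n_reactions,
                                 reversible_fraction = 0.3, seed = 1L) {
  if (n_compounds < 2L) stop("need at least 2 compounds")
  if (n_reactions < 0L) stop("n_reactions must be >= 0")
  cmp <- sprintf("C%03d", seq_len(n_compounds))
  with_local_seed(seed, {
    rxns <- list()
    max_side <- min(3L, n_compounds)
    for (i in seq_len(n_reactions)) {
      subs <- sample(cmp, sample.int(max_side, 1L))
      prods <- sample(cmp, sample.int(max_side, 1L))
      ec <- sprintf("%d.%d.%d.%d", sample.int(7L, 1L), sample.int(30L, 1L),
                    sample.int(30L, 1L), i)
      if (stats::runif(1) < reversible_fraction) {
        rxns[[length(rxns) + 1L]] <-
          new_reaction(sprintf("R%03d__f", i), ec, subs, prods, TRUE,
                       sprintf("R%03d", i))
        rxns[[length(rxns) + 1L]] <-
          new_reaction(sprintf("R%03d__r", i), ec, prods, subs, TRUE,
                       sprintf("R%03d", i))
      } else {
        rxns[[length(rxns) + 1L]] <- new_reaction(sprintf("R%03d", i), ec,
                                                  subs, prods)
      }
    }
    reaction_universe(cmp, rxns)
  })
}

#' Write a small self-contained demo community to disk
#'
#' Generates a three-genus toy community — an obligate-symbiont-like
#' genome plus two facultative-like genomes — over a universe containing
#' a currency tier (ATP/NAD-like), amino-acid chains split across
#' genomes, and shared limiting seeds, then writes universe, EC lists,
#' environment, target panel and occurrence table in the package's flat
#' formats.  Used by the pipeline smoke tests and the worked example.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed (reserved; the demo is fully deterministic).
#' @return Named list of the file paths written.
#' @export
write_demo_community <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # pathways: chain A split between fac1/fac2; chain B owned by the
  # obligate genome; a currency-consuming reaction in each facultative
  pwA <- make_linear_pathway(4, "aa")     # aa_c0 .. aa_c4
  pwB <- make_linear_pathway(2, "ob")     # ob_c0 .. ob_c2
  extra_cmp <- c("atp", "nad", "fac1_t", "fac2_t")
  extra <- reaction_universe(
    c("aa_c0", "ob_c2", extra_cmp),
    list(new_reaction("fx1", "2.7.1.1", c("atp", "aa_c0"), "fac1_t"),
         new_reaction("fx2", "1.1.1.1", c("nad", "atp", "ob_c2"), "fac2_t")))
  uni <- combine_universes(pwA, pwB, extra)
  split <- plant_split_pathway(pwA, 2L, c("fac1", "fac2"), "aa")
  ann <- list(
    genome_annotation("obligate_g1",
                      unique(unlist(lapply(pwB$reactions, `[[`, "ec")))),
    genome_annotation("fac1_g1", c(split$annotations[[1]]$ec_set, "2.7.1.1")),
    genome_annotation("fac2_g1", c(split$annotations[[2]]$ec_set, "1.1.1.1")))
  env <- environment_set("host_only", c("aa_c0", "ob_c0", "atp", "nad"))
  tgt <- target_set(c("aa_c4", "ob_c2", "fac1_t", "fac2_t"))
  occ <- occurrence_table(c("fac1_g1", "fac1_g1", "fac2_g1"),
                          c("fac2_g1", "obligate_g1", "obligate_g1"),
                          c(TRUE, TRUE, FALSE))
  paths <- list(universe = file.path(dir, "universe.tsv"),
                ec_dir = file.path(dir, "ec_lists"),
                environment = file.path(dir, "host_only.txt"),
                targets = file.path(dir, "targets.txt"),
                occurrence = file.path(dir, "occurrence.tsv"))
  dir.create(paths$ec_dir, showWarnings = FALSE)
  write_universe(uni, paths$universe)
  for (a in ann) {
    write_ec_list(a, file.path(paths$ec_dir, paste0(a$organism_id, ".txt")))
  }
  write_compound_set(env, paths$environment)
  write_compound_set(tgt, paths$targets)
  utils::write.table(occ, paths$occurrence, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
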