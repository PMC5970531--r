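# Shared toy fixtures built in code.

# tiny universe from an inline spec: list of c(id, "ec", "s1;s2", "p1", dir)
toy_universe <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(vapply(rows, paste, "", collapse = "\t"), f)
  on.exit(unlink(f))
  load_universe(f)
}

toy_network <- function(universe, ecs, organism_id = "toy") {
  network_from_ecs(universe, genome_annotation(organism_id, ecs),
                   quiet = TRUE)
}

# Lysine complementation toy: a Wolbachia-like genome carries the
# aspartate -> M-DAP chain but lacks the terminal diaminopimelate
# decarboxylase (EC 4.1.1.20), which the Hamiltonella-like genome
# carries; an obligate-symbiont-like genome owns an independent
# aspartate -> M-DAP route, so enriching the environment with its
# products lets the Hamiltonella-like genome make lysine alone.
lysine_toy <- function() {
  uni <- toy_universe(list(
    c("w1", "2.7.2.4",  "asp",  "asp_p",  ">"),
    c("w2", "1.2.1.11", "asp_p", "asp_sa", ">"),
    c("w3", "5.1.1.7",  "asp_sa", "mdap",  ">"),
    c("h1", "4.1.1.20", "mdap", "lysine", ">"),
    c("p1", "2.6.1.17", "asp",  "ob_i1",  ">"),
    c("p2", "3.5.1.18", "ob_i1", "mdap",  ">")))
  env <- environment_set("host_only", "asp")
  wolb <- toy_network(uni, c("2.7.2.4", "1.2.1.11", "5.1.1.7"), "Wolbachia_t")
  ham <- toy_network(uni, "4.1.1.20", "Hamiltonella_t")
  oblig <- toy_network(uni, c("2.6.1.17", "3.5.1.18"), "Obligate_t")
  list(universe = uni, env = env, wolb = wolb, ham = ham, oblig = oblig,
       env_hp = derive_host_obligate_env(env, oblig))
}

# Tryptophan dependency toy: tryptophan synthesis draws uniquely on
# D-ribose 5-phosphate (PRPP branch) and erythrose 4-phosphate +
# phosphoenolpyruvate (chorismate branch).
trp_toy <- function() {
  uni <- toy_universe(list(
    c("t1", "2.7.6.1",  "r5p",          "prpp",       ">"),
    c("t2", "2.5.1.54", "e4p;pep",      "dahp",       ">"),
    c("t3", "4.2.3.5",  "dahp",         "chorismate", ">"),
    c("t4", "2.4.2.18", "chorismate;prpp", "trp",     ">")))
  env <- environment_set("bacteriocyte", c("r5p", "e4p", "pep", "glc"))
  net <- toy_network(uni, c("2.7.6.1", "2.5.1.54", "4.2.3.5", "2.4.2.18"),
                     "Obligate_t")
  list(universe = uni, env = env, net = net, targets = target_set("trp"))
}

# Thiamine toy: only the kinase-bearing genome phosphorylates thiamine to
# thiamine diphosphate.
thiamine_toy <- function() {
  uni <- toy_universe(list(
    c("k1", "2.7.6.2", "thiamine;atp", "thdp", ">"),
    c("o1", "3.6.1.3", "atp",          "amp",  ">")))
  env <- environment_set("bacteriocyte", c("thiamine", "atp"))
  wolb <- toy_network(uni, c("2.7.6.2", "3.6.1.3"), "Wolbachia_t")
  rick <- toy_network(uni, "3.6.1.3", "Rickettsia_t")
  list(universe = uni, env = env, wolb = wolb, rick = rick,
       targets = target_set(c("thdp", "amp")))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "symbionet", mustWork = TRUE)
}

# numeric content of a competition matrix, attributes dropped
bare_matrix <- function(m) {
  matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
}
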