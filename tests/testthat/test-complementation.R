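test_that("pairwise complementary set is the joint excess over single scopes", {
  u <- toy_universe(list(
    c("R1", "1.1.1.1", "S", "X", ">"),
    c("R2", "2.2.2.2", "X", "T", ">")))
  a <- toy_network(u, "1.1.1.1", "a")
  b <- toy_network(u, "2.2.2.2", "b")
  env <- environment_set("e", "S")
  r <- complementary_metabolites(a, b, env)
  expect_equal(r$complementary, "T")
  expect_equal(r$environment_name, "e")
  # symmetric in the pair
  expect_equal(complementary_metabolites(b, a, env)$complementary, "T")
  # identical reaction content -> nothing complementary
  a2 <- toy_network(u, "1.1.1.1", "a2")
  expect_length(complementary_metabolites(a, a2, env)$complementary, 0L)
  expect_error(complementary_metabolites(a, a, env), "distinct")
})

test_that("complementary metabolites are never reachable by a single member", {
  set.seed(31)
  for (i in 1:10) {
    u <- make_random_universe(20, 30, seed = 300 + i)
    ecs <- universe_ecs(u)
    a <- network_from_ecs(u, genome_annotation("a", sample(ecs, 8)),
                          quiet = TRUE)
    b <- network_from_ecs(u, genome_annotation("b", sample(ecs, 8)),
                          quiet = TRUE)
    env <- environment_set("e", sample(u$compounds$id, 3))
    r <- complementary_metabolites(a, b, env)
    sa <- expand_scope(env, a)$scope
    sb <- expand_scope(env, b)$scope
    sm <- expand_scope(env, merge_networks(a, b))$scope
    # superadditivity and exact excess
    expect_true(all(union(sa, sb) %in% sm))
    expect_setequal(r$complementary, setdiff(sm, union(sa, sb)))
  }
})

test_that("k-wise detection matches hand enumeration on split chains", {
  u <- make_linear_pathway(3, "ch")
  split <- plant_split_pathway(u, c(1, 2), c("g1", "g2", "g3"), "ch")
  nets <- lapply(split$annotations, network_from_ecs, universe = u,
                 quiet = TRUE)
  env <- split$env
  # triple-only product: each pair misses a segment
  r3 <- kwise_complementary(nets, env)
  expect_equal(r3$complementary, "ch_c3")
  expect_equal(r3$complementary, split$expected_kwise)
  # the only productive pair is the one spanning consecutive segments
  expect_equal(complementary_metabolites(nets[[1]], nets[[2]], env)$complementary,
               "ch_c2")
  expect_length(complementary_metabolites(nets[[1]], nets[[3]], env)$complementary, 0L)
  expect_length(complementary_metabolites(nets[[2]], nets[[3]], env)$complementary, 0L)
  # k = 2 reduces to the pairwise definition
  expect_equal(kwise_complementary(nets[1:2], env)$complementary,
               complementary_metabolites(nets[[1]], nets[[2]], env)$complementary)
  expect_error(kwise_complementary(nets[1], env), "at least 2")
})

test_that("a triple adds nothing when a pair already completes the pathway", {
  u <- make_linear_pathway(2, "pp")
  split <- plant_split_pathway(u, 1, c("g1", "g2"), "pp")
  nets <- lapply(split$annotations, network_from_ecs, universe = u,
                 quiet = TRUE)
  bystander <- network_from_ecs(u, genome_annotation("g3", character()),
                                quiet = TRUE)
  r <- kwise_complementary(c(nets, list(bystander)), split$env)
  expect_length(r$complementary, 0L)
})

test_that("masking classification separates host-only from shared products", {
  toy <- lysine_toy()
  labels <- masking_classify(toy$wolb, toy$ham, toy$env, toy$env_hp)
  expect_equal(unname(labels["lysine"]), "host_only")
  # without the obligate enrichment the pair complementarity includes lysine
  expect_true("lysine" %in%
                complementary_metabolites(toy$wolb, toy$ham,
                                          toy$env)$complementary)
  # vacuous case: identical members -> empty labelling
  a <- toy_network(toy$universe, "4.1.1.20", "x")
  b <- toy_network(toy$universe, "4.1.1.20", "y")
  expect_length(masking_classify(a, b, toy$env, toy$env_hp), 0L)
})

test_that("environment enrichment can remove but also create complementarity", {
  # complementary sets need not be monotone in the environment: a compound
  # complementary in the host environment vanishes once one member can make
  # it alone from the enriched pool
  toy <- lysine_toy()
  ch <- complementary_metabolites(toy$wolb, toy$ham, toy$env)$complementary
  chp <- complementary_metabolites(toy$wolb, toy$ham, toy$env_hp)$complementary
  expect_true("lysine" %in% ch)
  expect_false("lysine" %in% chp)
  # while the underlying scopes themselves only grow
  expect_true(all(expand_scope(toy$env, toy$ham)$scope %in%
                    expand_scope(toy$env_hp, toy$ham)$scope))
})

test_that("profiles assemble deterministic binary incidence", {
  mk <- function(ids, env, comp) {
    structure(list(member_ids = ids, environment_name = env,
                   complementary = comp),
              class = "complementation_result")
  }
  single <- build_profile(list(mk(c("a", "b"), "host", c("m3", "m1", "m2"))))
  expect_equal(dim(single$incidence), c(1L, 3L))
  expect_true(all(single$incidence == 1L))
  expect_equal(colnames(single$incidence), c("m1", "m2", "m3"))
  two <- build_profile(list(mk(c("a", "b"), "host", c("m1", "m2")),
                            mk(c("a", "c"), "host", c("z1", "z2", "z3"))))
  expect_equal(dim(two$incidence), c(2L, 5L))
  expect_equal(unname(rowSums(two$incidence)), c(2, 3))
  expect_equal(sum(two$incidence[1, c("z1", "z2", "z3")]), 0)
})

test_that("PCA separates orthogonal profile groups and fixes signs", {
  mk <- function(id, comp) {
    structure(list(member_ids = c(id, "x"), environment_name = "host",
                   complementary = comp),
              class = "complementation_result")
  }
  prof <- build_profile(list(mk("a1", c("m1", "m2")), mk("a2", c("m1", "m2")),
                             mk("b1", c("n1", "n2")), mk("b2", c("n1", "n2"))))
  out <- pca_cluster_profiles(prof, n_components = 2, k = 2)
  pc1 <- out$coordinates[, 1]
  expect_true(all(sign(pc1[1:2]) == sign(pc1[1])))
  expect_true(all(sign(pc1[3:4]) == -sign(pc1[1])))
  expect_equal(length(unique(out$clusters[1:2])), 1L)
  expect_equal(length(unique(out$clusters[3:4])), 1L)
  expect_false(out$clusters[1] == out$clusters[3])
  # deterministic sign convention: repeated runs identical
  out2 <- pca_cluster_profiles(prof, n_components = 2, k = 2)
  expect_identical(out$coordinates, out2$coordinates)
  # identical rows: zero variance warning, all-zero coordinates
  flat <- build_profile(list(mk("a1", "m1"), mk("a2", "m1")))
  expect_warning(res <- pca_cluster_profiles(flat), "zero variance")
  expect_true(all(res$coordinates == 0))
})
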