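as_cmpmat <- function(m) {
  structure(m, class = c("competition_matrix", "matrix"),
            environment_basis = "optimal")
}

test_that("cross-genus mean excludes self and same-genus cells", {
  m <- as_cmpmat(matrix(c(NA, 0.1, 0.3, NA), 2, 2,
                        dimnames = list(c("A_1", "B_1"), c("A_1", "B_1"))))
  g <- c(A_1 = "A", B_1 = "B")
  expect_equal(mean_cross_genus_score(m, g), 0.2)
  # constant matrix -> that constant
  mc <- as_cmpmat(matrix(0.4, 3, 3, dimnames = list(letters[1:3],
                                                    letters[1:3])))
  diag(mc) <- NA
  expect_equal(mean_cross_genus_score(mc, c(a = "x", b = "y", c = "z")), 0.4)
  # invariant under row/column reordering
  ids <- c("A_1", "A_2", "B_1", "C_1")
  set.seed(5)
  mm <- matrix(runif(16), 4, 4, dimnames = list(ids, ids))
  diag(mm) <- NA
  g4 <- setNames(sub("_.*", "", ids), ids)
  perm <- c(3, 1, 4, 2)
  expect_equal(mean_cross_genus_score(as_cmpmat(mm), g4),
               mean_cross_genus_score(as_cmpmat(mm[perm, perm]), g4))
  # same-genus duplicate-genome cells never enter
  mm2 <- mm
  mm2["A_1", "A_2"] <- 99
  mm2["A_2", "A_1"] <- 99
  expect_equal(mean_cross_genus_score(as_cmpmat(mm2), g4),
               mean_cross_genus_score(as_cmpmat(mm), g4))
  expect_error(mean_cross_genus_score(as_cmpmat(mm), c(a = "x")), "genus_of")
})

test_that("occurrence association test is a Welch t-test on grouped scores", {
  ids <- paste0(letters[1:6], "_1")
  g <- setNames(letters[1:6], ids)
  m <- matrix(NA_real_, 6, 6, dimnames = list(ids, ids))
  # two clearly separated groups
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    m[i, j] <- if ((i + j) %% 2 == 0) 0 else 1
  }
  pairs <- t(combn(ids, 2))
  occ <- occurrence_table(pairs[, 1], pairs[, 2],
                          (match(pairs[, 1], ids) +
                             match(pairs[, 2], ids)) %% 2 == 0)
  res <- occurrence_association_test(as_cmpmat(m), occ, g)
  # groups {0,...} vs {1,...}: huge |t|, tiny p
  expect_true(abs(res$statistic) > 10)
  expect_lt(res$p.value, 1e-6)
  # identical groups -> t = 0
  m1 <- m; m1[!is.na(m1)] <- 0.3
  res0 <- occurrence_association_test(as_cmpmat(m1), occ, g)
  expect_equal(unname(res0$statistic), 0)
  expect_s3_class(res, "htest")
})

test_that("Welch test matches the textbook formula and a permutation check", {
  ids <- paste0(c("a", "b", "c", "d"), "_1")
  g <- setNames(c("a", "b", "c", "d"), ids)
  set.seed(8)
  m <- matrix(NA_real_, 4, 4, dimnames = list(ids, ids))
  m[row(m) != col(m)] <- round(runif(12), 2)
  pairs <- t(combn(ids, 2))
  flags <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  occ <- occurrence_table(pairs[, 1], pairs[, 2], flags)
  res <- occurrence_association_test(as_cmpmat(m), occ, g)
  # closed-form Welch statistic on the same grouping
  sc <- c(); fl <- c()
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    k <- which((pairs[, 1] == ids[i] & pairs[, 2] == ids[j]) |
                 (pairs[, 1] == ids[j] & pairs[, 2] == ids[i]))
    sc <- c(sc, m[i, j]); fl <- c(fl, flags[k])
  }
  x <- sc[fl]; y <- sc[!fl]
  tw <- (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  dfw <- (var(x) / length(x) + var(y) / length(y))^2 /
    ((var(x) / length(x))^2 / (length(x) - 1) +
       (var(y) / length(y))^2 / (length(y) - 1))
  expect_equal(unname(res$statistic), tw)
  expect_equal(unname(res$parameter), dfw)
  # Welch reduces to the pooled t-test when variances and sizes coincide
  x2 <- c(0.1, 0.2, 0.3); y2 <- c(0.4, 0.5, 0.6)
  expect_equal(unname(t.test(x2, y2, var.equal = FALSE)$statistic),
               unname(t.test(x2, y2, var.equal = TRUE)$statistic))
  # permutation p-value agrees with the t-test within Monte-Carlo error
  obs <- abs(tw)
  nperm <- 4000
  set.seed(99)
  perm <- replicate(nperm, {
    f <- sample(fl)
    px <- sc[f]; py <- sc[!f]
    abs((mean(px) - mean(py)) /
          sqrt(var(px) / length(px) + var(py) / length(py)))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_perm - res$p.value), 0.12)
})

test_that("the packaged whitefly pairwise table reproduces its summaries", {
  pt <- load_pairwise_table(fixture_path("whitefly_pairwise_predictions.tsv"))
  org <- load_organism_table(fixture_path("whitefly_organisms.tsv"))
  g <- setNames(org$genus, org$organism_id)
  # 38 cross-genus ordered cells, mean 0.18 at 2 decimals
  cross <- outer(g[rownames(pt$scores)], g[colnames(pt$scores)], `!=`)
  diag(cross) <- FALSE
  expect_equal(sum(cross & !is.na(pt$scores)), 38L)
  expect_equal(round(mean_cross_genus_score(pt$scores, g), 2), 0.18)
  # scores are asymmetric but complementary counts are pair-symmetric
  expect_false(isTRUE(all.equal(pt$scores, t(pt$scores))))
  ch <- pt$comp_host
  expect_equal(ch[!is.na(ch)], t(ch)[!is.na(ch)])
})

test_that("report emission is deterministic and complete", {
  ids <- c("o1", "o2")
  m <- as_cmpmat(matrix(c(NA, 0.25, 0.5, NA), 2, 2,
                        dimnames = list(ids, ids)))
  counts <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(ids, ids))
  ga <- list(host = list(
    o1 = assess_growth(c("t1"), target_set(c("t1", "t2"))),
    o2 = assess_growth(character(), target_set(c("t1", "t2")))))
  dep <- structure(matrix(0:3, 2, 2, dimnames = list(ids, c("s1", "s2"))),
                   class = c("dependency_table", "matrix"))
  res <- list(competition = m, comp_counts = list(host = counts),
              growth = ga, targets = target_set(c("t1", "t2")),
              dependency = dep)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- emit_reports(res, d1)
  f2 <- emit_reports(res, d2)
  expect_length(f1, 3L)
  for (k in seq_along(f1)) {
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  }
  pw <- read.delim(f1[1])
  # zero-count cells present, not missing; display format "m1 (score)"
  expect_equal(nrow(pw), 2L)
  expect_true(all(c("o1", "o2") %in% pw$row_id))
  expect_match(pw$cell[pw$row_id == "o1"], "^2 \\(0\\.5\\)$")
  tp <- read.delim(f1[2], check.names = FALSE)
  expect_equal(tp[tp$organism == "o1", "t1"], 1L)
  expect_equal(tp[tp$organism == "o2", "t1"], 0L)
})
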