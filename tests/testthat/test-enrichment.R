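# Weighted-KS enrichment engine: worked cases, invariants, oracle
# equivalence, permutation behavior, ssGSEA.

test_that("weighted-KS ES reproduces hand-worked running sums", {
  p10 <- ranked_profile(setNames(10:1, sprintf("g%02d", 1:10)))
  expect_identical(weighted_ks_es(p10, "g01")$es, 1)

  p5 <- ranked_profile(c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1))
  expect_identical(weighted_ks_es(p5, "g5")$es, -1)

  # hits g1 (5/8) and g3 (3/8); running sum peaks at 2/3 on g3
  res <- weighted_ks_es(p5, gene_set("pair", c("g1", "g3")))
  expect_equal(res$es, 2 / 3, tolerance = 1e-15)
  expect_identical(res$leading_edge, c("g1", "g3"))
  expect_identical(res$n_overlap, 2L)

  # negative extremum: leading edge is at or after the extremum
  expect_identical(weighted_ks_es(p5, "g5")$leading_edge, "g5")
})

test_that("absent set members are dropped and empty overlap errors", {
  p5 <- ranked_profile(c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1))
  res <- weighted_ks_es(p5, gene_set("x", c("g1", "g3", "nope")))
  expect_identical(res$n_overlap, 2L)
  expect_equal(res$es, 2 / 3, tolerance = 1e-15)
  expect_error(weighted_ks_es(p5, gene_set("y", "absent")), "no members")
  expect_error(ranked_profile(c(g1 = 1, g2 = NA)), "finite")
})

test_that("ES respects its bounds, scale invariance, and antisymmetry", {
  withr_seed <- 421
  set.seed(withr_seed)
  for (rep in 1:200) {
    cs <- random_es_case()
    prof <- ranked_profile(cs$scores, cs$genes)
    es <- weighted_ks_es(prof, cs$members, weight = cs$weight)$es
    expect_lte(abs(es), 1)
    # scale invariance for c > 0
    es_scaled <- weighted_ks_es(
      ranked_profile(cs$scores * 3.7, cs$genes), cs$members,
      weight = cs$weight
    )$es
    expect_equal(es, es_scaled, tolerance = 1e-12)
  }
  # a set occupying exactly the top |S| ranks scores +1 at weight 1
  scores <- setNames(seq(50, 1), paste0("g", 1:50))
  expect_identical(weighted_ks_es(ranked_profile(scores), paste0("g", 1:7))$es, 1)

  # antisymmetry: reversing the order and negating scores negates ES
  set.seed(withr_seed + 1)
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    genes <- paste0("g", 1:n)
    scores <- rnorm(n) # continuous: extremum a.s. unique
    members <- sample(genes, 5)
    es_fwd <- weighted_ks_es(ranked_profile(scores, genes), members)$es
    es_rev <- weighted_ks_es(ranked_profile(-scores, genes), members)$es
    expect_equal(es_fwd, -es_rev, tolerance = 1e-12)
  }
})

test_that("ES agrees with the brute-force running-sum oracle", {
  set.seed(77)
  for (rep in 1:300) {
    cs <- random_es_case()
    es <- weighted_ks_es(ranked_profile(cs$scores, cs$genes), cs$members,
      weight = cs$weight
    )$es
    expect_equal(es, oracle_es(cs$scores, cs$genes, cs$members, cs$weight),
      tolerance = 1e-12
    )
  }
})

test_that("ES agrees with fgsea's statistic on tie-free profiles", {
  skip_if_not_installed("fgsea")
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(20:100, 1)
    genes <- paste0("g", 1:n)
    scores <- sort(rnorm(n), decreasing = TRUE)
    members <- sample(genes, sample(3:10, 1))
    mine <- weighted_ks_es(ranked_profile(scores, genes), members)$es
    theirs <- fgsea::calcGseaStat(
      setNames(scores, genes),
      selectedStats = sort(match(members, genes)),
      gseaParam = 1
    )
    expect_equal(mine, theirs, tolerance = 1e-10)
  }
})

test_that("prerank GSEA permutation machinery behaves", {
  set.seed(5)
  genes <- paste0("g", 1:1000)
  scores <- setNames(sort(rnorm(1000), decreasing = TRUE), genes)

  # no permutations: ES only
  r0 <- prerank_gsea(scores, list(a = genes[1:20]), n_perm = 0)
  expect_true(is.na(r0$nes) && is.na(r0$p_nominal) && is.na(r0$fdr))

  # planted set occupying the top 20 ranks: p at the smallest achievable
  # bound, since no random same-size set attains ES = 1
  rp <- prerank_gsea(scores, list(top = genes[1:20]),
    n_perm = 999,
    seed = 11
  )
  expect_identical(rp$es, 1)
  expect_lte(rp$p_nominal, 0.002)

  # identical seeds give identical nes/p/fdr
  sets <- list(a = sample(genes, 30), b = sample(genes, 15))
  r1 <- prerank_gsea(scores, sets, n_perm = 200, seed = 42)
  r2 <- prerank_gsea(scores, sets, n_perm = 200, seed = 42)
  expect_identical(r1, r2)

  # sets with no overlap are dropped with a warning
  expect_warning(
    prerank_gsea(scores, list(a = genes[1:10], bad = "absent"), n_perm = 0),
    "no overlap"
  )
})

test_that("nominal permutation p-values are calibrated under the null", {
  set.seed(1234)
  genes <- paste0("g", 1:1000)
  scores <- setNames(sort(rnorm(1000), decreasing = TRUE), genes)
  sets <- lapply(1:50, function(i) sample(genes, 25))
  names(sets) <- paste0("s", 1:50)
  res <- prerank_gsea(scores, sets, n_perm = 999, seed = 2024)
  ks <- suppressWarnings(ks.test(res$p_nominal, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ssGSEA matches the position-by-position oracle", {
  # hand-enumerated: 4 genes, set {g1}, exponent 0 -> steps 1, 2/3, 1/3, 0
  expr4 <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  expect_equal(ssgsea_score(expr4, "g1", exponent = 0), 2.0,
    tolerance = 1e-15
  )

  # monotonicity: members at the top outrank members at the bottom
  genes <- paste0("g", 1:40)
  top <- setNames(seq(40, 1), genes)
  s_top <- ssgsea_score(top, genes[1:5])
  s_bottom <- ssgsea_score(top, genes[36:40])
  expect_gt(s_top, s_bottom)

  # all-gene set: no miss term, positive score
  expect_gt(ssgsea_score(expr4, names(expr4)), 0)

  # random-instance agreement with the independent oracle
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    g <- paste0("g", 1:n)
    e <- setNames(round(rnorm(n), 2), g)
    members <- sample(g, sample.int(min(12L, n - 1L), 1))
    expo <- sample(c(0, 0.25, 1), 1)
    expect_equal(
      ssgsea_score(e, members, exponent = expo),
      oracle_ssgsea(e, members, expo),
      tolerance = 1e-12
    )
  }
  expect_error(ssgsea_score(expr4, "absent"), "no members")
})
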