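# Consensus indicators, compound clustering, and mechanism annotation.

test_that("expression indicators threshold strictly at +/- 1", {
  v <- matrix(c(1.5, -0.2, -3.0, 1.0, -1.0, 0), 6, 1,
    dimnames = list(paste0("g", 1:6), "e1")
  )
  ind <- make_indicators(v, "cpd1")
  expect_identical(as.integer(ind$values), c(1L, 0L, -1L, 0L, 0L, 0L))
  zero <- make_indicators(v * 0, "cpd1")
  expect_true(all(zero$values == 0L))
  # band membership is all that matters: a monotone transform preserving
  # the (-1, 1) band leaves indicators unchanged
  expect_identical(
    make_indicators(sign(v) * abs(v)^3, "cpd1")$values,
    ind$values
  )
})

test_that("consensus vectors are per-compound indicator sums", {
  v <- matrix(c(2, 0, -2, 1.5, -1.5, -3), 3, 2,
    dimnames = list(paste0("g", 1:3), c("e1", "e2"))
  )
  ind <- make_indicators(v, c("cpdA", "cpdA"))
  cons <- consensus_vectors(ind)
  expect_identical(unname(cons[, "cpdA"]), c(2, -1, -2))
  expect_identical(attr(cons, "n_experiments")[["cpdA"]], 2L)

  # single experiment: consensus equals the indicator vector
  one <- consensus_vectors(make_indicators(v[, 1, drop = FALSE], "cpdB"))
  expect_identical(unname(one[, 1]), c(1, 0, -1))

  # experiment order is irrelevant
  cons2 <- consensus_vectors(make_indicators(v[, 2:1], c("cpdA", "cpdA")))
  expect_identical(cons, cons2)
})

test_that("Ward clustering on 1 - Pearson follows the hand oracle", {
  genes <- paste0("g", 1:3)
  vec <- cbind(A = c(3, 0, -3), B = c(2, 0, -2), C = c(-3, 0, 3))
  rownames(vec) <- genes
  cl <- cluster_compounds(vec, k = 2)
  # d(A,B) = 0, d(A,C) = d(B,C) = 2: first merge is {A, B} at height 0
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  expect_identical(cl$labels[["A"]], cl$labels[["B"]])
  expect_false(cl$labels[["A"]] == cl$labels[["C"]])

  # identical vectors merge at height 0; input order does not matter
  cl2 <- cluster_compounds(vec[, c("C", "B", "A")], k = 2)
  expect_identical(cl$labels, cl2$labels)

  # constant vector: correlation defined as 0 with a warning
  vec3 <- cbind(vec, D = c(1, 1, 1))
  expect_warning(cluster_compounds(vec3, k = 2), "constant")

  expect_error(cluster_compounds(vec[, 1, drop = FALSE]), "at least 2")
})

test_that("planted mechanism clusters are separated at the k = 2 cut", {
  gen <- gen_perturbation_compendium(
    n_genes = 800, cell_lines = c("A", "B", "C"),
    n_compounds = 40, n_shrna = 0, frac_shifting = 1, gamma = 1.5,
    n_mechanisms = 2, module_size = 80, module_strength = 3,
    seed = 17
  )
  comp <- gen$compendium
  is_cpd <- comp$meta$perturbagen_type == "compound"
  ind <- make_indicators(
    comp$values[, is_cpd, drop = FALSE],
    comp$meta$perturbagen_id[is_cpd]
  )
  cl <- cluster_compounds(consensus_vectors(ind), k = 2)
  planted <- gen$truth$compound_plan$mechanism[
    match(names(cl$labels), gen$truth$compound_plan$perturbagen_id)
  ]
  # the two-cluster cut must match the planted mechanisms exactly
  tab <- table(planted, cl$labels)
  expect_identical(sort(as.integer(tab)), c(0L, 0L, 20L, 20L))
})

test_that("cluster signatures are ranked per-gene medians", {
  vec <- cbind(m1 = c(2, 0, -2), m2 = c(4, 0, -4))
  rownames(vec) <- c("g1", "g2", "g3")
  cs <- cluster_signature(vec, "c1")
  expect_identical(unname(cs$medians), c(3, 0, -3)) # even size: midpoints
  expect_identical(cs$profile$gene_ids, c("g1", "g2", "g3"))

  single <- cluster_signature(vec[, 1, drop = FALSE])
  expect_identical(unname(single$medians), c(2, 0, -2))

  # sign flip: negated profiles negate the consensus and reverse the rank
  neg <- cluster_signature(-vec, "c2")
  expect_identical(neg$medians, -cs$medians)
  expect_identical(neg$profile$gene_ids, rev(cs$profile$gene_ids))
})

test_that("cluster annotation ranks the planted module on top", {
  set.seed(23)
  genes <- paste0("g", 1:400)
  med <- rnorm(400, sd = 0.3)
  names(med) <- genes
  module <- genes[1:40]
  med[module] <- med[module] + 3
  sets <- list(
    planted = module,
    decoy1 = sample(genes[41:400], 40),
    decoy2 = sample(genes[41:400], 40)
  )
  ann <- annotate_cluster(ranked_profile(med), sets, n_perm = 200, seed = 3)
  expect_identical(ann$set_id[1], "planted")
  expect_gt(ann$nes[1], ann$nes[2])
  # a set disjoint from the strong-consensus genes scores much weaker
  expect_gt(abs(ann$es[ann$set_id == "planted"]),
    abs(ann$es[ann$set_id == "decoy1"]))

  ann2 <- annotate_cluster(ranked_profile(med), sets, n_perm = 200, seed = 3)
  expect_identical(ann, ann2)
})
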