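# Induced changes, R/S signature derivation, scoring, PCA, and ROC.

make_cohort <- function(pre, post, response, scale = "linear") {
  dimnames(pre) <- dimnames(post) <-
    list(paste0("g", seq_len(nrow(pre))), paste0("p", seq_len(ncol(pre))))
  paired_cohort(pre, post, response, scale = scale)
}

test_that("induced changes follow the log2 fold-change definition", {
  pre <- matrix(c(4, 0, 8, 2), 2, 2)
  co <- make_cohort(pre, pre, c("R", "NR"))
  expect_true(all(compute_induced_changes(co) == 0))

  co2 <- make_cohort(
    matrix(c(4, 1, 4, 1), 2, 2), matrix(c(16, 1, 16, 1), 2, 2),
    c("R", "NR")
  )
  expect_equal(unname(compute_induced_changes(co2, pseudocount = 0)[1, 1]), 2)

  co3 <- make_cohort(
    matrix(0, 1, 2) + rbind(c(0, 0)), matrix(3, 1, 2), c("R", "NR")
  )
  expect_equal(unname(compute_induced_changes(co3, pseudocount = 1)[1, 1]), 2)
  expect_error(compute_induced_changes(co3, pseudocount = 0), "pseudocount")

  # log2-declared input is exponentiated first
  co4 <- make_cohort(
    matrix(2, 1, 2), matrix(4, 1, 2), c("R", "NR"),
    scale = "log2"
  )
  expect_equal(
    unname(compute_induced_changes(co4, pseudocount = 0)[1, 1]),
    log2(16 / 4)
  )
})

test_that("vectorized rank-sum p-values match wilcox.test", {
  set.seed(8)
  x <- matrix(rnorm(50 * 25), 50, 25)
  x[1:10, ] <- round(x[1:10, ], 1) # inject ties
  x[11, ] <- 1 # constant row
  idx1 <- 1:12
  idx2 <- 13:25
  p <- synshift:::ranksum_rows(x, idx1, idx2)
  for (i in seq_len(nrow(x))) {
    ref <- suppressWarnings(
      wilcox.test(x[i, idx1], x[i, idx2], exact = FALSE, correct = TRUE)
    )$p.value
    if (i == 11) {
      expect_identical(p[i], 1)
    } else {
      expect_equal(p[i], ref, tolerance = 1e-12, label = paste("row", i))
    }
  }
  # exact path for small tie-free classes
  y <- matrix(rnorm(20 * 10), 20, 10)
  pe <- synshift:::ranksum_rows(y, 1:5, 6:10)
  for (i in seq_len(nrow(y))) {
    ref <- wilcox.test(y[i, 1:5], y[i, 6:10], exact = TRUE)$p.value
    expect_equal(pe[i], ref, tolerance = 1e-12)
  }
})

test_that("signature derivation assigns direction by median difference", {
  # complete separation 5 vs 5: exact two-sided p = 2/252
  set.seed(2)
  changes <- matrix(rnorm(20 * 10, sd = 0.1), 20, 10,
    dimnames = list(paste0("g", 1:20), paste0("p", 1:10))
  )
  changes[1, ] <- c(10, 11, 12, 13, 14, 1, 2, 3, 4, 5) # resp all higher
  changes[2, ] <- c(1, 2, 3, 4, 5, 10, 11, 12, 13, 14) # resp all lower
  response <- rep(c("R", "NR"), each = 5)
  sig <- derive_signatures(changes, response)
  tab <- sig$table
  expect_equal(tab$p_value[tab$gene == "g1"], 2 / 252, tolerance = 1e-12)
  expect_identical(tab$direction[tab$gene == "g1"], "S")
  expect_identical(tab$direction[tab$gene == "g2"], "R")

  # label symmetry: swapping classes swaps S and R exactly
  swapped <- derive_signatures(changes, ifelse(response == "R", "NR", "R"))
  expect_setequal(s_genes(sig), r_genes(swapped))
  expect_setequal(r_genes(sig), s_genes(swapped))

  # identical change distributions in both classes: empty signature
  flat <- matrix(rep(c(1:5, 1:5), each = 10), 10, 10,
    dimnames = list(paste0("g", 1:10), paste0("p", 1:10))
  )
  expect_identical(nrow(derive_signatures(flat, response)$table), 0L)

  expect_error(derive_signatures(changes, rep(c("R", "NR"), c(1, 9))),
    "at least 2"
  )
})

test_that("planted signatures are recovered with the planted direction", {
  sim <- gen_paired_cohort(
    n_genes = 2000, n_planted = 200, effect = 1.5,
    seed = 10
  )
  sig <- derive_signatures(
    compute_induced_changes(sim$cohort),
    sim$cohort$response
  )
  rec_s <- intersect(s_genes(sig), sim$truth$planted_s_genes)
  rec_r <- intersect(r_genes(sig), sim$truth$planted_r_genes)
  expect_gte((length(rec_s) + length(rec_r)) / 400, 0.8)
  # no planted gene recovered with the wrong direction
  expect_length(intersect(s_genes(sig), sim$truth$planted_r_genes), 0)
  expect_length(intersect(r_genes(sig), sim$truth$planted_s_genes), 0)
})

test_that("surrogate changes center every gene on its cohort baseline", {
  x <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  expect_equal(unname(surrogate_changes(x)[1, ]), c(-1, 0, 1))
  set.seed(3)
  m <- matrix(rnorm(200), 20, 10,
    dimnames = list(paste0("g", 1:20), paste0("s", 1:10))
  )
  expect_true(all(abs(rowSums(surrogate_changes(m))) < 1e-9))
  expect_error(surrogate_changes(m[, 1, drop = FALSE]), "2 samples")
})

test_that("signature scores are plain means and combined is antisymmetric", {
  ch <- matrix(c(1, 3, 2), 3, 1,
    dimnames = list(c("a", "b", "c"), "s1")
  )
  sig <- list(s = c("a", "b"), r = "c")
  expect_equal(unname(signature_score(ch, sig, "S")), 2)
  expect_equal(unname(signature_score(ch, sig, "R")), 2)
  expect_equal(unname(signature_score(ch, sig, "combined")), 0)
  expect_true(all(signature_score(ch * 0, sig, "combined") == 0))

  set.seed(4)
  m <- matrix(rnorm(100), 20, 5,
    dimnames = list(paste0("g", 1:20), paste0("s", 1:5))
  )
  fwd <- signature_score(m, list(s = paste0("g", 1:5), r = paste0("g", 6:9)))
  rev <- signature_score(m, list(s = paste0("g", 6:9), r = paste0("g", 1:5)))
  expect_equal(fwd, -rev, tolerance = 1e-12)
  expect_error(
    signature_score(m, list(s = "zz", r = paste0("g", 1:2))),
    "cannot score"
  )
})

test_that("PCA response score is the leading principal projection", {
  set.seed(6)
  # rank-1 matrix: scores proportional to the latent factor
  loading <- rnorm(30)
  factor <- rnorm(8)
  x <- outer(loading, factor)
  dimnames(x) <- list(paste0("g", 1:30), paste0("s", 1:8))
  sc <- pca_response_score(x)
  expect_equal(abs(cor(sc, factor)), 1, tolerance = 1e-9)

  # duplicated samples get identical scores
  xx <- cbind(x, x[, 1, drop = FALSE])
  colnames(xx) <- c(colnames(x), "dup")
  sc2 <- pca_response_score(xx)
  expect_equal(unname(sc2["s1"]), unname(sc2["dup"]), tolerance = 1e-12)

  # projection variance equals the leading eigenvalue of the sample
  # covariance of the gene-centered matrix
  y <- matrix(rnorm(40 * 12), 40, 12,
    dimnames = list(paste0("g", 1:40), paste0("s", 1:12))
  )
  sy <- pca_response_score(y)
  yc <- y - rowMeans(y)
  ev <- eigen(crossprod(t(yc)) / (ncol(y) - 1), symmetric = TRUE)$values[1]
  expect_equal(var(as.numeric(sy)), ev, tolerance = 1e-9)

  expect_error(pca_response_score(matrix(1, 3, 3)), "zero variance")
})

test_that("ROC AUC is the concordant-pair fraction with ties at half", {
  expect_equal(
    as.numeric(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE))),
    0.75
  )
  expect_equal(as.numeric(roc_auc(c(3, 2, 1), c(TRUE, TRUE, FALSE))), 1)
  expect_equal(as.numeric(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3))), 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(9)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    scores <- sample(round(rnorm(n), 1)) # ties likely
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    a <- as.numeric(roc_auc(scores, labels))
    expect_equal(a, oracle_auc(scores, labels), tolerance = 1e-12)
    # complement property (holds with midrank tie handling too)
    expect_equal(a + as.numeric(roc_auc(-scores, labels)), 1,
      tolerance = 1e-12
    )
  }
})

test_that("ROC AUC agrees with pROC on random tie-free data", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- rnorm(60)
  labels <- rep(c(TRUE, FALSE), 30)
  mine <- as.numeric(roc_auc(scores, labels))
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(mine, theirs, tolerance = 1e-12)
})
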