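# TAS filtering, shift ability, R-to-S calls, knockdown assessment,
# aggregation, and target concordance/prioritization.

tiny_compendium <- function(values, type = "compound", target = NA,
                            cell = "CL1", tas = 0.9) {
  n <- ncol(values)
  meta <- data.frame(
    experiment_id = colnames(values),
    perturbagen_id = paste0("p", seq_len(n)),
    perturbagen_type = rep_len(type, n),
    target_gene = rep_len(target, n),
    cell_line = rep_len(cell, n),
    dose = "10uM", time = "24h",
    tas = rep_len(tas, n),
    stringsAsFactors = FALSE
  )
  perturbation_compendium(values, meta)
}

test_that("TAS filtering keeps the inclusive boundary", {
  set.seed(1)
  v <- matrix(rnorm(50), 5, 10,
    dimnames = list(paste0("g", 1:5), paste0("e", 1:10))
  )
  comp <- tiny_compendium(v, tas = seq(0.1, 1.0, by = 0.1))
  kept <- suppressMessages(filter_profiles(comp))
  expect_identical(ncol(kept$values), 7L) # 0.4 ... 1.0
  expect_true(0.4 %in% kept$meta$tas)

  none <- suppressMessages(suppressWarnings(
    filter_profiles(comp, tas_min = 1.01)
  ))
  expect_identical(ncol(none$values), 0L)
  expect_warning(
    suppressMessages(filter_profiles(comp, tas_min = 1.01)),
    "no experiment"
  )

  sub <- suppressMessages(
    filter_profiles(comp, gene_universe = c("g2", "g4"))
  )
  expect_identical(rownames(sub$values), c("g2", "g4"))
  expect_error(
    suppressMessages(filter_profiles(comp, gene_universe = "nope")),
    "absent"
  )
})

test_that("shift ability is ES_S minus ES_R with the documented extremes", {
  set.seed(2)
  v <- setNames(rnorm(100), paste0("g", 1:100))
  same <- shift_ability(v, paste0("g", 1:10), paste0("g", 1:10))
  expect_identical(same$shift_ability, 0)

  # S at the very top and R at the very bottom: exactly 2
  ranked <- setNames(seq(100, 1), paste0("g", sprintf("%03d", 1:100)))
  ex <- shift_ability(
    ranked,
    r_sig = names(ranked)[96:100], s_sig = names(ranked)[1:5]
  )
  expect_identical(ex$es_s, 1)
  expect_identical(ex$es_r, -1)
  expect_identical(ex$shift_ability, 2)
  expect_true(ex$r_suppressed && ex$s_induced)

  # oracle equivalence on a seeded random profile
  set.seed(33)
  prof <- setNames(rnorm(1000), paste0("g", 1:1000))
  s_sig <- sample(names(prof), 20)
  r_sig <- sample(setdiff(names(prof), s_sig), 20)
  res <- shift_ability(prof, r_sig, s_sig)
  expect_equal(
    res$shift_ability,
    oracle_es(prof, names(prof), s_sig) - oracle_es(prof, names(prof), r_sig),
    tolerance = 1e-12
  )
  expect_error(shift_ability(prof, "absent", s_sig), "no members")
})

test_that("R-to-S calls are inclusive at the threshold and monotone", {
  expect_true(call_r_to_s(0.7))
  expect_false(call_r_to_s(0.6999))
  set.seed(4)
  shifts <- sort(runif(50, -2, 2))
  calls <- call_r_to_s(shifts)
  expect_true(all(diff(calls) >= 0)) # calls form a suffix in sorted order
})

test_that("knockdown efficiency needs a negative z below the panel bar", {
  v <- c(TP53 = -3, OTHER = 1)
  a <- assess_knockdown(v, "TP53", c(-3, 0, 0.5, 1))
  expect_true(a$efficient)
  expect_identical(a$target_z, -3)

  b <- assess_knockdown(c(TP53 = 1), "TP53", c(-3, 0, 0.5, 1))
  expect_false(b$efficient)
  expect_identical(b$reason, "positive_change")

  miss <- assess_knockdown(c(OTHER = 1), "TP53", c(0, 1))
  expect_false(miss$efficient)
  expect_identical(miss$reason, "target_absent")

  # percentile cut equals the linear-interpolation order statistic
  set.seed(5)
  panel <- rnorm(8)
  cut <- oracle_percentile(panel, 25)
  just_below <- setNames(cut - 1e-9, "G")
  just_above <- setNames(cut + 1e-9, "G")
  if (cut < 0) {
    expect_true(assess_knockdown(just_below, "G", panel)$efficient)
    expect_false(assess_knockdown(just_above, "G", panel)$efficient)
  }
})

test_that("panel-wide knockdown assessment uses same-cell-line shRNAs", {
  genes <- paste0("g", 1:6)
  v <- matrix(0, 6, 4, dimnames = list(genes, paste0("e", 1:4)))
  v["g1", ] <- c(-4, 0.5, 1, 2) # e1 knocks g1 down, rest do not
  meta <- data.frame(
    experiment_id = paste0("e", 1:4),
    perturbagen_id = paste0("sh", 1:4),
    perturbagen_type = "shRNA",
    target_gene = "g1",
    cell_line = c("A", "A", "A", "A"),
    dose = "x", time = "x", tas = 0.9,
    stringsAsFactors = FALSE
  )
  kd <- assess_knockdowns(perturbation_compendium(v, meta))
  expect_identical(kd$efficient, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("perturbagen aggregation summarizes calls per cell line", {
  screen <- data.frame(
    perturbagen_id = c("a", "a", "b"),
    perturbagen_type = "compound",
    target_gene = NA_character_,
    cell_line = c("X", "X", "X"),
    shift_ability = c(0.8, 0.6, -0.1),
    stringsAsFactors = FALSE
  )
  agg <- aggregate_perturbagen(screen, threshold = 0.7)
  a_row <- agg[agg$perturbagen_id == "a", ]
  expect_equal(a_row$mean_shift, 0.7)
  expect_equal(a_row$frac_called, 0.5)
  expect_true(a_row$any_call)
  b_row <- agg[agg$perturbagen_id == "b", ]
  expect_identical(b_row$n_experiments, 1L)
  expect_false(b_row$any_call)

  # order invariance
  agg2 <- aggregate_perturbagen(screen[c(3, 1, 2), ], threshold = 0.7)
  expect_identical(agg, agg2)
})

test_that("concordance demands both modalities in the same cell line", {
  cp <- data.frame(
    perturbagen_id = c("d1", "d2"),
    cell_line = c("B", "A"),
    r_to_s_call = c(TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  sh <- data.frame(
    experiment_id = c("e1", "e2"),
    target_gene = c("T1", "T2"),
    cell_line = c("A", "A"),
    r_to_s_call = c(TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  map <- data.frame(
    perturbagen_id = c("d1", "d2"),
    target_gene = c("T1", "T2"),
    stringsAsFactors = FALSE
  )
  kd <- data.frame(
    experiment_id = c("e1", "e2"), efficient = c(TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  res <- concordant_targets(cp, sh, map, kd)
  # T1: shRNA calls in A, compound in B only -> not retained
  expect_identical(res$target_gene, "T2")
  expect_identical(res$cell_lines_concordant, "A")

  # an inefficient knockdown breaks concordance
  kd2 <- data.frame(
    experiment_id = c("e1", "e2"), efficient = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  expect_identical(nrow(concordant_targets(cp, sh, map, kd2)), 0L)
})

test_that("planted concordant targets are recovered from a compendium", {
  cohort_genes <- sprintf("g%05d", 1:500)
  r_sig <- cohort_genes[1:50]
  s_sig <- cohort_genes[51:100]
  # 3 concordant targets, 2 shRNA-only, 2 compound-only decoys
  cp_plan <- data.frame(
    perturbagen_id = sprintf("cpd%02d", 1:7),
    target_gene = c(r_sig[1:3], r_sig[4:5], r_sig[6:7]),
    gamma = c(3, 3, 3, 0, 0, 3, 3),
    mechanism = NA_integer_,
    stringsAsFactors = FALSE
  )
  sh_plan <- data.frame(
    perturbagen_id = sprintf("sh%02d", 1:7),
    target_gene = cp_plan$target_gene,
    gamma = c(3, 3, 3, 3, 3, 0, 0),
    stringsAsFactors = FALSE
  )
  gen <- gen_perturbation_compendium(
    n_genes = 500, cell_lines = c("A", "B"),
    r_sig = r_sig, s_sig = s_sig,
    compound_plan = cp_plan, shrna_plan = sh_plan,
    module_size = 20, seed = 21
  )
  screen <- shift_screen(gen$compendium, gen$r_sig, gen$s_sig)
  kd <- assess_knockdowns(gen$compendium)
  is_cpd <- screen$perturbagen_type == "compound"
  conc <- concordant_targets(
    screen[is_cpd, ], screen[!is_cpd, ],
    gen$drug_target_map, kd
  )
  expect_setequal(conc$target_gene, r_sig[1:3])
})

test_that("prioritization counts significantly negative cancer types", {
  assoc <- data.frame(
    target_gene = rep(c("T1", "T2"), each = 5),
    cancer_type = rep(paste0("ty", 1:5), 2),
    estimate = c(-0.5, -0.6, -0.4, 0.2, 0.1, 0.1, -0.05, 0.02, 0.3, -0.2),
    p_value = c(0.001, 0.01, 0.04, 0.2, 0.9, 0.5, 0.6, 0.9, 0.2, 0.4),
    stringsAsFactors = FALSE
  )
  out <- prioritize_targets(c("T1", "T2", "T3"), assoc, min_types = 1)
  t1 <- out[out$target_gene == "T1", ]
  expect_true(t1$prioritized)
  expect_identical(t1$n_types_negative, 3L)
  expect_false(out$prioritized[out$target_gene == "T2"])
  t3 <- out[out$target_gene == "T3", ]
  expect_false(t3$prioritized)
  expect_identical(t3$reason, "no_association_data")
})
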