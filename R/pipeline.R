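# Config-driven end-to-end pipeline: simulate -> derive signatures ->
# screen -> prioritize -> cluster -> associate, with deterministic
# standard-format outputs and a machine-readable run report.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with its default:
#' analysis thresholds (`alpha` for the signature split, `tas_min` for
#' profile retention, `shift_threshold` for R-to-S calls, `kd_percentile`
#' for knockdown efficiency, the `+/-1` indicator band is fixed),
#' synthetic-data scales, clustering cut (`cluster_k`, or an absolute
#' `cluster_cutoff`), permutation count and the master seed. All
#' stage-level seeds are derived deterministically from `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param ... Overrides of the defaults listed by
#'   `pipeline_config()$...`; unknown names are an error.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("synshift_run_"), seed = 1,
                            ...) {
  config <- list(
    out_dir = out_dir,
    seed = seed,
    # gene universe shared by all synthetic inputs
    n_genes = 2000,
    # paired cohort
    n_resp = 20, n_nonresp = 20, n_planted = 100, effect = 1.5,
    pseudocount = 1,
    alpha = 0.05,
    # perturbation compendium
    cell_lines = c("CL01", "CL02", "CL03"),
    n_compounds = 200, n_shrna = 100, frac_shifting = 0.15, gamma = 2,
    n_targets_concordant = 5, n_targets_shrna_only = 5,
    n_targets_compound_only = 5,
    tas_min = 0.4,
    shift_threshold = 0.7,
    kd_percentile = 25,
    # target prioritization
    min_types = 1,
    # mechanism clustering
    cluster_k = 2, cluster_cutoff = NULL, n_perm = 1000,
    # pan-cancer cohort
    n_types = 5, n_per_type = 100, beta_survival = 0.7, censor_rate = 0.3
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  config[names(overrides)] <- overrides
  class(config) <- "pipeline_config"
  validate_config(config)
  config
}

validate_config <- function(config) {
  in_range <- function(x, lo, hi, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lo || x > hi) {
      stop("config: ", name, " must be a number in [", lo, ", ", hi, "]",
        call. = FALSE
      )
    }
  }
  in_range(config$alpha, 0, 1, "alpha")
  in_range(config$tas_min, 0, 1, "tas_min")
  in_range(config$shift_threshold, -2, 2, "shift_threshold")
  in_range(config$kd_percentile, 0, 100, "kd_percentile")
  in_range(config$pseudocount, 0, Inf, "pseudocount")
  in_range(config$censor_rate, 0, 1 - 1e-12, "censor_rate")
  if (config$n_perm < 0) {
    stop("config: n_perm must be nonnegative", call. = FALSE)
  }
  invisible(config)
}

# Hash of the analysis-relevant configuration (the output path does not
# change what is computed, so it is excluded).
config_hash <- function(config) {
  config <- unclass(config)
  config$out_dir <- NULL
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

# Deterministic TSV writer: every output file starts with a comment line
# carrying the config hash and seed, so re-runs are verifiably identical.
write_stage_tsv <- function(df, path, stamp) {
  df <- as.data.frame(df)
  for (cl in names(df)) {
    if (is.list(df[[cl]])) {
      df[[cl]] <- vapply(df[[cl]], paste, character(1), collapse = ",")
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.table(df, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Run the full shift-ability pipeline
#'
#' Orchestrates the stages in analysis order on synthetic inputs drawn at
#' the configured scale: paired-cohort simulation, R/S signature
#' derivation, TAS filtering and shift-ability screening of the
#' perturbation compendium, knockdown assessment, compound/knockdown
#' target concordance, immune-association prioritization in a pan-cancer
#' cohort, consensus mechanism clustering with preranked-GSEA annotation,
#' and signature/immunity/survival association. All stage outputs are
#' written as stamped TSVs plus a JSON run report; identical
#' configurations produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list of class `pipeline_report`), invisibly
#'   also written to `report.json` in `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- paste0(
    "# synshift ", as.character(utils::packageVersion("synshift")),
    " config_hash=", config_hash(config), " seed=", config$seed
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }
  out <- function(name) file.path(config$out_dir, name)

  ## 1. simulate paired cohort + derive signatures -----------------------
  sim <- stage("simulate", gen_paired_cohort(
    n_resp = config$n_resp, n_nonresp = config$n_nonresp,
    n_genes = config$n_genes, n_planted = config$n_planted,
    effect = config$effect, seed = derive_seed(config$seed, 1)
  ))
  changes <- stage("derive-signatures", compute_induced_changes(
    sim$cohort,
    pseudocount = config$pseudocount
  ))
  sig <- stage("derive-signatures", derive_signatures(
    changes, sim$cohort$response,
    alpha = config$alpha
  ))
  recovered_r <- intersect(r_genes(sig), sim$truth$planted_r_genes)
  recovered_s <- intersect(s_genes(sig), sim$truth$planted_s_genes)
  write_stage_tsv(sig$table, out("signature.tsv"), stamp)

  ## 2. simulate compendium with planted concordance structure -----------
  plans <- stage("simulate", make_target_plans(config, sim$truth))
  comp <- stage("simulate", gen_perturbation_compendium(
    n_genes = config$n_genes, cell_lines = config$cell_lines,
    r_sig = sim$truth$planted_r_genes, s_sig = sim$truth$planted_s_genes,
    compound_plan = plans$compound_plan, shrna_plan = plans$shrna_plan,
    gamma = config$gamma, seed = derive_seed(config$seed, 2)
  ))

  ## 3. screen ------------------------------------------------------------
  filtered <- stage("screen", filter_profiles(comp$compendium,
    tas_min = config$tas_min
  ))
  screen <- stage("screen", shift_screen(filtered, sig,
    threshold = config$shift_threshold
  ))
  kd <- stage("screen", assess_knockdowns(filtered, q = config$kd_percentile))
  agg <- stage("screen", aggregate_perturbagen(screen))
  write_stage_tsv(screen, out("screen.tsv"), stamp)
  write_stage_tsv(kd, out("knockdowns.tsv"), stamp)
  write_stage_tsv(agg, out("aggregate.tsv"), stamp)

  ## 4. prioritize --------------------------------------------------------
  is_cpd <- screen$perturbagen_type == "compound"
  conc <- stage("prioritize", concordant_targets(
    screen[is_cpd, , drop = FALSE], screen[!is_cpd, , drop = FALSE],
    comp$drug_target_map, kd
  ))
  pan <- stage("simulate", gen_pancancer_cohort(
    n_types = config$n_types, n_per_type = config$n_per_type,
    n_genes = config$n_genes,
    r_genes = sim$truth$planted_r_genes,
    s_genes = sim$truth$planted_s_genes,
    anti_immune_targets = plans$concordant_targets,
    beta_survival = config$beta_survival,
    censor_rate = config$censor_rate,
    seed = derive_seed(config$seed, 3)
  ))
  cls_scores <- stage("prioritize", immune_class_scores(
    pan$cohort$expression, pan$immune_sets, pan$immune_classes
  ))
  assoc <- stage("prioritize", target_immune_association(
    pan$cohort$expression, cls_scores, pan$cohort$samples$cancer_type,
    conc$target_gene
  ))
  prior <- stage("prioritize", prioritize_targets(conc, assoc,
    min_types = config$min_types, alpha = config$alpha
  ))
  write_stage_tsv(conc, out("concordant_targets.tsv"), stamp)
  write_stage_tsv(prior, out("prioritized_targets.tsv"), stamp)

  ## 5. mechanism clustering ---------------------------------------------
  cluster_report <- list(n_shifting_compounds = 0L)
  shifting <- unique(agg$perturbagen_id[agg$any_call &
    agg$perturbagen_type == "compound"])
  cluster_report$n_shifting_compounds <- length(shifting)
  if (length(shifting) >= 2L) {
    keep <- filtered$meta$perturbagen_id %in% shifting
    ind <- stage("cluster", make_indicators(
      filtered$values[, keep, drop = FALSE],
      filtered$meta$perturbagen_id[keep]
    ))
    cons <- stage("cluster", consensus_vectors(ind))
    clust <- stage("cluster", cluster_compounds(cons,
      cutoff = config$cluster_cutoff, k = config$cluster_k
    ))
    go_sets <- c(
      stats::setNames(
        lapply(seq_along(comp$truth$modules), function(m) {
          gene_set(sprintf("module%d", m), comp$truth$modules[[m]])
        }),
        sprintf("module%d", seq_along(comp$truth$modules))
      ),
      with_seed(derive_seed(config$seed, 4), {
        stats::setNames(
          lapply(1:4, function(k) {
            gene_set(
              sprintf("decoy%d", k),
              sample(rownames(filtered$values), 50)
            )
          }),
          sprintf("decoy%d", 1:4)
        )
      })
    )
    annots <- list()
    for (cl in sort(unique(clust$labels))) {
      members <- names(clust$labels)[clust$labels == cl]
      csig <- cluster_signature(cons[, members, drop = FALSE],
        cluster_id = as.character(cl)
      )
      ann <- stage("cluster", annotate_cluster(csig, go_sets,
        n_perm = config$n_perm, seed = derive_seed(config$seed, 5) + cl
      ))
      ann$cluster <- cl
      annots[[as.character(cl)]] <- ann
      write_stage_tsv(
        data.frame(
          gene = csig$profile$gene_ids,
          consensus = csig$profile$scores
        ),
        out(sprintf("cluster_signature_%s.tsv", cl)), stamp
      )
    }
    annot_all <- do.call(rbind, annots)
    write_stage_tsv(
      data.frame(
        compound = names(clust$labels),
        cluster = unname(clust$labels)
      ),
      out("cluster_labels.tsv"), stamp
    )
    write_stage_tsv(
      data.frame(
        merge_left = clust$hclust$merge[, 1L],
        merge_right = clust$hclust$merge[, 2L],
        height = clust$hclust$height
      ),
      out("cluster_linkage.tsv"), stamp
    )
    write_stage_tsv(annot_all, out("cluster_annotation.tsv"), stamp)
    planted_mech <- plans$mechanism_of_compound[names(clust$labels)]
    cluster_report$sizes <- as.list(table(clust$labels))
    cluster_report$mechanism_confusion <- as.list(as.data.frame(
      table(planted = planted_mech, cluster = clust$labels)
    ))
    cluster_report$top_annotation <- lapply(annots, function(a) {
      list(set_id = a$set_id[1L], nes = a$nes[1L], fdr = a$fdr[1L])
    })
  }

  ## 6. cohort association ------------------------------------------------
  sur <- stage("associate", surrogate_by_type(
    pan$cohort$expression,
    pan$cohort$samples$cancer_type
  ))
  r_score <- stage("associate", signature_score(sur, sig, "R"))
  s_score <- stage("associate", signature_score(sur, sig, "S"))
  cd8 <- pan$cohort$infiltration[, "t_cell_cd8"]
  assoc_r <- correlate_with_immunity(r_score, cd8,
    pan$cohort$samples$cancer_type)
  assoc_s <- correlate_with_immunity(s_score, cd8,
    pan$cohort$samples$cancer_type)
  assoc_r$score <- "R"
  assoc_s$score <- "S"
  write_stage_tsv(rbind(assoc_r, assoc_s), out("association.tsv"), stamp)
  surv <- stage("associate", survival_association(
    r_score, pan$cohort$samples$pfi_time, pan$cohort$samples$pfi_event
  ))
  lr <- stage("associate", tertile_logrank(
    r_score, pan$cohort$samples$pfi_time, pan$cohort$samples$pfi_event
  ))
  write_stage_tsv(
    data.frame(
      score = "R", hazard_ratio = surv$hazard_ratio, log_hr = surv$log_hr,
      p_value = surv$p_value, logrank_chisq = lr$chi_square,
      logrank_p = lr$p_value
    ),
    out("survival.tsv"), stamp
  )

  ## report ---------------------------------------------------------------
  report <- list(
    package_version = as.character(utils::packageVersion("synshift")),
    seed = config$seed,
    config_hash = unname(config_hash(config)),
    signatures = list(
      n_r = length(r_genes(sig)), n_s = length(s_genes(sig)),
      planted_per_direction = config$n_planted,
      recovered_r = length(recovered_r), recovered_s = length(recovered_s)
    ),
    screen = list(
      n_experiments_total = ncol(comp$compendium$values),
      n_experiments_kept = nrow(screen),
      n_r_to_s_calls = sum(screen$r_to_s_call),
      n_shifting_compounds = cluster_report$n_shifting_compounds,
      planted_shifting_compounds =
        sum(plans$compound_plan$gamma > 0)
    ),
    targets = list(
      planted_concordant = length(plans$concordant_targets),
      recovered_concordant = nrow(conc),
      concordant_true_positive =
        length(intersect(conc$target_gene, plans$concordant_targets)),
      n_prioritized = sum(prior$prioritized)
    ),
    clusters = cluster_report,
    association = list(
      mean_pearson_r_s_vs_cd8 = mean(assoc_s$pearson_r),
      mean_pearson_r_r_vs_cd8 = mean(assoc_r$pearson_r),
      hazard_ratio_r = surv$hazard_ratio,
      logrank_p = lr$p_value
    )
  )
  jsonlite::write_json(report, out("report.json"),
    auto_unbox = TRUE,
    digits = NA, pretty = TRUE
  )
  class(report) <- "pipeline_report"
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("synshift pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("  signatures: ", x$signatures$n_r, " R / ", x$signatures$n_s,
    " S genes (planted ", x$signatures$planted_per_direction,
    " per direction; recovered ", x$signatures$recovered_r, " R / ",
    x$signatures$recovered_s, " S)\n",
    sep = ""
  )
  cat("  screen: ", x$screen$n_r_to_s_calls, " R-to-S calls over ",
    x$screen$n_experiments_kept, " experiments; ",
    x$screen$n_shifting_compounds, " shifting compounds\n",
    sep = ""
  )
  cat("  targets: ", x$targets$recovered_concordant, " concordant (",
    x$targets$concordant_true_positive, " planted of ",
    x$targets$planted_concordant, "), ", x$targets$n_prioritized,
    " prioritized\n",
    sep = ""
  )
  cat("  survival: HR(R score) = ",
    signif(x$association$hazard_ratio_r, 4),
    ", log-rank p = ", signif(x$association$logrank_p, 3), "\n",
    sep = ""
  )
  invisible(x)
}

# Per-cancer-type surrogate changes: each gene centered on its
# within-type population baseline.
surrogate_by_type <- function(expression, cancer_type) {
  out <- expression
  for (ty in unique(cancer_type)) {
    i <- cancer_type == ty
    out[, i] <- expression[, i, drop = FALSE] -
      rowMeans(expression[, i, drop = FALSE])
  }
  attr(out, "provenance") <- "surrogate"
  out
}

# Compound/shRNA plans with planted concordance structure: concordant
# targets get both a shifting compound and a shifting shRNA; decoys get
# only one modality shifting. Targets are drawn from the planted R genes
# (knocking down a resistance gene is what shifts the phenotype).
make_target_plans <- function(config, cohort_truth) {
  n_con <- config$n_targets_concordant
  n_sh <- config$n_targets_shrna_only
  n_cp <- config$n_targets_compound_only
  targets <- cohort_truth$planted_r_genes[seq_len(n_con + n_sh + n_cp)]
  concordant <- targets[seq_len(n_con)]
  shrna_only <- targets[n_con + seq_len(n_sh)]
  compound_only <- targets[n_con + n_sh + seq_len(n_cp)]

  cp <- default_compound_plan(
    config$n_compounds, config$frac_shifting,
    config$gamma, 2
  )
  # map targeted compounds onto the first shifting (concordant,
  # compound-only) and first non-shifting (shrna-only) compounds
  shift_rows <- which(cp$gamma > 0)
  null_rows <- which(cp$gamma == 0)
  stopifnot(
    length(shift_rows) >= n_con + n_cp,
    length(null_rows) >= n_sh
  )
  cp$target_gene[shift_rows[seq_len(n_con)]] <- concordant
  cp$target_gene[shift_rows[n_con + seq_len(n_cp)]] <- compound_only
  cp$target_gene[null_rows[seq_len(n_sh)]] <- shrna_only

  sh_targets <- c(concordant, shrna_only, compound_only)
  n_extra <- max(0L, config$n_shrna - length(sh_targets))
  extra <- setdiff(cohort_truth$planted_r_genes, sh_targets)[seq_len(n_extra)]
  sh <- data.frame(
    perturbagen_id = sprintf("sh%04d", seq_len(length(sh_targets) + n_extra)),
    target_gene = c(sh_targets, extra),
    gamma = c(
      rep(config$gamma, length(concordant) + length(shrna_only)),
      rep(0, length(compound_only)), rep(0, n_extra)
    ),
    stringsAsFactors = FALSE
  )
  mech <- stats::setNames(cp$mechanism, cp$perturbagen_id)
  list(
    compound_plan = cp, shrna_plan = sh,
    concordant_targets = concordant,
    shrna_only_targets = shrna_only,
    compound_only_targets = compound_only,
    mechanism_of_compound = mech
  )
}

#' Validate standard input formats
#'
#' Diagnostic (never failing) conformity checks of pipeline input files:
#' GCT files must carry a `#1.3` version line and a consistent dimensions
#' line; GMT lines need at least three tab-separated fields; compendium
#' metadata TSVs must carry the full metadata column set including `tas`.
#'
#' @param paths Character vector of file paths.
#' @return Data.frame with columns `file` and `issue`; zero rows when
#'   every file conforms.
#' @export
validate_formats <- function(paths) {
  issues <- list()
  flag <- function(path, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(
      file = path, issue = msg,
      stringsAsFactors = FALSE
    )
  }
  meta_cols <- c(
    "experiment_id", "perturbagen_id", "perturbagen_type",
    "target_gene", "cell_line", "dose", "time", "tas"
  )
  for (path in paths) {
    if (!file.exists(path)) {
      flag(path, "file not found")
      next
    }
    ext <- tolower(tools::file_ext(path))
    if (ext == "gct") {
      header <- readLines(path, n = 2L)
      if (length(header) < 2L || !startsWith(header[1L], "#1.")) {
        flag(path, "missing '#1.x' GCT version line")
      } else {
        dims <- suppressWarnings(
          as.integer(strsplit(header[2L], "\t", fixed = TRUE)[[1L]])
        )
        if (length(dims) < 2L || anyNA(dims[1:2])) {
          flag(path, "unparseable GCT dimensions line")
        }
      }
    } else if (ext == "gmt") {
      nf <- lengths(strsplit(readLines(path), "\t", fixed = TRUE))
      if (any(nf < 3L)) {
        flag(path, paste0(
          sum(nf < 3L),
          " GMT line(s) with fewer than 3 fields"
        ))
      }
    } else if (ext %in% c("tsv", "txt")) {
      header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
      if ("experiment_id" %in% header) {
        missing_cols <- setdiff(meta_cols, header)
        if (length(missing_cols) > 0L) {
          flag(path, paste0(
            "metadata TSV lacks column(s): ",
            paste(missing_cols, collapse = ", ")
          ))
        }
      }
    }
  }
  out <- if (length(issues) > 0L) {
    do.call(rbind, issues)
  } else {
    data.frame(file = character(0), issue = character(0),
      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
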