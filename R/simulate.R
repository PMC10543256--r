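# Synthetic-data generators. They emulate the statistical structure the
# pipeline assumes — a paired pre-/on-treatment cohort with planted
# response-dependent induced changes, a level-5-style perturbation
# compendium with planted R-to-S shifters, knockdown effects and mechanism
# modules, and a pan-cancer cohort with an immune latent factor and
# survival tied to the R-signature average — at a reduced scale, so every
# stage is testable against known ground truth without any download.
# All generators are pure functions of their arguments and seed.

gene_universe_ids <- function(n_genes) {
  sprintf("g%05d", seq_len(n_genes))
}

#' Simulate a paired pre-/on-treatment immunotherapy cohort
#'
#' Pre-treatment log2 expression is a per-gene baseline plus Gaussian
#' noise; on-treatment expression adds a per-patient induced change
#' `delta ~ N(0, noise_sd^2)`, shifted by `+effect * noise_sd` on the
#' planted S genes in responders and on the planted R genes in
#' non-responders. The default sizes mirror a paired melanoma anti-PD-1
#' cohort of 20 + 20 evaluable patients profiled on a reduced
#' 10,000-gene space.
#'
#' @param n_resp,n_nonresp Patients per response class (>= 2 each).
#' @param n_genes Size of the gene universe.
#' @param n_planted Planted genes per direction (S and R).
#' @param effect Planted induced-change shift in units of `noise_sd`.
#' @param noise_sd Standard deviation of expression noise and of the
#'   induced change.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution (log2
#'   scale).
#' @param seed Integer seed.
#' @return List with `cohort` (a [paired_cohort()], log2 scale) and
#'   `truth` (`planted_s_genes`, `planted_r_genes`, `effect`,
#'   `noise_sd`).
#' @export
gen_paired_cohort <- function(n_resp = 20, n_nonresp = 20, n_genes = 10000,
                              n_planted = 200, effect = 1.5, noise_sd = 1,
                              baseline_mean = 7, baseline_sd = 1, seed = 1) {
  stopifnot(n_resp >= 2L, n_nonresp >= 2L, effect >= 0, noise_sd > 0)
  if (2L * n_planted > n_genes) {
    stop("2 * n_planted may not exceed n_genes", call. = FALSE)
  }
  with_seed(seed, {
    genes <- gene_universe_ids(n_genes)
    patients <- c(
      sprintf("R%03d", seq_len(n_resp)),
      sprintf("N%03d", seq_len(n_nonresp))
    )
    response <- rep(c("R", "NR"), c(n_resp, n_nonresp))
    n <- n_resp + n_nonresp
    planted <- sample.int(n_genes, 2L * n_planted)
    s_idx <- planted[seq_len(n_planted)]
    r_idx <- planted[n_planted + seq_len(n_planted)]
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    pre <- baseline + matrix(stats::rnorm(n_genes * n, sd = noise_sd),
      n_genes, n
    )
    delta <- matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n)
    if (n_planted > 0L) {
      delta[s_idx, response == "R"] <-
        delta[s_idx, response == "R"] + effect * noise_sd
      delta[r_idx, response == "NR"] <-
        delta[r_idx, response == "NR"] + effect * noise_sd
    }
    post <- pre + delta
    dimnames(pre) <- dimnames(post) <- list(genes, patients)
    list(
      cohort = paired_cohort(pre, post, response, scale = "log2"),
      truth = list(
        planted_s_genes = genes[s_idx],
        planted_r_genes = genes[r_idx],
        effect = effect, noise_sd = noise_sd
      )
    )
  })
}

default_compound_plan <- function(n_compounds, frac_shifting, gamma,
                                  n_mechanisms) {
  n_shift <- round(frac_shifting * n_compounds)
  data.frame(
    perturbagen_id = sprintf("cpd%04d", seq_len(n_compounds)),
    target_gene = NA_character_,
    gamma = c(rep(gamma, n_shift), rep(0, n_compounds - n_shift)),
    mechanism = c(
      rep_len(seq_len(n_mechanisms), n_shift),
      rep(NA_integer_, n_compounds - n_shift)
    ),
    stringsAsFactors = FALSE
  )
}

#' Simulate a level-5-style perturbation compendium
#'
#' Each experiment's profile is standard normal over the gene universe;
#' perturbagens with reversal strength `gamma > 0` additionally get
#' `+gamma` on the planted S genes and `-gamma` on the planted R genes
#' (an R-to-S shifter), plus `+module_strength` on their mechanism's gene
#' module, so mechanism clusters are recoverable from consensus
#' signatures. shRNA profiles set their target gene's value to
#' `kd_effect` (a successful knockdown when negative). TAS is drawn from
#' a Beta distribution whose parameters depend on whether the perturbagen
#' is active (`gamma > 0`), reflecting that the activity score tracks
#' signal strength.
#'
#' The experiment layout, reversal strengths and targets can be
#' controlled explicitly through `compound_plan` /`shrna_plan`
#' data.frames (columns `perturbagen_id`, `target_gene`, `gamma`, and
#' `mechanism` for compounds); by default `frac_shifting` of the
#' compounds are shifters at strength `gamma` split evenly over
#' `n_mechanisms` mechanisms, and the shRNAs target the first planted R
#' genes at the same strength.
#'
#' @param n_genes Gene universe size.
#' @param cell_lines Character vector of cell lines; every perturbagen is
#'   profiled once per cell line and replicate.
#' @param n_compounds,n_shrna Perturbagen counts (used when no plan is
#'   given).
#' @param frac_shifting Fraction of compounds planted as R-to-S shifters.
#' @param gamma Default planted reversal strength.
#' @param n_reps Replicates (experiments) per perturbagen and cell line.
#' @param r_sig,s_sig Optional planted signatures ([gene_set()] or gene
#'   ids); sampled disjointly of size `n_sig` when `NULL`.
#' @param n_sig Planted signature size per direction.
#' @param compound_plan,shrna_plan Optional explicit perturbagen plans
#'   (see Details).
#' @param n_mechanisms,module_size,module_strength Mechanism-module
#'   layout for shifting compounds.
#' @param kd_effect Value assigned to an shRNA's target gene. The default
#'   (`-6`) is substantially below the signature-wide suppression `-gamma`,
#'   reflecting that direct on-target knockdown is stronger than the
#'   indirect signature response — which is what lets a panel-relative
#'   percentile criterion recognize it.
#' @param tas_null,tas_active Beta parameters (shape1, shape2) of the TAS
#'   distribution for inactive/active perturbagens.
#' @param seed Integer seed.
#' @return List with `compendium` (a [perturbation_compendium()]),
#'   `r_sig`, `s_sig` (the planted signatures as [gene_set()]s),
#'   `drug_target_map` (compound to target), and `truth` (plans, module
#'   gene lists, per-perturbagen `gamma`).
#' @export
gen_perturbation_compendium <- function(n_genes = 2000,
                                        cell_lines = c("CL01", "CL02", "CL03"),
                                        n_compounds = 200, n_shrna = 100,
                                        frac_shifting = 0.15, gamma = 2,
                                        n_reps = 1,
                                        r_sig = NULL, s_sig = NULL,
                                        n_sig = 100,
                                        compound_plan = NULL,
                                        shrna_plan = NULL,
                                        n_mechanisms = 2, module_size = 100,
                                        module_strength = 2, kd_effect = -6,
                                        tas_null = c(2, 4),
                                        tas_active = c(6, 2),
                                        seed = 1) {
  with_seed(seed, {
    genes <- gene_universe_ids(n_genes)
    if (is.null(r_sig) || is.null(s_sig)) {
      picked <- sample(genes, 2L * n_sig)
      if (is.null(r_sig)) r_sig <- picked[seq_len(n_sig)]
      if (is.null(s_sig)) s_sig <- picked[n_sig + seq_len(n_sig)]
    }
    r_sig <- as_one_gene_set(r_sig, "R")
    s_sig <- as_one_gene_set(s_sig, "S")
    r_idx <- match(intersect(r_sig$members, genes), genes)
    s_idx <- match(intersect(s_sig$members, genes), genes)
    stopifnot(length(r_idx) > 0L, length(s_idx) > 0L)

    free <- setdiff(seq_len(n_genes), c(r_idx, s_idx))
    modules <- lapply(seq_len(n_mechanisms), function(m) {
      idx <- free[(m - 1L) * module_size + seq_len(module_size)]
      idx[!is.na(idx)]
    })

    if (is.null(compound_plan)) {
      compound_plan <- default_compound_plan(
        n_compounds, frac_shifting,
        gamma, n_mechanisms
      )
    }
    if (is.null(shrna_plan) && n_shrna > 0L) {
      targets <- rep_len(r_sig$members[seq_len(min(n_shrna, length(r_sig$members)))],
        n_shrna
      )
      shrna_plan <- data.frame(
        perturbagen_id = sprintf("sh%04d", seq_len(n_shrna)),
        target_gene = targets,
        gamma = rep(gamma, n_shrna),
        stringsAsFactors = FALSE
      )
    }
    if (is.null(shrna_plan)) {
      shrna_plan <- data.frame(
        perturbagen_id = character(0), target_gene = character(0),
        gamma = numeric(0), stringsAsFactors = FALSE
      )
    }
    if (is.null(compound_plan$mechanism)) {
      compound_plan$mechanism <- NA_integer_
    }

    plan <- rbind(
      data.frame(
        perturbagen_id = compound_plan$perturbagen_id,
        perturbagen_type = "compound",
        target_gene = compound_plan$target_gene,
        gamma = compound_plan$gamma,
        mechanism = compound_plan$mechanism,
        stringsAsFactors = FALSE
      ),
      if (nrow(shrna_plan) > 0L) {
        data.frame(
          perturbagen_id = shrna_plan$perturbagen_id,
          perturbagen_type = "shRNA",
          target_gene = shrna_plan$target_gene,
          gamma = shrna_plan$gamma,
          mechanism = NA_integer_,
          stringsAsFactors = FALSE
        )
      }
    )

    layout <- expand.grid(
      rep = seq_len(n_reps), cell_line = cell_lines,
      row = seq_len(nrow(plan)),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    n_exp <- nrow(layout)
    values <- matrix(stats::rnorm(n_genes * n_exp), n_genes, n_exp)
    tas <- numeric(n_exp)
    for (e in seq_len(n_exp)) {
      p <- layout$row[e]
      g <- plan$gamma[p]
      if (g > 0) {
        values[s_idx, e] <- values[s_idx, e] + g
        values[r_idx, e] <- values[r_idx, e] - g
        m <- plan$mechanism[p]
        if (!is.na(m)) {
          values[modules[[m]], e] <- values[modules[[m]], e] + module_strength
        }
      }
      if (plan$perturbagen_type[p] == "shRNA") {
        ti <- match(plan$target_gene[p], genes)
        if (!is.na(ti)) {
          values[ti, e] <- kd_effect
        }
      }
      shp <- if (g > 0) tas_active else tas_null
      tas[e] <- stats::rbeta(1, shp[1L], shp[2L])
    }
    experiment_id <- sprintf(
      "%s_%s_r%d", plan$perturbagen_id[layout$row],
      layout$cell_line, layout$rep
    )
    dimnames(values) <- list(genes, experiment_id)
    meta <- data.frame(
      experiment_id = experiment_id,
      perturbagen_id = plan$perturbagen_id[layout$row],
      perturbagen_type = plan$perturbagen_type[layout$row],
      target_gene = plan$target_gene[layout$row],
      cell_line = layout$cell_line,
      dose = "10uM",
      time = "24h",
      tas = tas,
      stringsAsFactors = FALSE
    )
    map_rows <- !is.na(compound_plan$target_gene)
    drug_target_map <- data.frame(
      perturbagen_id = compound_plan$perturbagen_id[map_rows],
      target_gene = compound_plan$target_gene[map_rows],
      stringsAsFactors = FALSE
    )
    list(
      compendium = perturbation_compendium(values, meta),
      r_sig = r_sig, s_sig = s_sig,
      drug_target_map = drug_target_map,
      truth = list(
        compound_plan = compound_plan, shrna_plan = shrna_plan,
        modules = lapply(modules, function(i) genes[i]),
        gamma = stats::setNames(plan$gamma, plan$perturbagen_id)
      )
    )
  })
}

#' Simulate a pan-cancer association and survival cohort
#'
#' A per-sample latent immune factor drives the immune-response signature
#' genes and the infiltration estimates positively and the planted
#' anti-immune target genes negatively; a second latent factor drives the
#' R-signature genes, and survival times are exponential with log-hazard
#' `beta_survival` times the realized per-sample R-signature average
#' (centered within cancer type), under independent exponential
#' censoring.
#'
#' @param n_types,n_per_type Cancer types and samples per type.
#' @param n_genes Gene universe size.
#' @param r_genes,s_genes Signature gene ids (sampled when `NULL`).
#' @param n_sig Signature size per direction when sampling.
#' @param anti_immune_targets Gene ids planted as negatively
#'   immune-associated; defaults to the first 5 R-signature genes.
#' @param immune_loading,anti_loading Latent-factor loadings of immune
#'   signature genes and anti-immune targets.
#' @param n_classes,sets_per_class,set_size Immune-response signature
#'   collection layout.
#' @param beta_survival Planted log-hazard coefficient on the R-signature
#'   average.
#' @param base_hazard Baseline exponential hazard.
#' @param censor_rate Approximate censoring fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `cohort` (a [pancancer_cohort()]), `immune_sets`
#'   (list of [gene_set()]s), `immune_classes` (set id to class map), and
#'   `truth`.
#' @export
gen_pancancer_cohort <- function(n_types = 5, n_per_type = 100,
                                 n_genes = 2000,
                                 r_genes = NULL, s_genes = NULL, n_sig = 100,
                                 anti_immune_targets = NULL,
                                 immune_loading = 1, anti_loading = -1,
                                 n_classes = 4, sets_per_class = 2,
                                 set_size = 30,
                                 beta_survival = 0.7, base_hazard = 0.1,
                                 censor_rate = 0.3, seed = 1) {
  stopifnot(censor_rate >= 0, censor_rate < 1)
  with_seed(seed, {
    genes <- gene_universe_ids(n_genes)
    if (is.null(r_genes) || is.null(s_genes)) {
      picked <- sample(genes, 2L * n_sig)
      if (is.null(r_genes)) r_genes <- picked[seq_len(n_sig)]
      if (is.null(s_genes)) s_genes <- picked[n_sig + seq_len(n_sig)]
    }
    r_genes <- intersect(as.character(r_genes), genes)
    s_genes <- intersect(as.character(s_genes), genes)
    if (is.null(anti_immune_targets)) {
      anti_immune_targets <- r_genes[seq_len(min(5L, length(r_genes)))]
    }
    anti_immune_targets <- intersect(as.character(anti_immune_targets), genes)

    n <- n_types * n_per_type
    cancer_type <- rep(sprintf("T%02d", seq_len(n_types)), each = n_per_type)
    sample_id <- sprintf("S%05d", seq_len(n))

    free <- setdiff(genes, c(r_genes, s_genes, anti_immune_targets))
    n_sets <- n_classes * sets_per_class
    if (length(free) < n_sets * set_size) {
      stop("gene universe too small for the immune-signature layout (",
        length(free), " free genes, ", n_sets * set_size, " needed)",
        call. = FALSE
      )
    }
    imm_genes <- sample(free, n_sets * set_size)
    immune_sets <- lapply(seq_len(n_sets), function(k) {
      gene_set(
        sprintf("imm%02d", k),
        imm_genes[(k - 1L) * set_size + seq_len(set_size)]
      )
    })
    names(immune_sets) <- vapply(immune_sets, function(s) s$set_id,
      character(1))
    immune_classes <- stats::setNames(
      rep(sprintf("class%d", seq_len(n_classes)), each = sets_per_class),
      names(immune_sets)
    )

    f_immune <- stats::rnorm(n)
    u_resist <- stats::rnorm(n)
    expr <- matrix(stats::rnorm(n_genes * n), n_genes, n,
      dimnames = list(genes, sample_id)
    )
    expr <- expr + stats::rnorm(n_genes, mean = 6, sd = 1) # gene baselines
    expr[imm_genes, ] <- expr[imm_genes, ] +
      rep(immune_loading * f_immune, each = length(imm_genes))
    expr[s_genes, ] <- expr[s_genes, ] +
      rep(immune_loading * f_immune, each = length(s_genes))
    expr[r_genes, ] <- expr[r_genes, ] +
      rep(u_resist, each = length(r_genes))
    expr[anti_immune_targets, ] <- expr[anti_immune_targets, ] +
      rep(anti_loading * f_immune, each = length(anti_immune_targets))

    cell_types <- c("t_cell_cd8", "t_cell_cd4", "b_cell", "macrophage",
      "dendritic")
    infiltration <- vapply(cell_types, function(ct) {
      pmax(0, 0.2 + 0.05 * f_immune + stats::rnorm(n, sd = 0.02))
    }, numeric(n))
    rownames(infiltration) <- sample_id

    r_avg <- colMeans(expr[r_genes, , drop = FALSE])
    r_avg <- r_avg - stats::ave(r_avg, cancer_type) # center within type
    hazard <- base_hazard * exp(beta_survival * r_avg)
    t_event <- stats::rexp(n, rate = hazard)
    pfi_time <- t_event
    pfi_event <- rep(1L, n)
    if (censor_rate > 0) {
      c_rate <- base_hazard * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(n, rate = c_rate)
      pfi_event <- as.integer(t_event <= t_cens)
      pfi_time <- pmin(t_event, t_cens)
    }
    samples <- data.frame(
      sample_id = sample_id, cancer_type = cancer_type,
      pfi_time = pfi_time, pfi_event = pfi_event,
      stringsAsFactors = FALSE
    )
    list(
      cohort = pancancer_cohort(expr, samples, infiltration),
      immune_sets = immune_sets,
      immune_classes = immune_classes,
      truth = list(
        r_genes = r_genes, s_genes = s_genes,
        anti_immune_targets = anti_immune_targets,
        beta_survival = beta_survival,
        f_immune = stats::setNames(f_immune, sample_id),
        r_avg = stats::setNames(r_avg, sample_id)
      )
    )
  })
}
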