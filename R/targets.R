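# Synergy-target concordance and immune-association prioritization.

#' Drug targets with concordant compound and knockdown shifting
#'
#' A target is retained when there exists at least one cell line in which
#' (a) some shRNA experiment against the target is called R-to-S with an
#' efficient knockdown, and (b) some compound mapped to the target is
#' called R-to-S. The same-cell-line requirement is what distinguishes a
#' pharmacologically actionable target from a coincidental shifter.
#'
#' @param compound_screen `shift_screen` rows (or any data.frame with
#'   `perturbagen_id`, `cell_line`, `r_to_s_call`) for compound
#'   experiments.
#' @param shrna_screen `shift_screen` rows for shRNA experiments (must
#'   include `experiment_id`, `target_gene`, `cell_line`, `r_to_s_call`).
#' @param drug_target_map Data.frame mapping `perturbagen_id` to
#'   `target_gene`; compounds absent from the map are skipped (their
#'   count is reported via `message()`).
#' @param knockdowns Output of [assess_knockdowns()]; joined to
#'   `shrna_screen` by `experiment_id` to supply the `efficient` flag.
#' @return Data.frame with one row per concordant target: `target_gene`,
#'   `cell_lines_concordant` (comma-separated), `n_cell_lines`, sorted by
#'   target.
#' @export
concordant_targets <- function(compound_screen, shrna_screen,
                               drug_target_map, knockdowns) {
  stopifnot(
    is.data.frame(compound_screen), is.data.frame(shrna_screen),
    is.data.frame(drug_target_map), is.data.frame(knockdowns)
  )
  eff <- knockdowns$efficient[match(
    shrna_screen$experiment_id,
    knockdowns$experiment_id
  )]
  eff[is.na(eff)] <- FALSE
  sh_hit <- shrna_screen$r_to_s_call & eff
  sh_pairs <- unique(data.frame(
    target_gene = shrna_screen$target_gene[sh_hit],
    cell_line = shrna_screen$cell_line[sh_hit],
    stringsAsFactors = FALSE
  ))

  cp_target <- drug_target_map$target_gene[match(
    compound_screen$perturbagen_id,
    drug_target_map$perturbagen_id
  )]
  unmapped <- is.na(cp_target)
  n_unmapped <- length(unique(compound_screen$perturbagen_id[unmapped]))
  if (n_unmapped > 0L) {
    message(
      "concordant_targets: skipped ", n_unmapped,
      " compound(s) absent from the drug-target map"
    )
  }
  cp_hit <- !unmapped & compound_screen$r_to_s_call
  cp_pairs <- unique(data.frame(
    target_gene = cp_target[cp_hit],
    cell_line = compound_screen$cell_line[cp_hit],
    stringsAsFactors = FALSE
  ))

  both <- merge(sh_pairs, cp_pairs, by = c("target_gene", "cell_line"))
  if (nrow(both) == 0L) {
    return(data.frame(
      target_gene = character(0), cell_lines_concordant = character(0),
      n_cell_lines = integer(0), stringsAsFactors = FALSE
    ))
  }
  cells <- split(both$cell_line, both$target_gene)
  out <- data.frame(
    target_gene = names(cells),
    cell_lines_concordant = vapply(cells, function(cl) {
      paste(sort(unique(cl)), collapse = ",")
    }, character(1)),
    n_cell_lines = vapply(cells, function(cl) {
      length(unique(cl))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$target_gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-target immune association across cancer types
#'
#' Correlates each candidate target's expression with each immune-class
#' score, within each cancer type (Pearson). This is the association table
#' consumed by [prioritize_targets()].
#'
#' @param expression Genes x samples matrix (e.g. surrogate expression
#'   changes of a pan-cancer cohort).
#' @param class_scores Samples x immune-class matrix from
#'   [immune_class_scores()].
#' @param cancer_type Character vector per sample.
#' @param targets Candidate target genes.
#' @return Data.frame: `target_gene`, `cancer_type`, `immune_class`, `n`,
#'   `estimate` (Pearson r), `p_value`. Targets absent from the gene
#'   space are skipped with a message.
#' @export
target_immune_association <- function(expression, class_scores, cancer_type,
                                      targets) {
  check_finite_matrix(expression, "expression")
  stopifnot(is.matrix(class_scores), nrow(class_scores) == ncol(expression))
  targets <- unique(as.character(targets))
  absent <- setdiff(targets, rownames(expression))
  if (length(absent) > 0L) {
    message(
      "target_immune_association: ", length(absent),
      " candidate(s) absent from the cohort gene space"
    )
    targets <- setdiff(targets, absent)
  }
  rows <- list()
  for (tg in targets) {
    x <- expression[tg, ]
    for (cls in colnames(class_scores)) {
      assoc <- correlate_with_immunity(x, class_scores[, cls], cancer_type)
      if (nrow(assoc) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        target_gene = tg,
        cancer_type = assoc$cancer_type,
        immune_class = cls,
        n = assoc$n,
        estimate = assoc$pearson_r,
        p_value = assoc$pearson_p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      target_gene = character(0), cancer_type = character(0),
      immune_class = character(0), n = integer(0),
      estimate = numeric(0), p_value = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

#' Prioritize concordant targets by immune association
#'
#' A target's expression standing in for its activity, inhibition of the
#' target corresponds to immune activation when the target is
#' significantly *negatively* correlated with the immune-activation class
#' scores. A cancer type counts as negative (positive) for the target when
#' at least one immune class shows a significant negative (positive)
#' Pearson correlation at `alpha`. The target is prioritized when the
#' number of negative cancer types reaches `min_types`.
#'
#' @param candidates Character vector of target genes, or the output of
#'   [concordant_targets()].
#' @param immune_assoc Association table from
#'   [target_immune_association()] (columns `target_gene`, `cancer_type`,
#'   `estimate`, `p_value`).
#' @param min_types Minimum number of significantly negative cancer types
#'   (default `1`).
#' @param alpha Per-correlation significance level (default `0.05`).
#' @return Data.frame: `target_gene`, `n_types_negative`,
#'   `n_types_positive`, `prioritized`, `reason` (`"ok"` or
#'   `"no_association_data"`), sorted by decreasing `n_types_negative`.
#' @export
prioritize_targets <- function(candidates, immune_assoc, min_types = 1,
                               alpha = 0.05) {
  if (is.data.frame(candidates)) {
    candidates <- candidates$target_gene
  }
  candidates <- unique(as.character(candidates))
  stopifnot(is.data.frame(immune_assoc))
  rows <- lapply(candidates, function(tg) {
    a <- immune_assoc[immune_assoc$target_gene == tg, , drop = FALSE]
    if (nrow(a) == 0L) {
      return(data.frame(
        target_gene = tg, n_types_negative = 0L, n_types_positive = 0L,
        prioritized = FALSE, reason = "no_association_data",
        stringsAsFactors = FALSE
      ))
    }
    sig_neg <- a$p_value < alpha & a$estimate < 0
    sig_pos <- a$p_value < alpha & a$estimate > 0
    n_neg <- length(unique(a$cancer_type[sig_neg]))
    n_pos <- length(unique(a$cancer_type[sig_pos]))
    data.frame(
      target_gene = tg, n_types_negative = n_neg, n_types_positive = n_pos,
      prioritized = n_neg >= min_types, reason = "ok",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_types_negative, out$target_gene, method = "radix"), ,
    drop = FALSE
  ]
  rownames(out) <- NULL
  out
}
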