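# Knockdown-efficiency assessment for shRNA perturbation profiles.

#' Assess knockdown efficiency of one shRNA experiment
#'
#' Knockdown efficiency is judged by the target gene's expression change
#' relative to other experiments in the same panel (the experiments
#' sharing a cell line): the knockdown is `efficient` when the target's
#' z-score is negative AND at or below the `q`-th percentile of that
#' gene's values across the panel (linear-interpolation percentile,
#' `stats::quantile` type 7).
#'
#' @param values Named numeric vector: the shRNA experiment's profile.
#' @param target_gene The knocked-down gene.
#' @param panel_values Numeric vector: the target gene's values across
#'   the panel (including this experiment).
#' @param q Percentile bar in `[0, 100]` (default `25`).
#' @return List with `target_gene`, `target_z`, `efficient`, and a
#'   `reason` code (`"ok"`, `"target_absent"`, `"positive_change"`,
#'   `"above_percentile"`).
#' @export
assess_knockdown <- function(values, target_gene, panel_values, q = 25) {
  stopifnot(is.numeric(q), q >= 0, q <= 100)
  if (!target_gene %in% names(values)) {
    return(list(
      target_gene = target_gene, target_z = NA_real_,
      efficient = FALSE, reason = "target_absent"
    ))
  }
  tz <- unname(values[[target_gene]])
  cut <- unname(stats::quantile(panel_values, q / 100, type = 7, names = FALSE))
  reason <- if (tz >= 0) {
    "positive_change"
  } else if (tz > cut) {
    "above_percentile"
  } else {
    "ok"
  }
  list(
    target_gene = target_gene, target_z = tz,
    efficient = reason == "ok", reason = reason
  )
}

#' Assess knockdown efficiency for every shRNA experiment in a compendium
#'
#' For each shRNA experiment the panel is the set of shRNA experiments in
#' the same cell line; see [assess_knockdown()] for the criterion.
#'
#' @param compendium A [perturbation_compendium()].
#' @param q Percentile bar (default `25`).
#' @return Data.frame with one row per shRNA experiment:
#'   `experiment_id`, `target_gene`, `cell_line`, `target_z`,
#'   `efficient`, `reason`.
#' @export
assess_knockdowns <- function(compendium, q = 25) {
  stopifnot(inherits(compendium, "perturbation_compendium"))
  meta <- compendium$meta
  sh <- which(meta$perturbagen_type == "shRNA")
  if (length(sh) == 0L) {
    return(data.frame(
      experiment_id = character(0), target_gene = character(0),
      cell_line = character(0), target_z = numeric(0),
      efficient = logical(0), reason = character(0),
      stringsAsFactors = FALSE
    ))
  }
  genes <- rownames(compendium$values)
  rows <- lapply(sh, function(j) {
    panel <- sh[meta$cell_line[sh] == meta$cell_line[j]]
    target <- meta$target_gene[j]
    if (target %in% genes) {
      panel_values <- compendium$values[target, panel]
      v <- compendium$values[, j]
      names(v) <- genes
      a <- assess_knockdown(v, target, panel_values, q = q)
    } else {
      a <- list(
        target_gene = target, target_z = NA_real_,
        efficient = FALSE, reason = "target_absent"
      )
    }
    data.frame(
      experiment_id = meta$experiment_id[j],
      target_gene = a$target_gene,
      cell_line = meta$cell_line[j],
      target_z = a$target_z,
      efficient = a$efficient,
      reason = a$reason,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
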