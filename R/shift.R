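# Shift-ability scoring of perturbation profiles.

#' Shift ability of a single perturbation profile
#'
#' Ranks the profile's differential-expression values in descending order
#' (stable tie rule) and computes the weighted-KS enrichment scores of the
#' S and R signatures at weight 1. The shift ability is their difference,
#' `ES_S - ES_R`, in `[-2, 2]`: a high positive value means the
#' perturbation suppresses the resistance signature while inducing the
#' sensitivity signature (an R-to-S shift); a negative value indicates the
#' opposite, immune-suppressive shift.
#'
#' @param values Named numeric vector: one experiment's per-gene z-score
#'   profile.
#' @param r_sig,s_sig The R and S signatures as [gene_set()]s or character
#'   vectors of gene ids; both must overlap the profile gene space.
#' @param weight Weighting exponent passed to [weighted_ks_es()].
#' @return A list with `es_r`, `es_s`, `shift_ability = es_s - es_r`,
#'   `r_suppressed` (`es_r < 0`), and `s_induced` (`es_s > 0`).
#' @export
shift_ability <- function(values, r_sig, s_sig, weight = 1) {
  prof <- ranked_profile(values)
  r_sig <- as_one_gene_set(r_sig, "R")
  s_sig <- as_one_gene_set(s_sig, "S")
  es_r <- weighted_ks_es(prof, r_sig, weight = weight)$es
  es_s <- weighted_ks_es(prof, s_sig, weight = weight)$es
  list(
    es_r = es_r,
    es_s = es_s,
    shift_ability = es_s - es_r,
    r_suppressed = es_r < 0,
    s_induced = es_s > 0
  )
}

#' Shift-ability screen over a perturbation compendium
#'
#' Applies [shift_ability()] to every experiment and calls R-to-S shifters
#' at the inclusive threshold (default `0.7`).
#'
#' @param compendium A [perturbation_compendium()] (typically after
#'   [filter_profiles()]).
#' @param r_sig,s_sig The R and S signatures (gene sets or gene id
#'   vectors). A `response_signature` may be given as `r_sig`, in which
#'   case its R and S parts are used and `s_sig` must be missing.
#' @param threshold R-to-S call threshold on the shift ability
#'   (inclusive).
#' @param weight Weighting exponent for the enrichment scores.
#' @return A data.frame of class `shift_screen`, one row per experiment:
#'   metadata columns plus `es_r`, `es_s`, `shift_ability`,
#'   `r_suppressed`, `s_induced`, `r_to_s_call`. The threshold is stored
#'   in the `"threshold"` attribute.
#' @export
shift_screen <- function(compendium, r_sig, s_sig = NULL, threshold = 0.7,
                         weight = 1) {
  stopifnot(inherits(compendium, "perturbation_compendium"))
  if (inherits(r_sig, "response_signature")) {
    stopifnot(is.null(s_sig))
    s_sig <- gene_set("S", s_genes(r_sig))
    r_sig <- gene_set("R", r_genes(r_sig))
  }
  r_sig <- as_one_gene_set(r_sig, "R")
  s_sig <- as_one_gene_set(s_sig, "S")
  genes <- rownames(compendium$values)
  res <- vapply(seq_len(ncol(compendium$values)), function(j) {
    v <- compendium$values[, j]
    names(v) <- genes
    s <- shift_ability(v, r_sig, s_sig, weight = weight)
    c(s$es_r, s$es_s, s$shift_ability)
  }, numeric(3))
  out <- cbind(
    compendium$meta,
    data.frame(
      es_r = res[1L, ],
      es_s = res[2L, ],
      shift_ability = res[3L, ],
      stringsAsFactors = FALSE
    )
  )
  out$r_suppressed <- out$es_r < 0
  out$s_induced <- out$es_s > 0
  out$r_to_s_call <- call_r_to_s(out$shift_ability, threshold)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("shift_screen", "data.frame")
  out
}

#' R-to-S shift call
#'
#' An experiment is called an R-to-S shifter when its shift ability meets
#' the threshold (inclusive), `shift_ability >= threshold`.
#'
#' @param x Numeric shift abilities, a [shift_ability()] result, or a
#'   `shift_screen` row set.
#' @param threshold Call threshold (default `0.7`).
#' @return Logical vector of calls.
#' @export
call_r_to_s <- function(x, threshold = 0.7) {
  if (is.list(x) && !is.null(x$shift_ability)) {
    x <- x$shift_ability
  }
  stopifnot(is.numeric(x), is.numeric(threshold))
  x >= threshold
}

#' @export
print.shift_screen <- function(x, ...) {
  cat("Shift-ability screen:", nrow(x), "experiments, threshold",
    attr(x, "threshold"), "\n")
  cat("  R-to-S calls:", sum(x$r_to_s_call), "(",
    signif(100 * mean(x$r_to_s_call), 3), "% )\n")
  cat("  shift ability: median", signif(stats::median(x$shift_ability), 3),
    ", range [", signif(min(x$shift_ability), 3), ",",
    signif(max(x$shift_ability), 3), "]\n")
  invisible(x)
}

#' @export
summary.shift_screen <- function(object, ...) {
  print(object)
  by_type <- split(object$r_to_s_call, object$perturbagen_type)
  for (ty in names(by_type)) {
    cat("  ", ty, ": ", sum(by_type[[ty]]), "/", length(by_type[[ty]]),
      " called\n",
      sep = ""
    )
  }
  invisible(object)
}

#' Aggregate a shift screen by perturbagen and cell line
#'
#' Summarizes experiments of the same perturbagen in the same cell line:
#' mean shift ability, fraction of experiments called R-to-S, and whether
#' any experiment was called.
#'
#' @param screen A `shift_screen` data.frame.
#' @param threshold Call threshold; defaults to the screen's own.
#' @return Data.frame with one row per perturbagen x cell line:
#'   `perturbagen_id`, `perturbagen_type`, `target_gene`, `cell_line`,
#'   `n_experiments`, `mean_shift`, `frac_called`, `any_call`, sorted by
#'   perturbagen then cell line.
#' @export
aggregate_perturbagen <- function(screen,
                                  threshold = attr(screen, "threshold")) {
  stopifnot(is.data.frame(screen))
  if (is.null(threshold)) {
    threshold <- 0.7
  }
  key <- paste(screen$perturbagen_id, screen$cell_line, sep = "\r")
  idx <- split(seq_len(nrow(screen)), key)
  rows <- lapply(idx, function(i) {
    called <- screen$shift_ability[i] >= threshold
    data.frame(
      perturbagen_id = screen$perturbagen_id[i[1L]],
      perturbagen_type = screen$perturbagen_type[i[1L]],
      target_gene = screen$target_gene[i[1L]],
      cell_line = screen$cell_line[i[1L]],
      n_experiments = length(i),
      mean_shift = mean(screen$shift_ability[i]),
      frac_called = mean(called),
      any_call = any(called),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$perturbagen_id, out$cell_line, method = "radix"), ,
    drop = FALSE
  ]
  rownames(out) <- NULL
  out
}
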