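# Pan-cancer cohort associations: immune class scores, correlation with
# immunity, and survival.

#' Pan-cancer cohort container
#'
#' @param expression Genes x samples matrix (log scale).
#' @param samples Data.frame with one row per sample: `sample_id`,
#'   `cancer_type`, and optionally `pfi_time` (nonnegative) and
#'   `pfi_event` (0/1); the survival endpoint column is taken as given
#'   (progression-free interval or overall survival).
#' @param infiltration Optional samples x cell-type matrix of precomputed
#'   immune-infiltration fractions (consumed as input, never estimated
#'   here).
#' @return An object of class `pancancer_cohort`.
#' @export
pancancer_cohort <- function(expression, samples, infiltration = NULL) {
  check_finite_matrix(expression, "expression")
  stopifnot(is.data.frame(samples))
  required <- c("sample_id", "cancer_type")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0L) {
    stop("samples lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!identical(as.character(samples$sample_id), colnames(expression))) {
    stop("samples$sample_id must match colnames(expression) in order",
      call. = FALSE
    )
  }
  if (!is.null(samples$pfi_time) && any(samples$pfi_time < 0)) {
    stop("pfi_time must be nonnegative", call. = FALSE)
  }
  if (!is.null(infiltration)) {
    stopifnot(is.matrix(infiltration), nrow(infiltration) == ncol(expression))
    if (any(infiltration < 0)) {
      stop("infiltration fractions must be nonnegative", call. = FALSE)
    }
  }
  structure(
    list(expression = expression, samples = samples,
      infiltration = infiltration),
    class = "pancancer_cohort"
  )
}

#' @export
print.pancancer_cohort <- function(x, ...) {
  cat("Pan-cancer cohort:", nrow(x$expression), "genes x",
    ncol(x$expression), "samples,",
    length(unique(x$samples$cancer_type)), "cancer types\n")
  invisible(x)
}

#' Per-sample immune class scores
#'
#' Scores each immune-response signature in each sample by [ssgsea_score()]
#' and averages the signature scores within each immunity class. Each
#' sample is ranked once and all signatures are scored against that
#' ranking. Signatures with no overlap in the cohort gene space are
#' dropped with a warning.
#'
#' @param expression Genes x samples matrix (or a [pancancer_cohort()]).
#' @param sets Immune-response signatures (list of [gene_set()]s or named
#'   list of gene id vectors).
#' @param classes Named character vector mapping signature id to immunity
#'   class; defaults to one class per signature.
#' @param exponent ssGSEA rank-weighting exponent (default `0.25`).
#' @return Samples x classes numeric matrix of class-averaged scores,
#'   with the per-signature score matrix in attribute `"set_scores"`.
#' @export
immune_class_scores <- function(expression, sets, classes = NULL,
                                exponent = 0.25) {
  if (inherits(expression, "pancancer_cohort")) {
    expression <- expression$expression
  }
  check_finite_matrix(expression, "expression")
  sets <- as_gene_sets(sets)
  if (is.null(classes)) {
    classes <- stats::setNames(names(sets), names(sets))
  }
  stopifnot(all(names(sets) %in% names(classes)))
  genes <- rownames(expression)
  overlaps <- lapply(sets, function(s) which(genes %in% s$members))
  scorable <- vapply(overlaps, length, integer(1)) > 0L
  if (!all(scorable)) {
    warning(sum(!scorable), " signature(s) with no overlap were dropped",
      call. = FALSE
    )
    sets <- sets[scorable]
    overlaps <- overlaps[scorable]
  }
  if (length(sets) == 0L) {
    stop("no scorable immune signature", call. = FALSE)
  }
  member_idx <- overlaps
  set_scores <- matrix(
    NA_real_, ncol(expression), length(sets),
    dimnames = list(colnames(expression), names(sets))
  )
  for (j in seq_len(ncol(expression))) {
    v <- expression[, j]
    ord <- stable_order(v, genes)
    pos_of_gene <- integer(length(genes))
    pos_of_gene[ord] <- seq_along(ord)
    for (k in seq_along(sets)) {
      hit <- logical(length(genes))
      hit[pos_of_gene[member_idx[[k]]]] <- TRUE
      set_scores[j, k] <- ssgsea_from_order(hit, exponent)
    }
  }
  cls <- classes[names(sets)]
  class_names <- sort(unique(cls), method = "radix")
  out <- vapply(class_names, function(cn) {
    rowMeans(set_scores[, cls == cn, drop = FALSE])
  }, numeric(nrow(set_scores)))
  out <- matrix(out,
    nrow = nrow(set_scores),
    dimnames = list(rownames(set_scores), class_names)
  )
  attr(out, "set_scores") <- set_scores
  out
}

#' Correlate a per-sample statistic with immunity, by cancer type
#'
#' Both Pearson and Spearman correlations are computed within each cancer
#' type (to avoid relying on the linearity assumption alone), with
#' significance flagged at `alpha`. Types with fewer than 3 samples or a
#' constant input are excluded with a reason.
#'
#' @param x Per-sample statistic (gene expression or a signature score).
#' @param y Per-sample immune score or infiltration estimate.
#' @param cancer_type Character vector per sample; `NULL` treats the whole
#'   input as one group.
#' @param alpha Significance level (default `0.05`).
#' @return Data.frame: `cancer_type`, `n`, `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`, `significant` (Pearson p < alpha),
#'   `direction`. Excluded types are reported in the `"excluded"`
#'   attribute with their reason.
#' @export
correlate_with_immunity <- function(x, y, cancer_type = NULL, alpha = 0.05) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (is.null(cancer_type)) {
    cancer_type <- rep("all", length(x))
  }
  types <- sort(unique(as.character(cancer_type)), method = "radix")
  rows <- list()
  excluded <- list()
  for (ty in types) {
    i <- cancer_type == ty
    if (sum(i) < 3L) {
      excluded[[ty]] <- "fewer than 3 samples"
      next
    }
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) {
      excluded[[ty]] <- "constant input; correlation undefined"
      next
    }
    pe <- stats::cor.test(x[i], y[i], method = "pearson")
    sp <- suppressWarnings(
      stats::cor.test(x[i], y[i], method = "spearman")
    )
    rows[[ty]] <- data.frame(
      cancer_type = ty,
      n = sum(i),
      pearson_r = unname(pe$estimate),
      pearson_p = pe$p.value,
      spearman_rho = unname(sp$estimate),
      spearman_p = sp$p.value,
      significant = pe$p.value < alpha,
      direction = ifelse(pe$estimate > 0, "positive", "negative"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      cancer_type = character(0), n = integer(0),
      pearson_r = numeric(0), pearson_p = numeric(0),
      spearman_rho = numeric(0), spearman_p = numeric(0),
      significant = logical(0), direction = character(0),
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Single-covariate Cox proportional-hazards association
#'
#' Fits `Surv(time, event) ~ score` by partial likelihood with the Efron
#' tie approximation and reports the hazard ratio per unit score and its
#' Wald p-value. Degenerate inputs (no events, constant score,
#' non-convergence) produce a flagged result with `hazard_ratio = NA`
#' rather than a fabricated estimate.
#'
#' @param score Per-sample numeric score (e.g. the average R-signature
#'   expression change).
#' @param time Nonnegative follow-up times (e.g. progression-free
#'   interval).
#' @param event Event indicator, 0/1.
#' @return List with `hazard_ratio`, `log_hr`, `se`, `p_value`, `n`,
#'   `n_events`, `converged`, `reason`.
#' @export
survival_association <- function(score, time, event) {
  stopifnot(
    is.numeric(score), is.numeric(time), length(score) == length(time),
    length(event) == length(time), all(event %in% c(0, 1)),
    all(time >= 0)
  )
  flagged <- function(reason) {
    list(
      hazard_ratio = NA_real_, log_hr = NA_real_, se = NA_real_,
      p_value = NA_real_, n = length(score), n_events = sum(event),
      converged = FALSE, reason = reason
    )
  }
  if (sum(event) < 1) {
    return(flagged("no events"))
  }
  if (stats::sd(score) == 0) {
    return(flagged("constant score; coefficient undefined"))
  }
  ok <- TRUE
  fit <- withCallingHandlers(
    tryCatch(
      survival::coxph(survival::Surv(time, event) ~ score,
        ties = "efron"
      ),
      error = function(e) NULL
    ),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w))) {
        ok <<- FALSE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (is.null(fit) || !ok || !is.finite(stats::coef(fit)[1L])) {
    return(flagged("fit did not converge"))
  }
  beta <- unname(stats::coef(fit)[1L])
  se <- sqrt(unname(stats::vcov(fit)[1L, 1L]))
  list(
    hazard_ratio = exp(beta), log_hr = beta, se = se,
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    n = length(score), n_events = sum(event),
    converged = TRUE, reason = "ok"
  )
}

#' Log-rank test between the top and bottom score tertiles
#'
#' Samples are split into three groups of as-even-as-possible size by
#' score order (group sizes differ by at most one; remainder samples go
#' to the lower groups; tied scores are assigned in input order, so a tie
#' spanning a boundary is placed in the lower tertile first). The
#' log-rank statistic compares only the highest and lowest tertiles. When
#' both groups carry zero events the statistic is 0 with p = 1.
#'
#' @param score Per-sample numeric score.
#' @param time Nonnegative follow-up times.
#' @param event Event indicator, 0/1.
#' @return List with `chi_square`, `p_value`, `n_low`, `n_mid`, `n_high`.
#' @export
tertile_logrank <- function(score, time, event) {
  n <- length(score)
  stopifnot(
    n >= 6L, length(time) == n, length(event) == n,
    all(event %in% c(0, 1)), all(time >= 0)
  )
  ord <- order(score, seq_len(n), method = "radix")
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, 0L) # remainder to the lower groups
  grp <- integer(n)
  grp[ord] <- rep(1:3, times = sizes)
  sel <- grp != 2L
  if (sum(event[sel]) == 0) {
    return(list(
      chi_square = 0, p_value = 1,
      n_low = sizes[1L], n_mid = sizes[2L], n_high = sizes[3L]
    ))
  }
  sd_fit <- survival::survdiff(
    survival::Surv(time[sel], event[sel]) ~ grp[sel]
  )
  list(
    chi_square = unname(sd_fit$chisq),
    p_value = stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE),
    n_low = sizes[1L], n_mid = sizes[2L], n_high = sizes[3L]
  )
}
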