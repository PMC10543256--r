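#' Paired pre-/on-treatment cohort
#'
#' Container for a paired immunotherapy cohort: a pre-treatment and an
#' on-treatment expression matrix over the same genes and patients, plus a
#' responder/non-responder label per patient. Expression may be on the
#' linear or log2 scale; the scale must be declared because treatment-
#' induced changes are defined on the linear scale.
#'
#' @param pre,post Genes x patients numeric matrices with identical
#'   dimnames.
#' @param response Character vector per patient: `"R"` (responder) or
#'   `"NR"` (non-responder); both classes must be present.
#' @param scale Declared expression scale, `"log2"` or `"linear"`.
#' @return An object of class `paired_cohort`.
#' @export
paired_cohort <- function(pre, post, response, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  check_finite_matrix(pre, "pre")
  check_finite_matrix(post, "post")
  if (!identical(dim(pre), dim(post)) ||
    !identical(dimnames(pre), dimnames(post))) {
    stop("pre and post must share identical gene and patient ordering",
      call. = FALSE
    )
  }
  response <- as.character(response)
  if (length(response) != ncol(pre)) {
    stop("one response label per patient is required", call. = FALSE)
  }
  if (!all(response %in% c("R", "NR"))) {
    stop('response labels must be "R" or "NR"', call. = FALSE)
  }
  if (length(unique(response)) < 2L) {
    stop("both response classes must be present", call. = FALSE)
  }
  if (scale == "linear" && (any(pre < 0) || any(post < 0))) {
    stop("linear-scale expression must be non-negative", call. = FALSE)
  }
  structure(
    list(
      pre = pre, post = post,
      patient_ids = colnames(pre), response = response, scale = scale
    ),
    class = "paired_cohort"
  )
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat("Paired cohort:", nrow(x$pre), "genes x", ncol(x$pre), "patients (",
    sum(x$response == "R"), "R /", sum(x$response == "NR"), "NR ),",
    x$scale, "scale\n"
  )
  invisible(x)
}

#' Treatment-induced expression changes of a paired cohort
#'
#' The treatment-induced change of a gene in a patient is the
#' log2-transformed fold change between on-treatment and pre-treatment
#' expression, computed on the linear scale with a pseudocount:
#' `log2((post + pseudocount) / (pre + pseudocount))`. Cohorts declared on
#' the log2 scale are exponentiated first.
#'
#' @param cohort A [paired_cohort()].
#' @param pseudocount Nonnegative value added to both numerator and
#'   denominator on the linear scale (default `1`).
#' @return Genes x patients matrix of log2 fold changes with attribute
#'   `provenance = "paired"`.
#' @export
compute_induced_changes <- function(cohort, pseudocount = 1) {
  stopifnot(inherits(cohort, "paired_cohort"))
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L,
    pseudocount >= 0)
  if (cohort$scale == "log2") {
    pre_lin <- 2^cohort$pre
    post_lin <- 2^cohort$post
  } else {
    pre_lin <- cohort$pre
    post_lin <- cohort$post
  }
  if (pseudocount == 0 && any(pre_lin == 0 | post_lin == 0)) {
    stop("zero expression with pseudocount 0; supply a positive pseudocount",
      call. = FALSE
    )
  }
  changes <- log2((post_lin + pseudocount) / (pre_lin + pseudocount))
  attr(changes, "provenance") <- "paired"
  changes
}

#' Surrogate expression changes for unpaired cohorts
#'
#' When pre/on pairs are unavailable, relative expression differing from
#' the cohort population baseline stands in for the treatment-induced
#' change: each gene is centered on its cohort baseline (mean by default,
#' median by option), in log space. Every output row is mean-zero (exactly,
#' for the mean baseline).
#'
#' @param expression Genes x samples numeric matrix (log scale).
#' @param baseline Population baseline statistic, `"mean"` or `"median"`.
#' @return Genes x samples matrix with attribute `provenance =
#'   "surrogate"`.
#' @export
surrogate_changes <- function(expression, baseline = c("mean", "median")) {
  baseline <- match.arg(baseline)
  check_finite_matrix(expression, "expression")
  if (ncol(expression) < 2L) {
    stop("surrogate changes need at least 2 samples", call. = FALSE)
  }
  center <- if (baseline == "mean") {
    rowMeans(expression)
  } else {
    apply(expression, 1L, stats::median)
  }
  out <- expression - center
  attr(out, "provenance") <- "surrogate"
  out
}
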