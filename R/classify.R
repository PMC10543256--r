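# Response classification: PCA response score and ROC/AUC evaluation.

#' First-principal-component response score
#'
#' Projects samples onto the first principal axis of the gene-centered
#' matrix (genes are centered, not scaled). Because a principal-component
#' sign is arbitrary, the orientation is fixed deterministically: when a
#' response signature is supplied the score is flipped, if needed, to
#' correlate non-negatively with the combined signature score; otherwise
#' the loading vector's largest-magnitude entry is made positive.
#'
#' @param x Genes x samples numeric matrix (expression or induced
#'   changes); at least 2 genes and 2 samples.
#' @param signature Optional `response_signature` used only to orient the
#'   score.
#' @return Named numeric vector of per-sample scores, with the loading
#'   vector in attribute `"loadings"`.
#' @export
pca_response_score <- function(x, signature = NULL) {
  check_finite_matrix(x, "x")
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("PCA response score needs >= 2 genes and >= 2 samples",
      call. = FALSE
    )
  }
  centered <- x - rowMeans(x)
  if (all(centered == 0)) {
    stop("matrix has zero variance; no principal axis exists", call. = FALSE)
  }
  pc <- stats::prcomp(t(centered), center = FALSE, scale. = FALSE)
  score <- pc$x[, 1L]
  loading <- pc$rotation[, 1L]
  flip <- FALSE
  if (!is.null(signature)) {
    combined <- signature_score(x, signature, "combined")
    r <- suppressWarnings(stats::cor(score, combined))
    if (is.finite(r) && r != 0) {
      flip <- r < 0
    } else {
      flip <- loading[which.max(abs(loading))] < 0
    }
  } else {
    flip <- loading[which.max(abs(loading))] < 0
  }
  if (flip) {
    score <- -score
    loading <- -loading
  }
  names(score) <- colnames(x)
  attr(score, "loadings") <- loading
  score
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the fraction of positive/negative pairs ranked
#' concordantly by the score, with tied pairs counted one half (the
#' Mann-Whitney formulation). The ROC point sequence is attached as the
#' `"points"` attribute.
#'
#' @param scores Numeric classification scores (higher = more
#'   positive-like).
#' @param labels Class labels; compared against `positive`.
#' @param positive The label counted as the positive class (default `TRUE`
#'   for logical labels, `"R"` otherwise).
#' @return AUC in `[0, 1]`, with attribute `"points"`: a data.frame of
#'   (`fpr`, `tpr`) stepping through the score thresholds.
#' @export
roc_auc <- function(scores, labels,
                    positive = if (is.logical(labels)) TRUE else "R") {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute an ROC curve",
      call. = FALSE
    )
  }
  r <- rank(scores) # midranks: tied pairs count 1/2
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  grp <- cumsum(!duplicated(scores[ord])) # group tied scores
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  last <- !duplicated(grp, fromLast = TRUE)
  points <- data.frame(
    fpr = c(0, fp[last] / n_neg),
    tpr = c(0, tp[last] / n_pos)
  )
  attr(auc, "points") <- points
  auc
}
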