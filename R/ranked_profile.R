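#' Ranked gene profile
#'
#' Builds the substrate of all enrichment computations: a gene list ranked by
#' a real-valued statistic (for perturbation profiles, the level-5-style
#' z-scores; for consensus cluster signatures, the median consensus
#' expression change). Genes are sorted by score in non-increasing order with
#' a stable, locale-independent tie rule (score descending, then gene id
#' ascending), so the ranking is bit-reproducible.
#'
#' @param scores Numeric vector of finite ranking statistics, named by gene
#'   id unless `gene_ids` is given.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   score.
#' @return An object of class `ranked_profile` with elements `gene_ids` and
#'   `scores`, ordered non-increasingly by score.
#' @examples
#' ranked_profile(c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1))
#' @export
ranked_profile <- function(scores, gene_ids = names(scores)) {
  if (inherits(scores, "ranked_profile")) {
    return(scores)
  }
  if (is.null(gene_ids)) {
    stop("scores must be named by gene id or gene_ids supplied", call. = FALSE)
  }
  scores <- as.numeric(scores)
  gene_ids <- as.character(gene_ids)
  if (length(scores) != length(gene_ids)) {
    stop("scores and gene_ids differ in length", call. = FALSE)
  }
  if (length(scores) < 2L) {
    stop("a ranked profile needs at least 2 genes", call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("ranking scores must all be finite", call. = FALSE)
  }
  if (anyDuplicated(gene_ids) || anyNA(gene_ids)) {
    stop("gene ids must be unique and non-missing", call. = FALSE)
  }
  ord <- stable_order(scores, gene_ids)
  structure(
    list(gene_ids = gene_ids[ord], scores = scores[ord]),
    class = "ranked_profile"
  )
}

#' @export
print.ranked_profile <- function(x, ...) {
  n <- length(x$gene_ids)
  cat("Ranked profile of", n, "genes\n")
  show <- seq_len(min(5L, n))
  cat("  top:   ", paste0(x$gene_ids[show], " (", signif(x$scores[show], 4), ")",
    collapse = ", "
  ), "\n")
  show <- seq.int(max(1L, n - 4L), n)
  cat("  bottom:", paste0(x$gene_ids[show], " (", signif(x$scores[show], 4), ")",
    collapse = ", "
  ), "\n")
  invisible(x)
}

#' @export
length.ranked_profile <- function(x) length(x$gene_ids)
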