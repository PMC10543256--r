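# R/S response-signature derivation from treatment-induced expression
# changes.

# Vectorized two-sided Wilcoxon rank-sum p-values per row of `x` between
# column groups idx1 and idx2. Exact null distribution (stats::pwilcox)
# when both groups have <= `exact_max` observations and the row is
# tie-free; otherwise the normal approximation with tie correction and
# continuity correction, matching stats::wilcox.test(correct = TRUE).
# Rows that are constant across all columns get p = 1.
ranksum_rows <- function(x, idx1, idx2, exact_max = 10L) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  n <- n1 + n2
  sub <- x[, c(idx1, idx2), drop = FALSE]
  r <- t(apply(sub, 1L, rank))
  u <- rowSums(r[, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2
  has_ties <- apply(sub, 1L, anyDuplicated) > 0L
  p <- rep(NA_real_, nrow(sub))

  exact <- n1 <= exact_max && n2 <= exact_max
  if (exact && any(!has_ties)) {
    ue <- u[!has_ties]
    p_lo <- stats::pwilcox(ue, n1, n2)
    p_hi <- 1 - stats::pwilcox(ue - 1, n1, n2)
    p[!has_ties] <- pmin(1, 2 * pmin(p_lo, p_hi))
  }
  approx_idx <- if (exact) which(has_ties) else seq_len(nrow(sub))
  if (length(approx_idx) > 0L) {
    tie_term <- numeric(length(approx_idx))
    needs_tt <- has_ties[approx_idx]
    if (any(needs_tt)) {
      tie_term[needs_tt] <- vapply(approx_idx[needs_tt], function(i) {
        tt <- table(sub[i, ])
        sum(tt^3 - tt)
      }, numeric(1))
    }
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- u[approx_idx] - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    pa <- pmin(1, 2 * stats::pnorm(-abs(z)))
    pa[sigma2 <= 0] <- 1 # constant row: no evidence either way
    p[approx_idx] <- pa
  }
  p
}

#' Derive anti-PD-1 R and S response signatures
#'
#' Per gene, a two-sided Wilcoxon rank-sum test compares treatment-induced
#' expression changes between responders and non-responders. Genes with
#' `p < alpha` are assigned to the sensitivity (S) signature when the
#' responder median change exceeds the non-responder median change, and to
#' the resistance (R) signature otherwise. Significant genes whose class
#' medians are exactly equal have no defensible direction; they are
#' excluded and recorded in the `excluded_ties` attribute-equivalent field.
#'
#' The test is exact (via the Mann-Whitney null distribution) when both
#' classes have at most 10 patients and the gene is tie-free; otherwise the
#' normal approximation with tie and continuity correction is used. By
#' default p-values are used raw at `alpha = 0.05`; Benjamini-Hochberg
#' adjustment is available via `adjust = "BH"`.
#'
#' @param changes Genes x patients matrix of induced (or surrogate)
#'   expression changes, e.g. from [compute_induced_changes()].
#' @param response Character vector per patient, `"R"` (responder) or
#'   `"NR"`.
#' @param alpha Significance cutoff on the (possibly adjusted) p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `response_signature`: a list with `table`
#'   (data.frame: `gene`, `direction` in `{S, R}`, `p_value`,
#'   `median_diff` = responder median minus non-responder median), `alpha`,
#'   `adjust`, `n_genes_tested`, and `excluded_ties`.
#' @seealso [r_genes()], [s_genes()], [signature_score()]
#' @export
derive_signatures <- function(changes, response, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  check_finite_matrix(changes, "changes")
  response <- as.character(response)
  stopifnot(length(response) == ncol(changes))
  idx_r <- which(response == "R")
  idx_nr <- which(response == "NR")
  if (length(idx_r) < 2L || length(idx_nr) < 2L) {
    stop("each response class needs at least 2 patients", call. = FALSE)
  }
  genes <- rownames(changes)
  if (is.null(genes)) {
    genes <- paste0("gene", seq_len(nrow(changes)))
  }
  p <- ranksum_rows(changes, idx_r, idx_nr)
  if (adjust == "BH") {
    p <- stats::p.adjust(p, method = "BH")
  }
  med_diff <- apply(changes[, idx_r, drop = FALSE], 1L, stats::median) -
    apply(changes[, idx_nr, drop = FALSE], 1L, stats::median)
  sig <- p < alpha
  ties <- sig & med_diff == 0
  keep <- sig & !ties
  tab <- data.frame(
    gene = genes[keep],
    direction = ifelse(med_diff[keep] > 0, "S", "R"),
    p_value = p[keep],
    median_diff = med_diff[keep],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  tab <- tab[order(tab$p_value, tab$gene, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(
      table = tab,
      alpha = alpha,
      adjust = adjust,
      n_genes_tested = nrow(changes),
      excluded_ties = genes[ties]
    ),
    class = "response_signature"
  )
}

#' Resistance-signature genes of a response signature
#' @param signature A `response_signature` (or a list with an `r`/`s`
#'   element pair, or `gene_set`s).
#' @return Character vector of gene ids.
#' @export
r_genes <- function(signature) {
  signature_part(signature, "R")
}

#' Sensitivity-signature genes of a response signature
#' @inheritParams r_genes
#' @return Character vector of gene ids.
#' @export
s_genes <- function(signature) {
  signature_part(signature, "S")
}

signature_part <- function(signature, part) {
  if (inherits(signature, "response_signature")) {
    return(signature$table$gene[signature$table$direction == part])
  }
  if (is.list(signature)) {
    nm <- tolower(names(signature))
    el <- signature[[match(tolower(part), nm)]]
    if (inherits(el, "gene_set")) {
      return(el$members)
    }
    return(as.character(el))
  }
  stop("cannot extract ", part, " genes from class ", class(signature)[1],
    call. = FALSE
  )
}

#' @export
print.response_signature <- function(x, ...) {
  cat("Anti-PD-1 response signature (alpha = ", x$alpha,
    if (x$adjust != "none") paste0(", ", x$adjust, "-adjusted"), ")\n",
    sep = ""
  )
  cat("  R (resistance) genes: ", sum(x$table$direction == "R"), "\n", sep = "")
  cat("  S (sensitivity) genes:", sum(x$table$direction == "S"), "\n")
  cat("  tested:", x$n_genes_tested, "genes;",
    length(x$excluded_ties), "significant gene(s) excluded for tied medians\n")
  invisible(x)
}

#' @export
summary.response_signature <- function(object, ...) {
  print(object)
  tab <- object$table
  if (nrow(tab) > 0) {
    cat("Top genes by p-value:\n")
    print(utils::head(tab, 10), row.names = FALSE)
  }
  invisible(object)
}

#' Average signature expression-change score per sample
#'
#' The per-sample mean change over the signature genes present in the
#' matrix: part `"S"` (or `"R"`) averages the S (R) genes, and
#' `"combined"` is the S mean minus the R mean, so that larger values
#' indicate a sensitivity-like induced profile.
#'
#' @param changes Genes x samples matrix of (induced or surrogate)
#'   expression changes.
#' @param signature A `response_signature` or a list with `r` and `s` gene
#'   vectors.
#' @param part `"combined"` (default), `"S"`, or `"R"`.
#' @return Named numeric vector, one score per sample.
#' @export
signature_score <- function(changes, signature,
                            part = c("combined", "S", "R")) {
  part <- match.arg(part)
  check_finite_matrix(changes, "changes")
  mean_part <- function(genes, label) {
    present <- intersect(genes, rownames(changes))
    if (length(present) == 0L) {
      stop("no ", label, " signature gene is present in the matrix (",
        length(genes), " missing); cannot score",
        call. = FALSE
      )
    }
    colMeans(changes[present, , drop = FALSE])
  }
  switch(part,
    S = mean_part(s_genes(signature), "S"),
    R = mean_part(r_genes(signature), "R"),
    combined = mean_part(s_genes(signature), "S") -
      mean_part(r_genes(signature), "R")
  )
}
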