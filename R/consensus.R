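# Consensus expression-change signatures and mechanism clustering of
# R-to-S shifting compounds.

#' Expression indicators of perturbation profiles
#'
#' Thresholds each level-5-style z-score at +/-1 (strict): values above 1
#' become `+1`, below -1 become `-1`, otherwise `0`.
#'
#' @param values Genes x experiments numeric matrix of treatment-induced
#'   expression (z-scores).
#' @param compound Character vector per experiment: the compound each
#'   experiment belongs to.
#' @return An object of class `indicator_matrix`: list with `values`
#'   (integer matrix in `{-1, 0, 1}`) and `compound`.
#' @export
make_indicators <- function(values, compound) {
  check_finite_matrix(values, "values")
  compound <- as.character(compound)
  stopifnot(length(compound) == ncol(values))
  ind <- matrix(0L, nrow(values), ncol(values), dimnames = dimnames(values))
  ind[values > 1] <- 1L
  ind[values < -1] <- -1L
  structure(list(values = ind, compound = compound),
    class = "indicator_matrix"
  )
}

#' Per-compound consensus expression-change vectors
#'
#' The consensus expression change of a gene for a compound is the sum of
#' its expression indicators across the compound's experiments.
#'
#' @param indicators An [make_indicators()] result.
#' @return Genes x compounds integer matrix, columns ordered by compound
#'   id, with the per-compound experiment counts in attribute
#'   `"n_experiments"`.
#' @export
consensus_vectors <- function(indicators) {
  stopifnot(inherits(indicators, "indicator_matrix"))
  compounds <- sort(unique(indicators$compound), method = "radix")
  out <- vapply(compounds, function(cp) {
    cols <- indicators$compound == cp
    rowSums(indicators$values[, cols, drop = FALSE])
  }, numeric(nrow(indicators$values)))
  out <- as.matrix(out)
  rownames(out) <- rownames(indicators$values)
  n_exp <- vapply(compounds, function(cp) {
    sum(indicators$compound == cp)
  }, integer(1))
  attr(out, "n_experiments") <- n_exp
  out
}

#' Cluster compounds by consensus expression-change correlation
#'
#' Pairwise compound distance is one minus the Pearson correlation of
#' their consensus vectors; agglomeration uses the Ward criterion applied
#' directly to that precomputed distance (`hclust` method `"ward.D"`).
#' Flat clusters are obtained either at an absolute dendrogram height
#' (`cutoff`) or as a fixed number of clusters (`k`, the default with
#' `k = 2`). Because merge heights under a non-Euclidean 1 - r distance
#' depend on this convention, an absolute cutoff is only meaningful
#' relative to it, which is why `k` is the tested default. Compounds are
#' canonically ordered by id before clustering so the result is invariant
#' to input order; constant (zero-variance) consensus vectors get
#' correlation 0 (distance 1) with a warning.
#'
#' @param vectors Genes x compounds consensus matrix from
#'   [consensus_vectors()].
#' @param cutoff Optional absolute merge-height cutoff.
#' @param k Number of flat clusters when `cutoff` is `NULL` (default
#'   `2`).
#' @return An object of class `compound_clustering`: list with `hclust`
#'   (the linkage), `labels` (named integer cluster labels), `distance`
#'   (`"1-pearson"`), `cutoff`, `k`.
#' @export
cluster_compounds <- function(vectors, cutoff = NULL, k = 2) {
  stopifnot(is.matrix(vectors))
  if (ncol(vectors) < 2L) {
    stop("clustering needs at least 2 compounds", call. = FALSE)
  }
  vectors <- vectors[, order(colnames(vectors), method = "radix"),
    drop = FALSE
  ]
  sds <- apply(vectors, 2L, stats::sd)
  cormat <- suppressWarnings(stats::cor(vectors))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant consensus vector(s); their ",
      "correlations are defined as 0",
      call. = FALSE
    )
    cormat[!is.finite(cormat)] <- 0
    diag(cormat) <- 1
  }
  d <- stats::as.dist(1 - cormat)
  hc <- stats::hclust(d, method = "ward.D")
  if (is.unsorted(hc$height)) {
    warning("non-monotone merge heights in the Ward agglomeration",
      call. = FALSE
    )
  }
  labels <- if (!is.null(cutoff)) {
    stats::cutree(hc, h = cutoff)
  } else {
    stats::cutree(hc, k = k)
  }
  structure(
    list(
      hclust = hc, labels = labels, distance = "1-pearson",
      cutoff = cutoff, k = if (is.null(cutoff)) k else NA_integer_
    ),
    class = "compound_clustering"
  )
}

#' @export
print.compound_clustering <- function(x, ...) {
  tab <- table(x$labels)
  cat("Compound clustering (Ward on 1 - Pearson):",
    length(x$labels), "compounds in", length(tab), "clusters\n")
  cat("  sizes:", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  if (!is.null(x$cutoff)) {
    cat("  cut at height", x$cutoff, "\n")
  } else {
    cat("  cut at k =", x$k, "\n")
  }
  invisible(x)
}

#' Consensus signature of a compound cluster
#'
#' The per-gene median of the cluster members' consensus expression
#' changes, ranked descending (stable tie rule). Medians of even-sized
#' clusters are midpoints of the two central values.
#'
#' @param vectors Genes x compounds consensus matrix restricted to one
#'   cluster's members (>= 1 column).
#' @param cluster_id Optional identifier stored with the signature.
#' @return An object of class `cluster_signature`: list with
#'   `cluster_id`, `medians` (named, in gene-universe order), and
#'   `profile` (a [ranked_profile()] over the full gene universe).
#' @export
cluster_signature <- function(vectors, cluster_id = "cluster") {
  stopifnot(is.matrix(vectors), ncol(vectors) >= 1L)
  med <- apply(vectors, 1L, stats::median)
  structure(
    list(
      cluster_id = as.character(cluster_id),
      medians = med,
      profile = ranked_profile(med, rownames(vectors))
    ),
    class = "cluster_signature"
  )
}

#' Annotate a cluster signature by preranked GSEA
#'
#' Runs [prerank_gsea()] of a gene set collection (e.g. GO terms) against
#' the cluster's descending-ranked consensus signature, and orders the
#' results by decreasing NES (ES when no permutations are run).
#'
#' @param signature A [cluster_signature()] (or a `ranked_profile`).
#' @param go_sets Gene set collection (list of [gene_set()]s or named
#'   list).
#' @param n_perm Number of permutations (default `1000`).
#' @param seed Seed for the permutation null.
#' @param weight Weighting exponent.
#' @return A `gsea_result` data.frame sorted by decreasing NES.
#' @export
annotate_cluster <- function(signature, go_sets, n_perm = 1000, seed = NULL,
                             weight = 1) {
  profile <- if (inherits(signature, "cluster_signature")) {
    signature$profile
  } else {
    ranked_profile(signature)
  }
  res <- prerank_gsea(profile, go_sets,
    n_perm = n_perm, weight = weight,
    seed = seed
  )
  key <- if (all(is.na(res$nes))) res$es else res$nes
  res[order(-key, res$set_id, method = "radix"), , drop = FALSE]
}
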