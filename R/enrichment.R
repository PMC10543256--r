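# Weighted Kolmogorov-Smirnov enrichment engine.
#
# The running sum walks the ranked profile from top to bottom: at a gene in
# the set ("hit") it increases by that gene's |score|^weight divided by the
# total hit weight; at a gene outside the set ("miss") it decreases by
# 1/(N - N_hits). The enrichment score is the signed maximum deviation of
# the running sum from zero. Because the sum only increases at hits and
# decreases linearly between them, its extrema occur at hit positions
# (maxima) or immediately before hits (minima), which is what es_core
# enumerates — an O(N_hits) computation once hit positions are known.

# Core ES computation from hit positions (sorted, 1-based) and their raw
# weights within a profile of n genes. Returns the signed extremum and the
# position at which it is attained (for the leading edge).
es_core <- function(n, hit_pos, hit_w) {
  nh <- length(hit_pos)
  tot <- sum(hit_w)
  inc <- if (tot > 0) hit_w / tot else rep.int(1 / nh, nh)
  miss <- if (n > nh) 1 / (n - nh) else 0
  ch <- cumsum(inc)
  n_miss_before <- hit_pos - seq_len(nh) # misses strictly before each hit
  at_hit <- ch - n_miss_before * miss # running sum at the hit
  pre_hit <- c(0, ch[-nh]) - n_miss_before * miss # just before the hit
  # interleave in position order: (p_1 - 1, p_1, p_2 - 1, p_2, ...)
  vals <- as.numeric(rbind(pre_hit, at_hit))
  pos <- as.integer(rbind(hit_pos - 1L, hit_pos))
  m <- max(abs(vals))
  if (m == 0) {
    return(list(es = 0, pos = NA_integer_))
  }
  # exact magnitude ties (e.g. a positive and a negative extremum of equal
  # deviation) are broken toward the earliest position; the 1e-9 slack
  # keeps the rule stable under floating-point summation order
  k <- which(abs(vals) >= m - 1e-9)[1L]
  list(es = vals[k], pos = pos[k])
}

#' Weighted-KS enrichment score of a gene set in a ranked profile
#'
#' Preranked GSEA enrichment statistic: hits advance the running sum by
#' their normalized `|score|^weight`, misses retreat it by
#' `1/(N - N_hits)`; the enrichment score (ES) is the signed maximum
#' deviation from zero. Set members absent from the profile are dropped
#' before scoring and the remaining overlap is reported in `n_overlap`.
#'
#' @param profile A [ranked_profile()] (or a named numeric vector, which is
#'   ranked with the stable descending tie rule).
#' @param gene_set A [gene_set()] or character vector of gene ids.
#' @param weight Nonnegative weighting exponent on the ranking scores;
#'   `1` reproduces the classic weighted statistic, `0` the unweighted KS
#'   statistic.
#' @return An object of class `enrichment_result`: a list with `set_id`,
#'   `es`, `n_overlap`, `leading_edge` (set members at or before the
#'   extremum when `es > 0`, at or after it when `es < 0`), and `nes`,
#'   `p_nominal`, `fdr` (all `NA` here; filled by [prerank_gsea()] when
#'   permutations are run).
#' @examples
#' prof <- ranked_profile(c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1))
#' weighted_ks_es(prof, gene_set("demo", c("g1", "g3")))$es # 2/3
#' @seealso [prerank_gsea()], [ssgsea_score()], [shift_ability()]
#' @export
weighted_ks_es <- function(profile, gene_set, weight = 1) {
  profile <- ranked_profile(profile)
  gene_set <- as_one_gene_set(gene_set)
  stopifnot(is.numeric(weight), length(weight) == 1L, weight >= 0)
  hit <- profile$gene_ids %in% gene_set$members
  nh <- sum(hit)
  if (nh == 0L) {
    stop("gene set '", gene_set$set_id,
      "' has no members in the profile; cannot be scored",
      call. = FALSE
    )
  }
  hit_pos <- which(hit)
  core <- es_core(length(profile$gene_ids), hit_pos,
    abs(profile$scores[hit_pos])^weight)
  leading <- character(0)
  if (core$es > 0) {
    leading <- profile$gene_ids[hit_pos[hit_pos <= core$pos]]
  } else if (core$es < 0) {
    leading <- profile$gene_ids[hit_pos[hit_pos >= core$pos]]
  }
  structure(
    list(
      set_id = gene_set$set_id,
      es = core$es,
      nes = NA_real_,
      p_nominal = NA_real_,
      fdr = NA_real_,
      leading_edge = leading,
      n_overlap = nh
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Enrichment of '", x$set_id, "': ES = ", signif(x$es, 4),
    " (", x$n_overlap, " genes in profile)\n",
    sep = ""
  )
  if (!is.na(x$nes)) {
    cat("  NES = ", signif(x$nes, 4), ", p = ", signif(x$p_nominal, 3),
      ", FDR = ", signif(x$fdr, 3), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Preranked GSEA over a collection of gene sets
#'
#' Computes the weighted-KS enrichment score for each set and, when
#' `n_perm > 0`, a permutation null built from random same-size gene sets
#' drawn without replacement from the profile genes (the only feasible null
#' for a single preranked list). Sets with the same overlap size share one
#' null sample. For each set,
#' `NES = ES / mean(|null ES| of the matching sign)` and the nominal p-value
#' is `(1 + #null at least as extreme, same sign) / (1 + #null same sign)`.
#' The false discovery rate uses the sign-stratified ratio-of-tails over the
#' pooled null NES, as in standard GSEA practice. When no null ES of the
#' observed sign exists the NES/p/FDR are left `NA` rather than fabricated.
#'
#' @param profile A [ranked_profile()] or named numeric vector.
#' @param sets A list of [gene_set()]s (or a named list of character
#'   vectors).
#' @param n_perm Number of permutations; `0` reports ES only.
#' @param weight Weighting exponent, as in [weighted_ks_es()].
#' @param seed Optional integer seed; identical seeds reproduce identical
#'   NES/p/FDR. The caller's RNG state is restored on exit.
#' @return A data.frame of class `gsea_result` with one row per scorable
#'   set: `set_id`, `n_overlap`, `es`, `nes`, `p_nominal`, `fdr`, and a
#'   `leading_edge` list-column. Unscorable sets (no overlap) are dropped
#'   with a warning.
#' @export
prerank_gsea <- function(profile, sets, n_perm = 0, weight = 1, seed = NULL) {
  profile <- ranked_profile(profile)
  sets <- as_gene_sets(sets)
  stopifnot(n_perm >= 0)
  n <- length(profile$gene_ids)
  w_all <- abs(profile$scores)^weight

  obs <- lapply(sets, function(s) {
    hit_pos <- which(profile$gene_ids %in% s$members)
    if (length(hit_pos) == 0L) {
      return(NULL)
    }
    core <- es_core(n, hit_pos, w_all[hit_pos])
    list(set = s, hit_pos = hit_pos, es = core$es, pos = core$pos)
  })
  dropped <- vapply(obs, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " gene set(s) had no overlap with the profile ",
      "and were dropped",
      call. = FALSE
    )
    obs <- obs[!dropped]
  }
  if (length(obs) == 0L) {
    stop("no gene set overlaps the profile", call. = FALSE)
  }

  sizes <- vapply(obs, function(o) length(o$hit_pos), integer(1))
  es <- vapply(obs, function(o) o$es, numeric(1))
  leading <- lapply(obs, function(o) {
    hp <- o$hit_pos
    if (o$es > 0) {
      profile$gene_ids[hp[hp <= o$pos]]
    } else if (o$es < 0) {
      profile$gene_ids[hp[hp >= o$pos]]
    } else {
      character(0)
    }
  })

  nes <- p_nom <- fdr <- rep(NA_real_, length(obs))
  if (n_perm > 0) {
    null_by_size <- with_seed(seed, {
      out <- list()
      for (k in sort(unique(sizes))) {
        out[[as.character(k)]] <- vapply(seq_len(n_perm), function(b) {
          idx <- sort.int(sample.int(n, k))
          es_core(n, idx, w_all[idx])$es
        }, numeric(1))
      }
      out
    })
    # per-set normalization: divide by the mean |null ES| of the same sign
    mean_pos <- mean_neg <- list()
    null_nes_pool <- numeric(0)
    for (k in names(null_by_size)) {
      nb <- null_by_size[[k]]
      mp <- if (any(nb > 0)) mean(nb[nb > 0]) else NA_real_
      mn <- if (any(nb < 0)) mean(abs(nb[nb < 0])) else NA_real_
      mean_pos[[k]] <- mp
      mean_neg[[k]] <- mn
      nn <- ifelse(nb >= 0, nb / mp, nb / mn)
      null_nes_pool <- c(null_nes_pool, nn[is.finite(nn)])
    }
    for (i in seq_along(obs)) {
      k <- as.character(sizes[i])
      nb <- null_by_size[[k]]
      if (es[i] >= 0) {
        same <- nb[nb > 0]
        denom <- mean_pos[[k]]
      } else {
        same <- abs(nb[nb < 0])
        denom <- mean_neg[[k]]
      }
      if (length(same) == 0L || !is.finite(denom)) next
      nes[i] <- es[i] / denom
      p_nom[i] <- (1 + sum(same >= abs(es[i]))) / (1 + length(same))
    }
    # sign-stratified ratio-of-tails FDR on the pooled NES
    pool_pos <- null_nes_pool[null_nes_pool >= 0]
    pool_neg <- null_nes_pool[null_nes_pool < 0]
    obs_pos <- nes[!is.na(nes) & nes >= 0]
    obs_neg <- nes[!is.na(nes) & nes < 0]
    for (i in seq_along(obs)) {
      if (is.na(nes[i])) next
      if (nes[i] >= 0) {
        if (length(pool_pos) == 0L) next
        top <- mean(pool_pos >= nes[i])
        bottom <- mean(obs_pos >= nes[i])
      } else {
        if (length(pool_neg) == 0L) next
        top <- mean(pool_neg <= nes[i])
        bottom <- mean(obs_neg <= nes[i])
      }
      fdr[i] <- if (bottom > 0) min(1, top / bottom) else NA_real_
    }
  }

  out <- data.frame(
    set_id = vapply(obs, function(o) o$set$set_id, character(1)),
    n_overlap = sizes,
    es = es,
    nes = nes,
    p_nominal = p_nom,
    fdr = fdr,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out$leading_edge <- I(unname(leading))
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Single-sample gene set enrichment (ssGSEA) score
#'
#' Genes are ordered by decreasing expression (stable tie rule); hit weights
#' are the rank values `(N - position + 1)` raised to `exponent` and
#' normalized to sum to one, miss steps are `1/(N - |S|)`, and the score is
#' the sum over all positions of the running hit-minus-miss difference.
#' Larger scores mean the set members sit uniformly higher in the sample's
#' expression ranking. No cross-sample normalization is applied.
#'
#' @param sample_expression Named numeric vector: one sample's expression by
#'   gene.
#' @param gene_set A [gene_set()] or character vector of gene ids; members
#'   absent from the sample are dropped.
#' @param exponent Nonnegative rank-weighting exponent (default `0.25`, the
#'   customary ssGSEA value; `0` gives the unweighted statistic).
#' @return A single numeric score.
#' @export
ssgsea_score <- function(sample_expression, gene_set, exponent = 0.25) {
  stopifnot(is.numeric(sample_expression), exponent >= 0)
  gene_set <- as_one_gene_set(gene_set)
  genes <- names(sample_expression)
  if (is.null(genes)) {
    stop("sample_expression must be named by gene id", call. = FALSE)
  }
  if (any(!is.finite(sample_expression))) {
    stop("sample_expression contains non-finite values", call. = FALSE)
  }
  ord <- stable_order(sample_expression, genes)
  hit <- genes[ord] %in% gene_set$members
  if (!any(hit)) {
    stop("gene set '", gene_set$set_id,
      "' has no members in the sample; cannot be scored",
      call. = FALSE
    )
  }
  ssgsea_from_order(hit, exponent)
}

# ssGSEA running sum given the hit indicator in ranked order. Split out so
# immune_class_scores() can rank each sample once and score many sets.
ssgsea_from_order <- function(hit, exponent) {
  n <- length(hit)
  nh <- sum(hit)
  rankv <- (n - which(hit) + 1)^exponent
  step_hit <- numeric(n)
  step_hit[hit] <- rankv / sum(rankv)
  step_miss <- numeric(n)
  if (n > nh) {
    step_miss[!hit] <- 1 / (n - nh)
  }
  sum(cumsum(step_hit) - cumsum(step_miss))
}
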