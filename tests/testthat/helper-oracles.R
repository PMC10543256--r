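# Independent brute-force oracles. These deliberately re-derive each
# statistic position by position (or pair by pair), sharing no code with
# the package implementations they check.

# Weighted-KS enrichment score by walking the full running sum. Magnitude
# ties between extrema are broken toward the earliest position, with the
# same 1e-9 slack the package documents for its tie rule.
oracle_es <- function(scores, genes, members, weight = 1) {
  scores <- unname(scores)
  ord <- order(-scores, genes, method = "radix")
  scores <- scores[ord]
  genes <- genes[ord]
  hit <- genes %in% members
  n <- length(genes)
  nh <- sum(hit)
  w <- abs(scores)^weight
  tot <- sum(w[hit])
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      running <- running +
        if (tot > 0) w[i] / tot else 1 / nh
    } else {
      running <- running - 1 / (n - nh)
    }
    if (abs(running) > abs(best) + 1e-9) {
      best <- running
    }
  }
  best
}

# ssGSEA score by explicit position-by-position accumulation.
oracle_ssgsea <- function(expr, members, exponent) {
  ord <- order(-expr, names(expr), method = "radix")
  genes <- names(expr)[ord]
  hit <- genes %in% members
  n <- length(genes)
  nh <- sum(hit)
  hit_w <- numeric(n)
  hit_w[hit] <- (n - which(hit) + 1)^exponent
  hit_w <- hit_w / sum(hit_w)
  total <- 0
  cum_hit <- 0
  cum_miss <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      cum_hit <- cum_hit + hit_w[i]
    } else if (n > nh) {
      cum_miss <- cum_miss + 1 / (n - nh)
    }
    total <- total + (cum_hit - cum_miss)
  }
  total
}

# AUC by exhaustive pair counting, ties worth one half.
oracle_auc <- function(scores, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# Percentile with the linear-interpolation rule (sorted order statistics).
oracle_percentile <- function(x, q) {
  x <- sort(x)
  h <- 1 + (q / 100) * (length(x) - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

random_es_case <- function() {
  n <- sample(5:50, 1)
  genes <- paste0("g", seq_len(n))
  scores <- round(rnorm(n), 2) # rounding induces occasional ties
  k <- sample.int(min(10L, n - 1L), 1)
  members <- sample(genes, k)
  weight <- sample(c(0, 1, 2), 1)
  list(n = n, genes = genes, scores = scores, members = members,
    weight = weight)
}
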