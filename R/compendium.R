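#' Perturbation profile compendium
#'
#' A level-5-style perturbation compendium: one z-score differential
#' expression profile per experiment (columns) over a shared gene universe
#' (rows), with per-experiment metadata including the perturbagen, its
#' type (`compound` or `shRNA`), target gene, cell line, dose, time, and
#' transcriptional activity score (TAS, in `[0, 1]`). TAS is consumed as
#' metadata and never recomputed.
#'
#' @param values Genes x experiments numeric matrix; colnames are
#'   experiment ids.
#' @param meta Data.frame with one row per experiment and columns
#'   `experiment_id`, `perturbagen_id`, `perturbagen_type`, `target_gene`
#'   (`NA` allowed for compounds), `cell_line`, `dose`, `time`, `tas`.
#' @return An object of class `perturbation_compendium`.
#' @export
perturbation_compendium <- function(values, meta) {
  check_finite_matrix(values, "values")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene rownames and experiment colnames",
      call. = FALSE
    )
  }
  required <- c(
    "experiment_id", "perturbagen_id", "perturbagen_type",
    "target_gene", "cell_line", "dose", "time", "tas"
  )
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("meta lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!identical(as.character(meta$experiment_id), colnames(values))) {
    stop("meta$experiment_id must match colnames(values) in order",
      call. = FALSE
    )
  }
  if (any(!is.finite(meta$tas)) || any(meta$tas < 0 | meta$tas > 1)) {
    stop("tas must be finite and within [0, 1]", call. = FALSE)
  }
  if (!all(meta$perturbagen_type %in% c("compound", "shRNA"))) {
    stop('perturbagen_type must be "compound" or "shRNA"', call. = FALSE)
  }
  sh <- meta$perturbagen_type == "shRNA"
  if (any(sh & (is.na(meta$target_gene) | !nzchar(meta$target_gene)))) {
    stop("every shRNA profile must carry a target gene", call. = FALSE)
  }
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta),
    class = "perturbation_compendium"
  )
}

#' @export
print.perturbation_compendium <- function(x, ...) {
  cat("Perturbation compendium:", nrow(x$values), "genes x",
    ncol(x$values), "experiments\n")
  cat("  compounds:", sum(x$meta$perturbagen_type == "compound"),
    " shRNA:", sum(x$meta$perturbagen_type == "shRNA"),
    " cell lines:", length(unique(x$meta$cell_line)), "\n")
  invisible(x)
}

#' Subset a compendium by experiment
#'
#' @param x A `perturbation_compendium`.
#' @param i Experiment selector (logical, integer, or experiment ids).
#' @param ... Ignored.
#' @export
`[.perturbation_compendium` <- function(x, i, ...) {
  if (is.character(i)) {
    i <- match(i, x$meta$experiment_id)
  }
  perturbation_compendium(
    x$values[, i, drop = FALSE],
    x$meta[i, , drop = FALSE]
  )
}

#' Filter a compendium on transcriptional activity and gene universe
#'
#' Retains experiments whose TAS is at least `tas_min` (boundary
#' inclusive) and restricts the gene space to `gene_universe` (e.g. the
#' landmark plus best-inferred genes). Kept/dropped counts are reported
#' via `message()` and recorded in the `"filter_log"` attribute.
#'
#' @param compendium A [perturbation_compendium()].
#' @param tas_min Minimum TAS to retain (default `0.4`).
#' @param gene_universe Optional character vector of gene ids; must be a
#'   subset of the compendium gene space.
#' @return The filtered `perturbation_compendium` (possibly with zero
#'   experiments, in which case a warning is emitted).
#' @export
filter_profiles <- function(compendium, tas_min = 0.4, gene_universe = NULL) {
  stopifnot(inherits(compendium, "perturbation_compendium"))
  stopifnot(is.numeric(tas_min), length(tas_min) == 1L)
  values <- compendium$values
  if (!is.null(gene_universe)) {
    absent <- setdiff(gene_universe, rownames(values))
    if (length(absent) > 0L) {
      stop(length(absent), " gene_universe gene(s) absent from the ",
        "compendium gene space",
        call. = FALSE
      )
    }
    values <- values[gene_universe, , drop = FALSE]
  }
  keep <- compendium$meta$tas >= tas_min
  message(
    "filter_profiles: kept ", sum(keep), " of ", length(keep),
    " experiments at TAS >= ", tas_min
  )
  if (!any(keep)) {
    warning("no experiment passes the TAS filter", call. = FALSE)
  }
  out <- structure(
    list(
      values = values[, keep, drop = FALSE],
      meta = compendium$meta[keep, , drop = FALSE]
    ),
    class = "perturbation_compendium"
  )
  rownames(out$meta) <- NULL
  attr(out, "filter_log") <- list(
    tas_min = tas_min, kept = sum(keep),
    dropped = sum(!keep)
  )
  out
}
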