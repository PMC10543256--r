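#' Read a GCT 1.3 expression matrix
#'
#' Minimal reader for the GCT 1.3 text format: a `#1.3` version line, a
#' dimensions line (rows, columns, optional metadata counts), then a
#' tab-delimited table whose first column holds row ids. Row/column
#' metadata columns beyond the id and `Description` are ignored.
#'
#' @param path Path to a `.gct` file.
#' @return Numeric matrix with gene ids as rownames and sample/experiment
#'   ids as colnames.
#' @export
read_gct <- function(path) {
  header <- readLines(path, n = 2L)
  if (length(header) < 2L || !startsWith(header[1L], "#1.")) {
    stop("not a GCT file (missing '#1.x' version line): ", path,
      call. = FALSE
    )
  }
  dims <- as.integer(strsplit(header[2L], "\t", fixed = TRUE)[[1L]])
  nr <- dims[1L]
  nc <- dims[2L]
  n_rmeta <- if (length(dims) >= 3L && !is.na(dims[3L])) dims[3L] else 1L
  tab <- utils::read.delim(path,
    skip = 2L, header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  ids <- as.character(tab[[1L]])
  data_cols <- seq.int(ncol(tab) - nc + 1L, ncol(tab))
  m <- as.matrix(tab[, data_cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (nrow(m) != nr) {
    stop("GCT dimensions line does not match table: ", path, call. = FALSE)
  }
  m
}

#' Write a GCT 1.3 expression matrix
#'
#' @param x Numeric matrix with rownames (gene ids) and colnames (sample or
#'   experiment ids).
#' @param path Output path.
#' @param description Optional per-row description column; defaults to
#'   `"na"`.
#' @export
write_gct <- function(x, path, description = NULL) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  if (is.null(description)) {
    description <- rep("na", nrow(x))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("#1.3", paste(nrow(x), ncol(x), 1, 0, sep = "\t")), con)
  tab <- data.frame(
    id = rownames(x), Description = description, x,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(tab, con,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}
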