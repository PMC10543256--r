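#' Gene set
#'
#' A named collection of gene identifiers, e.g. the anti-PD-1 resistance (R)
#' or sensitivity (S) signature, an immune-response signature, or a GO term.
#'
#' @param set_id Identifier of the set.
#' @param members Character vector of gene ids; duplicates are dropped.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(set_id, members) {
  members <- unique(as.character(members))
  members <- members[!is.na(members) & nzchar(members)]
  if (length(members) == 0L) {
    stop("gene set '", set_id, "' has no members", call. = FALSE)
  }
  structure(list(set_id = as.character(set_id), members = members),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$set_id, "': ", length(x$members), " genes\n", sep = "")
  invisible(x)
}

# Coerce a character vector, gene_set, or (named) list into a named list of
# gene_set objects.
as_gene_sets <- function(x) {
  if (inherits(x, "gene_set")) {
    out <- list(x)
    names(out) <- x$set_id
    return(out)
  }
  if (is.character(x)) {
    return(as_gene_sets(gene_set("set", x)))
  }
  if (!is.list(x)) {
    stop("cannot interpret gene sets of class ", class(x)[1], call. = FALSE)
  }
  nm <- names(x)
  out <- lapply(seq_along(x), function(i) {
    el <- x[[i]]
    if (inherits(el, "gene_set")) {
      return(el)
    }
    id <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else paste0("set", i)
    gene_set(id, el)
  })
  names(out) <- vapply(out, function(s) s$set_id, character(1))
  out
}

as_one_gene_set <- function(x, default_id = "set") {
  if (inherits(x, "gene_set")) {
    return(x)
  }
  if (is.character(x)) {
    return(gene_set(default_id, x))
  }
  stop("expected a gene_set or character vector of gene ids", call. = FALSE)
}

#' Read gene sets from a GMT file
#'
#' Tab-delimited GMT: set name, description, then member genes.
#'
#' @param path Path to a GMT file.
#' @return Named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  as_gene_sets(sets)
}

#' Write gene sets to a GMT file
#'
#' @param sets List of `gene_set` objects (or named list of character
#'   vectors).
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (second GMT column); defaults to `"na"`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  sets <- as_gene_sets(sets)
  if (is.null(descriptions)) {
    descriptions <- rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(sets[[i]]$set_id, descriptions[i], sets[[i]]$members),
      collapse = "\t"
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
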