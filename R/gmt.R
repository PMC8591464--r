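#' Gene set collection
#'
#' Named lists of member gene ids with optional descriptions, as stored in
#' GMT files (MSigDB layout: name, description, then tab-separated members).
#'
#' @param sets named list of character vectors of member gene ids.
#' @param descriptions optional character vector, one per set.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  sets <- lapply(sets, function(s) as.character(unique(s)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets))
    stop("one description per set required")
  structure(list(sets = sets,
                 descriptions = stats::setNames(descriptions, names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)\n",
              length(x$sets), min(sz), max(sz)))
  invisible(x)
}

#' Read / write GMT gene set files
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>member1<TAB>member2...`.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1L])
  nm <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection` to write.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a collection to a gene universe and size bounds
#'
#' Intersects every set with `universe` and keeps sets whose intersection
#' size lies in `[min_size, max_size]`.
#'
#' @param collection a `gene_set_collection`.
#' @param universe character vector of measured gene ids.
#' @param min_size,max_size inclusive bounds on the intersected set size.
#' @return A filtered `gene_set_collection`.
#' @export
filter_collection <- function(collection, universe, min_size = 5,
                              max_size = 500) {
  sets <- lapply(collection$sets, function(s) s[s %in% universe])
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  if (!any(keep)) stop("no gene set survives the size filter")
  gene_set_collection(sets[keep], collection$descriptions[keep])
}
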