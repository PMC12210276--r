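#' Read / write gene-set collections in GMT format
#'
#' GMT: one set per line, tab-separated: name, description, genes... Reading
#' goes through `fgsea::gmtPathways`; the universe defaults to the union of
#' all sets unless supplied.
#'
#' @param path GMT file path.
#' @param universe optional character vector of gene ids.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe)
}

#' @rdname read_gmt
#' @param collection a [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(collection)
}
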