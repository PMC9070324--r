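#' Taxonomic lineage strings
#'
#' Lineages are serialized as semicolon-delimited `rank:name` pairs ordered
#' from most to least inclusive, e.g.
#' `"superkingdom:Eukaryota;kingdom:Fungi;phylum:Ascomycota"`. A lineage is
#' *fungal* when any pair carries the name `Fungi` (exact match); the phylum is
#' the name at rank `phylum`, or `NA` when absent. Both predicates are
#' vectorized over character vectors.
#'
#' @param lineage Character vector of serialized lineages.
#' @return `lineage_is_fungal()` a logical vector; `lineage_phylum()` a
#'   character vector (`NA` where no phylum rank is present).
#' @export
#' @examples
#' lineage_is_fungal("kingdom:Fungi;phylum:Ascomycota")
#' lineage_phylum(c("kingdom:Fungi;phylum:Ascomycota", "kingdom:Viridiplantae"))
lineage_is_fungal <- function(lineage) {
  vapply(parse_lineage(lineage), function(l) any(l$name == "Fungi"), logical(1))
}

#' @rdname lineage_is_fungal
#' @export
lineage_phylum <- function(lineage) {
  vapply(parse_lineage(lineage), function(l) {
    i <- which(l$rank == "phylum")
    if (length(i) == 0) NA_character_ else l$name[i[1]]
  }, character(1))
}

#' Build a lineage string from rank/name pairs
#'
#' @param ranks,names Equal-length character vectors; `ranks` must be unique.
#' @return A single serialized lineage string.
#' @export
#' @examples
#' make_lineage(c("kingdom", "phylum"), c("Fungi", "Ascomycota"))
make_lineage <- function(ranks, names) {
  stopifnot(length(ranks) == length(names))
  if (anyDuplicated(ranks)) {
    abort("rank names must be unique within one lineage")
  }
  paste(paste(ranks, names, sep = ":"), collapse = ";")
}

# internal: parse a vector of serialized lineages into list of data frames
parse_lineage <- function(lineage) {
  lapply(lineage, function(x) {
    if (is.na(x) || !nzchar(x)) {
      return(list(rank = character(), name = character()))
    }
    parts <- strsplit(x, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    bad <- lengths(kv) != 2
    if (any(bad)) {
      abort(paste0("malformed lineage component: '", parts[bad][1], "'"))
    }
    rank <- vapply(kv, `[[`, "", 1)
    name <- vapply(kv, `[[`, "", 2)
    if (anyDuplicated(rank)) {
      abort(paste0("duplicate rank in lineage: '", x, "'"))
    }
    list(rank = rank, name = name)
  })
}

# internal: validate a vector of lineage strings, returns invisibly
check_lineages <- function(lineage) {
  invisible(parse_lineage(lineage))
}

# internal lineage templates used by simulators and fixtures
lineage_for_category <- function(category) {
  templates <- c(
    PLANT  = "superkingdom:Eukaryota;kingdom:Viridiplantae;phylum:Streptophyta",
    ASCO   = "superkingdom:Eukaryota;kingdom:Fungi;phylum:Ascomycota",
    BASIDIO = "superkingdom:Eukaryota;kingdom:Fungi;phylum:Basidiomycota",
    OTHER  = "superkingdom:Eukaryota;kingdom:Fungi;phylum:Mucoromycota"
  )
  unname(templates[category])
}
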