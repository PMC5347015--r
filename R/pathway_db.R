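#' Construct a pathway annotation database
#'
#' Maps pathway ids to display names and member gene sets.  Genes may belong
#' to several pathways; member sets must be non-empty.  The union of all
#' members is the default annotation universe (the `N` of the
#' over-representation test).
#'
#' @param members named list of character vectors: pathway id -> gene ids.
#' @param names optional named character vector of display names (defaults
#'   to the ids).
#' @return An object of class `pathway_db`.
#' @export
pathway_db <- function(members, names = NULL) {
  if (!length(members) || is.null(base::names(members)))
    stopf("'members' must be a non-empty named list")
  if (anyDuplicated(base::names(members))) stopf("duplicate pathway id")
  members <- lapply(members, function(g) unique(as.character(g)))
  empty <- lengths(members) == 0L
  if (any(empty))
    stopf("pathway '%s' has zero members", base::names(members)[empty][1L])
  if (is.null(names)) {
    names <- stats::setNames(base::names(members), base::names(members))
  } else {
    names <- stats::setNames(as.character(names)[match(base::names(members),
                                                       base::names(names))],
                             base::names(members))
    names[is.na(names)] <- base::names(members)[is.na(names)]
  }
  structure(list(members = members, names = names), class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d pathways, %d annotated genes\n",
              length(x$members), length(pathway_universe(x))))
  invisible(x)
}

#' @export
length.pathway_db <- function(x) length(x$members)

#' All genes carrying at least one pathway annotation
#'
#' @param db a [pathway_db()].
#' @return Character vector of gene ids.
#' @export
pathway_universe <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  unique(unlist(db$members, use.names = FALSE))
}

#' Read pathway annotation (GMT or two-column TSV)
#'
#' The dialect is inferred from the column count: lines with three or more
#' tab-separated fields are GMT (`pathway_id<TAB>name<TAB>gene...`); files
#' whose every line has exactly two fields are gene-to-pathway pairs
#' (`gene_id<TAB>pathway_id`).  Both dialects encoding the same membership
#' yield the same database.
#'
#' @param path annotation file.
#' @return A [pathway_db()].
#' @export
read_pathway_db <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stopf("empty pathway file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L))
    stopf("malformed pathway line %d (fewer than 2 fields)",
          which(nf < 2L)[1L])
  if (all(nf == 2L)) {
    gene <- vapply(fields, `[`, "", 1L)
    pw <- vapply(fields, `[`, "", 2L)
    members <- split(gene, pw)
    # preserve first-appearance order of pathways
    members <- members[unique(pw)]
    return(pathway_db(members))
  }
  if (any(nf == 2L))
    stopf("malformed GMT line %d: pathway with zero member genes",
          which(nf == 2L)[1L])
  ids <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(ids)) stopf("duplicate pathway id '%s'",
                                ids[duplicated(ids)][1L])
  nms <- stats::setNames(vapply(fields, `[`, "", 2L), ids)
  members <- stats::setNames(lapply(fields, function(f) f[-c(1L, 2L)]), ids)
  pathway_db(members, nms)
}

#' Write pathway annotation as GMT
#'
#' @param db a [pathway_db()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- vapply(names(db$members), function(id) {
    paste(c(id, db$names[[id]], db$members[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
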