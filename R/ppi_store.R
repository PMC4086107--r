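# Interactome storage: the universe of proteins and undirected binary
# interactions that seed searches run against, plus the external-ID -> canonical
# ID mapping used to connect user gene lists to it.

read_two_column <- function(path, what) {
  lines <- readLines(path)
  keep <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    stop(sprintf("empty %s file: '%s'", what, path), call. = FALSE)
  }
  fields <- lapply(strsplit(lines[keep], "\t", fixed = TRUE), function(f) {
    f <- trimws(f)
    f[nzchar(f)]
  })
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s row at line %d of '%s': need 2 tab-delimited columns",
                 what, keep[bad[1L]], path), call. = FALSE)
  }
  data.frame(a = vapply(fields, `[[`, "", 1L),
             b = vapply(fields, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

# Header heuristic: row 1 is a header iff neither of its tokens reappears
# anywhere else in the table.
drop_header <- function(tab) {
  if (nrow(tab) > 1L) {
    rest <- c(tab$a[-1L], tab$b[-1L])
    if (!any(c(tab$a[1L], tab$b[1L]) %in% rest)) tab <- tab[-1L, , drop = FALSE]
  }
  tab
}

#' Load a protein-protein interaction universe
#'
#' Reads a tab-delimited two-column edge list of undirected binary
#' interactions (comment lines starting `#` are skipped; a header row is
#' auto-detected when its tokens appear nowhere else). Self-interactions and
#' duplicate pairs -- `(a,b)` and `(b,a)` count once -- are dropped with a
#' logged count. An optional two-column mapping file (external ID, canonical
#' ID) connects user gene identifiers to the interactome; without it the
#' mapping is the identity over the interactome's proteins.
#'
#' @param path Path to the tab-delimited edge list.
#' @param mapping_path Optional path to a two-column external-to-canonical ID
#'   mapping table.
#' @param species Free-text label for the interactome (e.g. `"human"`).
#' @return An `interaction_db` object with elements `species`, `proteins`
#'   (character vector of canonical IDs), `interactions` (two-column data
#'   frame, each unordered pair once), and `id_map` (named character vector,
#'   external ID -> canonical ID; always contains the identity over
#'   `proteins`).
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "A\tA", "B\tC"), f)
#' db <- load_interactions(f)
#' db$proteins
#' @export
load_interactions <- function(path, mapping_path = NULL, species = "custom") {
  tab <- drop_header(read_two_column(path, "interaction"))
  if (nrow(tab) == 0L) stop("no interaction rows in '", path, "'", call. = FALSE)

  self <- tab$a == tab$b
  if (any(self)) {
    message(sum(self), " self-interaction(s) dropped")
    tab <- tab[!self, , drop = FALSE]
  }
  key <- paste(pmin(tab$a, tab$b), pmax(tab$a, tab$b), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate interaction(s) dropped")
    tab <- tab[!dup, , drop = FALSE]
  }
  interactions <- data.frame(from = pmin(tab$a, tab$b), to = pmax(tab$a, tab$b),
                             stringsAsFactors = FALSE)
  proteins <- sort(unique(c(interactions$from, interactions$to)))

  id_map <- setNames(proteins, proteins)
  if (!is.null(mapping_path)) {
    m <- read_two_column(mapping_path, "mapping")
    id_map[m$a] <- m$b
  }

  structure(list(species = species, proteins = proteins,
                 interactions = interactions, id_map = id_map),
            class = "interaction_db")
}

#' Write an interactome back to disk
#'
#' Inverse of [load_interactions()]: writes the interaction table (and, when
#' requested, the non-identity part of the ID mapping) so that reloading
#' yields an identical database.
#'
#' @param db An `interaction_db`.
#' @param path Output path for the edge list.
#' @param mapping_path Optional output path for the mapping table.
#' @return `db`, invisibly.
#' @export
write_interactions <- function(db, path, mapping_path = NULL) {
  stopifnot(inherits(db, "interaction_db"))
  utils::write.table(db$interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(mapping_path)) {
    keep <- names(db$id_map) != unname(db$id_map)
    utils::write.table(
      data.frame(names(db$id_map)[keep], unname(db$id_map)[keep]),
      mapping_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(db)
}

#' @export
print.interaction_db <- function(x, ...) {
  cat(sprintf("Interactome (%s): %d proteins, %d interactions, %d mapped IDs\n",
              x$species, length(x$proteins), nrow(x$interactions),
              length(x$id_map)))
  invisible(x)
}

#' Map external gene identifiers onto the interactome
#'
#' Order-preserving translation of external IDs through the database's ID
#' map. Every input ID lands in exactly one of the two outputs; distinct
#' inputs collapsing onto the same canonical protein are reported once, with
#' a logged note.
#'
#' @param db An `interaction_db`.
#' @param ids Character vector of external gene/probe IDs.
#' @return A list with `mapped` (canonical IDs, deduplicated, input order)
#'   and `unmapped` (inputs with no entry in the map).
#' @export
map_ids <- function(db, ids) {
  stopifnot(inherits(db, "interaction_db"))
  ids <- trimws(as.character(ids))
  hit <- ids %in% names(db$id_map)
  mapped_raw <- unname(db$id_map[ids[hit]])
  if (anyDuplicated(mapped_raw)) {
    message(sum(duplicated(mapped_raw)),
            " input ID(s) collapsed onto already-mapped canonical IDs")
  }
  list(mapped = unique(mapped_raw), unmapped = unique(ids[!hit]))
}
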