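# Taxonomic path model: parsing, formatting, LCA, novelty helpers.
#
# A taxonomic path is a named character vector over the seven canonical
# ranks; NA marks an unknown rank. Dataset-level taxonomy lives in the seven
# rank columns of a zOTU data frame (see read_annotated_fasta()).

#' The seven canonical taxonomic ranks
#'
#' Ordered shallow to deep: domain, phylum, class, order, family, genus,
#' species.
#'
#' @return Character vector of rank names.
#' @export
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
.RANK_PREFIX <- c(domain = "d", phylum = "p", class = "c", order = "o",
                  family = "f", genus = "g", species = "s")
.PLACEHOLDERS <- c(phylum = "UNKPHYLUM", class = "UNKCLASS", order = "UNKORDER")

#' An all-unknown taxonomic path
#' @return Named character vector of the seven ranks, all `NA`.
#' @export
empty_tax_path <- function() {
  setNames(rep(NA_character_, 7L), .RANKS)
}

#' Parse a taxonomy annotation string
#'
#' Parses the `tax=` annotation dialect used in FASTA headers:
#' comma-separated `<prefix>:<name>` tokens with single-letter rank prefixes
#' `d,p,c,o,f,g,s` (e.g. `"tax=d:Bacteria,p:Actinobacteriota,g:Bifidobacterium"`).
#' The leading `tax=` is optional; ranks not mentioned are unknown (`NA`).
#' An empty string yields an all-unknown path.
#'
#' @param annotation A single annotation string.
#' @return Named character vector over [tax_ranks()]; `NA` = unknown.
#' @seealso [format_taxonomy()] for the inverse.
#' @export
parse_taxonomy <- function(annotation) {
  if (length(annotation) != 1L || !is.character(annotation) || is.na(annotation))
    stop_ticlust("'annotation' must be a single character string")
  path <- empty_tax_path()
  s <- sub("^tax=", "", annotation)
  if (!nzchar(s)) return(path)
  tokens <- strsplit(s, ",", fixed = TRUE)[[1L]]
  for (tok in tokens) {
    m <- regmatches(tok, regexec("^([a-z]):(.+)$", tok))[[1L]]
    if (length(m) != 3L)
      stop_ticlust("malformed taxonomy token: '", tok, "'")
    rank <- names(.RANK_PREFIX)[match(m[2L], .RANK_PREFIX)]
    if (is.na(rank))
      stop_ticlust("unknown rank prefix in taxonomy token: '", tok, "'")
    if (!is.na(path[[rank]]))
      stop_ticlust("duplicate rank in taxonomy annotation: '", tok, "'")
    path[[rank]] <- m[3L]
  }
  path
}

#' Format a taxonomic path as an annotation string
#'
#' Inverse of [parse_taxonomy()]: known ranks are joined shallow-to-deep as
#' comma-separated `<prefix>:<name>` tokens; unknown ranks are omitted. An
#' all-unknown path formats as `""`.
#'
#' @param path Named character vector over [tax_ranks()] (`NA` = unknown).
#' @return A single string (without the `tax=` key).
#' @export
format_taxonomy <- function(path) {
  path <- as_tax_path(path)
  known <- !is.na(path)
  if (!any(known)) return("")
  paste0(.RANK_PREFIX[.RANKS[known]], ":", path[known], collapse = ",")
}

# Coerce a 7-element vector (possibly unnamed, e.g. a data-frame row) into
# a canonical path vector.
as_tax_path <- function(path) {
  if (is.list(path)) path <- unlist(path)
  if (length(path) != 7L)
    stop_ticlust("a taxonomic path must have exactly 7 ranks")
  path <- as.character(path)
  names(path) <- .RANKS
  path
}

#' Depth of a taxonomic path
#'
#' Index (1 = domain ... 7 = species) of the deepest known rank; 0 if all
#' ranks are unknown. Placeholder names (UNKPHYLUM/UNKCLASS/UNKORDER) count
#' as known: they fill a rank.
#'
#' @param path A taxonomic path.
#' @return Integer in 0..7.
#' @export
tax_depth <- function(path) {
  path <- as_tax_path(path)
  known <- which(!is.na(path))
  if (length(known) == 0L) return(0L)
  max(known)
}

#' Last common ancestor of taxonomic paths
#'
#' The deepest path on whose known ranks every input agrees: descending
#' rank by rank, the first rank at which inputs disagree (or any input is
#' unknown) ends the consensus; that rank and all deeper ranks are `NA`.
#'
#' @param paths A list of taxonomic paths (or a character matrix / data
#'   frame with 7 rank columns, one row per path).
#' @return A taxonomic path.
#' @export
lca <- function(paths) {
  if (is.data.frame(paths) || is.matrix(paths)) {
    paths <- lapply(seq_len(nrow(paths)), function(i) as_tax_path(paths[i, , drop = TRUE]))
  }
  if (!is.list(paths) || length(paths) == 0L)
    stop_ticlust("'paths' must be a non-empty list of taxonomic paths")
  paths <- lapply(paths, as_tax_path)
  out <- empty_tax_path()
  for (r in seq_len(7L)) {
    names_r <- vapply(paths, function(p) p[[r]], character(1L))
    if (anyNA(names_r) || length(unique(names_r)) != 1L) break
    out[[r]] <- names_r[[1L]]
  }
  out
}

#' Is a taxon name a TIC placeholder?
#'
#' @param name Character vector of taxon names.
#' @return Logical: `TRUE` for UNKPHYLUM, UNKCLASS or UNKORDER.
#' @export
is_placeholder <- function(name) {
  !is.na(name) & name %in% .PLACEHOLDERS
}

#' Is a taxon name TIC-created?
#'
#' Novel OTU names have the deterministic forms `sOTU_<n>`, `gOTU_<n>` or
#' `fOTU_<n>`.
#'
#' @param name Character vector of taxon names.
#' @return Logical vector.
#' @export
is_novel_name <- function(name) {
  !is.na(name) & grepl("^[sgf]OTU_[0-9]+$", name)
}

# Path keys used to group sequences/clusters by a taxonomy prefix.
# `upto` is the deepest rank index included. Rows with any NA inside the
# prefix get an NA key.
path_key <- function(tax, upto) {
  if (upto == 0L) return(rep("", nrow(tax)))
  cols <- .RANKS[seq_len(upto)]
  m <- as.matrix(tax[, cols, drop = FALSE])
  key <- apply(m, 1L, function(r) if (anyNA(r)) NA_character_ else paste(r, collapse = "\r"))
  as.character(key)
}

# Lenient variant for internal cluster registries: NA ranks become a
# reserved marker so an all-unknown domain (the only rank without a
# placeholder) still yields a usable, non-colliding key.
path_key_lenient <- function(tax, upto) {
  if (upto == 0L) return(rep("", nrow(tax)))
  m <- as.matrix(tax[, .RANKS[seq_len(upto)], drop = FALSE])
  m[is.na(m)] <- "\001"
  apply(m, 1L, paste, collapse = "\r")
}

state_key <- function(tax_vec, upto) {
  v <- as.character(tax_vec[seq_len(upto)])
  v[is.na(v)] <- "\001"
  paste(v, collapse = "\r")
}

# Validate prefix-contiguity: a known rank requires all shallower ranks to
# be known (placeholders count as known).
check_contiguous <- function(tax, ids = NULL) {
  m <- !is.na(as.matrix(tax[, .RANKS, drop = FALSE]))
  depth <- apply(m, 1L, function(r) if (!any(r)) 0L else max(which(r)))
  nknown <- rowSums(m)
  bad <- nknown != depth
  if (any(bad)) {
    which_bad <- if (is.null(ids)) which(bad)[1L] else ids[bad][1L]
    stop_ticlust("taxonomy is not prefix-contiguous (a deep rank is known ",
                 "while a shallower one is unknown) for sequence: ", which_bad)
  }
  invisible(TRUE)
}
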