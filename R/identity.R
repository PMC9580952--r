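# Pairwise global sequence identity and the exhaustive search primitive.

#' Global pairwise identity between two DNA sequences
#'
#' Computes an optimal Needleman-Wunsch global alignment (match +1,
#' mismatch -1, gap -2, linear gap penalty) and returns
#' matching columns / alignment columns excluding terminal gaps, the
#' "iddef 2"-style convention of the usual OTU clustering tools. Internal
#' gaps count against identity; `N` never counts as a match. When several
#' alignments are optimal, the traceback prefers a substitution over a gap,
#' making the value fully deterministic.
#'
#' @param a,b Non-empty DNA strings (uppercase A/C/G/T/N).
#' @return Identity fraction in \[0, 1\]; symmetric, and
#'   `global_identity(a, a) == 1` for N-free `a`.
#' @export
global_identity <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L || length(b) != 1L)
    stop_ticlust("'a' and 'b' must be single strings")
  if (!nzchar(a) || !nzchar(b))
    stop_ticlust("sequences must be non-empty")
  nw_identity_cpp(a, b)
}

#' Top hits of a query against a reference set
#'
#' Exhaustive search: computes [global_identity()] of the query against
#' every reference and returns up to `k` hits with identity at least
#' `min_identity`, sorted by identity (descending); ties are broken by
#' larger reference `size`, then by reference `id` (C-locale ascending).
#'
#' @param query Either a single sequence string or a one-row zOTU data
#'   frame (only the `seq` field is used).
#' @param references A zOTU data frame with columns `id`, `seq`, `size`.
#' @param k Maximum number of hits (>= 1).
#' @param min_identity Minimum identity to report, in \[0, 1\].
#' @return Data frame with columns `target_id`, `identity` (possibly 0 rows).
#' @export
top_hits <- function(query, references, k = 10L, min_identity = 0) {
  if (is.data.frame(query)) {
    if (nrow(query) != 1L) stop_ticlust("'query' must be a single sequence")
    query <- query$seq
  }
  if (k < 1L) stop_ticlust("'k' must be >= 1")
  if (is.null(references) || nrow(references) == 0L)
    return(data.frame(target_id = character(0), identity = numeric(0)))
  ident <- nw_identity_many_cpp(query, references$seq)
  keep <- which(ident >= min_identity)
  if (length(keep) == 0L)
    return(data.frame(target_id = character(0), identity = numeric(0)))
  size <- if ("size" %in% names(references)) references$size[keep] else rep(1L, length(keep))
  ord <- order(-ident[keep], -size, references$id[keep], method = "radix")
  keep <- keep[ord][seq_len(min(k, length(keep)))]
  data.frame(target_id = references$id[keep], identity = ident[keep],
             stringsAsFactors = FALSE)
}
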