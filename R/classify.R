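# kNN-LCA consensus classifier: places a query by the lineage consensus of
# its k closest labeled reference sequences.

#' Classify a query sequence by kNN-LCA consensus
#'
#' Finds the `k` closest references by [global_identity()] (ties per
#' [top_hits()]), then assigns taxonomy rank by rank from domain downward:
#' a rank is assigned the name shared by at least `consensus` of the hits
#' (an absolute count, unchanged when fewer than `k` references are
#' available); the first rank without a consensus name stops the descent and
#' deeper ranks stay unknown. The default 7-of-10 consensus places a
#' sequence at the last common ancestor supported by at least 7 of its 10
#' closest database sequences.
#'
#' @param query A sequence string or one-row zOTU data frame.
#' @param references A labeled zOTU data frame (columns `id`, `seq`, `size`
#'   and the seven rank columns).
#' @param k Number of nearest references to consult (default 10).
#' @param consensus Minimum number of hits that must share a name
#'   (default 7); must satisfy `1 <= consensus <= k`.
#' @param min_identity Hits below this identity are ignored (default 0.5,
#'   excluding junk matches).
#' @return A taxonomic path (named character vector over [tax_ranks()]).
#'   An empty reference set yields an all-unknown path.
#' @export
knn_lca_classify <- function(query, references, k = 10L, consensus = 7L,
                             min_identity = 0.5) {
  if (consensus < 1L || consensus > k)
    stop_ticlust("'consensus' must satisfy 1 <= consensus <= k")
  out <- empty_tax_path()
  if (is.null(references) || nrow(references) == 0L) return(out)
  hits <- top_hits(query, references, k = k, min_identity = min_identity)
  if (nrow(hits) == 0L) return(out)
  ref_tax <- references[match(hits$target_id, references$id), .RANKS, drop = FALSE]
  for (r in seq_len(7L)) {
    names_r <- ref_tax[[.RANKS[r]]]
    names_r <- names_r[!is.na(names_r)]
    if (length(names_r) == 0L) break
    tab <- table(names_r)
    if (max(tab) < consensus) break
    winners <- sort(names(tab)[tab == max(tab)], method = "radix")
    out[[r]] <- winners[1L]
  }
  out
}

#' Classify many queries against a reference set
#'
#' Vectorised wrapper around [knn_lca_classify()]: classifies every row of
#' `queries` and writes the resulting paths into its rank columns.
#'
#' @param queries A zOTU data frame.
#' @inheritParams knn_lca_classify
#' @return `queries` with the seven rank columns replaced by the
#'   classifier's assignments.
#' @export
classify_dataset <- function(queries, references, k = 10L, consensus = 7L,
                             min_identity = 0.5) {
  for (rank in .RANKS) queries[[rank]] <- NA_character_
  for (i in seq_len(nrow(queries))) {
    p <- knn_lca_classify(queries$seq[i], references, k = k,
                          consensus = consensus, min_identity = min_identity)
    queries[i, .RANKS] <- as.list(p)
  }
  queries
}
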