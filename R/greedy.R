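# Internal greedy centroid clustering engine (abundance-sorted, AGC style).
# Stands in for the external USEARCH/VSEARCH binaries of classic pipelines.

#' Greedy centroid clustering at an identity threshold
#'
#' Sequences are processed in the canonical order: abundance (`size`)
#' descending, ties by sequence string and then by id (C locale). The first
#' sequence founds the first cluster; every subsequent sequence joins the
#' centroid with the highest [global_identity()] at or above `threshold`
#' (ties: larger centroid `size`, then centroid id), or founds a new
#' cluster. Centroids are founders and are never recomputed, so the result
#' is deterministic and independent of input row order.
#'
#' @param x A zOTU data frame with columns `id`, `seq`, `size`.
#' @param threshold Identity threshold in (0, 1\]; joining is inclusive
#'   (identity == threshold joins).
#' @return An object of class `greedy_clustering`: a list with
#'   `assignment` (named character vector, sequence id -> centroid id),
#'   `centroids` (centroid ids in founding order) and `members` (list of
#'   member-id vectors, founding order).
#' @export
greedy_cluster <- function(x, threshold) {
  if (is.null(x) || nrow(x) == 0L) stop_ticlust("no sequences to cluster")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop_ticlust("'threshold' must lie in (0, 1]")
  if (anyDuplicated(x$id)) stop_ticlust("duplicate sequence ids")
  x <- x[canonical_order(x), , drop = FALSE]
  n <- nrow(x)
  cent_idx <- integer(0)         # row indices of centroids, founding order
  assign_to <- integer(n)        # per row: index into cent_idx
  for (i in seq_len(n)) {
    if (length(cent_idx) == 0L) {
      cent_idx <- i
      assign_to[i] <- 1L
      next
    }
    ident <- nw_identity_many_cpp(x$seq[i], x$seq[cent_idx])
    best <- max(ident)
    if (best >= threshold) {
      cand <- which(ident == best)
      if (length(cand) > 1L) {
        ord <- order(-x$size[cent_idx[cand]], x$id[cent_idx[cand]],
                     method = "radix")
        cand <- cand[ord]
      }
      assign_to[i] <- cand[1L]
    } else {
      cent_idx <- c(cent_idx, i)
      assign_to[i] <- length(cent_idx)
    }
  }
  centroids <- x$id[cent_idx]
  assignment <- setNames(centroids[assign_to], x$id)
  members <- split(x$id, assign_to)
  names(members) <- NULL
  structure(list(assignment = assignment, centroids = centroids,
                 members = members, threshold = threshold),
            class = "greedy_clustering")
}

#' @export
print.greedy_clustering <- function(x, ...) {
  cat(sprintf("greedy_clustering: %d sequences in %d clusters (threshold %.3f)\n",
              length(x$assignment), length(x$centroids), x$threshold))
  invisible(x)
}
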