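# Cluster-quality metrics against a ground-truth labeling: pooled purity,
# adjusted Rand index, normalised mutual information, and mixed-clade
# counts. The evaluation unit is the unique sequence (zOTU), not read
# abundance.

# Normalise a partition argument: accepts a named vector (id -> cluster
# label) or a list of member-id vectors.
as_partition <- function(x, arg = "partition") {
  if (is.list(x) && !is.data.frame(x)) {
    ids <- unlist(x, use.names = FALSE)
    if (anyDuplicated(ids)) stop_ticlust("'", arg, "' is not a partition: duplicated ids")
    labs <- rep(seq_along(x), lengths(x))
    return(setNames(as.character(labs), ids))
  }
  if (is.null(names(x)) || length(x) == 0L)
    stop_ticlust("'", arg, "' must be a non-empty named vector or list of id vectors")
  setNames(as.character(x), names(x))
}

#' Contingency table of two partitions
#'
#' @param a,b Partitions over the same id universe: named vectors
#'   (id -> cluster label) or lists of member-id vectors.
#' @return Integer matrix `n_ij` = number of ids in cluster i of `a` and
#'   cluster j of `b`.
#' @export
contingency_table <- function(a, b) {
  a <- as_partition(a, "a"); b <- as_partition(b, "b")
  if (length(a) != length(b) || !setequal(names(a), names(b)))
    stop_ticlust("partitions must cover the same id universe")
  b <- b[names(a)]
  unclass(table(a, b))
}

#' Pooled cluster purity
#'
#' The fraction of sequences whose cluster's majority true label matches
#' their own: `sum_i max_j n_ij / n`, pooled over clusters. Ids whose true
#' label is unknown (`NA`) are excluded before counting, so pruned labels
#' never count for or against a cluster. The macro-averaged variant (mean
#' of per-cluster purities, clusters weighted equally) is available with
#' `macro = TRUE`.
#'
#' @param clusters Partition of sequence ids (named vector or list).
#' @param truth Named character vector: sequence id -> true label
#'   (`NA` = unknown, excluded).
#' @param macro If `TRUE`, average per-cluster purities instead of pooling.
#' @return Purity in \[0, 1\].
#' @export
purity <- function(clusters, truth, macro = FALSE) {
  clusters <- as_partition(clusters, "clusters")
  labeled <- names(truth)[!is.na(truth)]
  keep <- names(clusters) %in% labeled
  clusters <- clusters[keep]
  if (length(clusters) == 0L)
    stop_ticlust("empty partition: no clustered sequence has a known true label")
  tab <- unclass(table(clusters, truth[names(clusters)]))
  if (macro) return(mean(apply(tab, 1L, max) / rowSums(tab)))
  sum(apply(tab, 1L, max)) / sum(tab)
}

#' Adjusted Rand index
#'
#' Chance-corrected pairwise agreement between two partitions under the
#' permutation model: `(Index - E[Index]) / (Max - E[Index])` over pair
#' counts from the contingency table. Equals 1 iff the partitions are
#' identical; a single-element universe (and the degenerate case where the
#' correction denominator vanishes with identical partitions) is defined
#' as 1.
#'
#' @inheritParams contingency_table
#' @return ARI, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- contingency_table(a, b)
  n <- sum(tab)
  if (n < 2L) return(1.0)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1.0)  # both partitions trivial
  (sum_ij - expected) / (maximum - expected)
}

#' Normalised mutual information
#'
#' `I(A;B) / mean(H(A), H(B))` with natural-log entropies computed from the
#' contingency table (arithmetic-mean normalisation). In \[0, 1\]; equals 1
#' for identical non-degenerate partitions. When both partitions are
#' trivial (a single cluster each) the value is defined as 1.
#'
#' @inheritParams contingency_table
#' @return NMI in \[0, 1\].
#' @export
normalized_mutual_information <- function(a, b) {
  tab <- contingency_table(a, b)
  n <- sum(tab)
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha == 0 && hb == 0) return(1.0)
  p <- tab / n
  pe <- outer(pa, pb)
  mi <- sum(ifelse(p > 0, p * log(p / pe), 0))
  val <- mi / mean(c(ha, hb))
  min(max(val, 0), 1)
}

#' Count clusters mixing distinct true clades
#'
#' The impurity statistic: the number of clusters at one level whose
#' members carry two or more distinct *known* true names at that rank
#' (unknown true labels are ignored, so pruned labels never create
#' conflicts).
#'
#' @param clusters A `tic_result` (resolved at `rank` via
#'   [cluster_members()]), or a partition (named vector / list of member-id
#'   vectors).
#' @param truth Data frame with column `id` plus the seven rank columns
#'   (true taxonomy), or a named vector id -> true name at `rank`.
#' @param rank `"genus"` or `"family"`.
#' @return Integer count of mixed clusters.
#' @export
count_mixed_clusters <- function(clusters, truth, rank = c("genus", "family")) {
  rank <- match.arg(rank)
  if (inherits(clusters, "tic_result"))
    clusters <- cluster_members(clusters, rank)
  members <- if (is.list(clusters)) clusters else split(names(clusters), as.character(clusters))
  lab <- if (is.data.frame(truth)) setNames(truth[[rank]], truth$id) else truth
  sum(vapply(members, function(m) {
    l <- lab[m]
    length(unique(l[!is.na(l)])) >= 2L
  }, logical(1)))
}
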