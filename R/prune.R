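# Benchmark taxonomy pruning: "hard" (whole-clade removal) and "soft"
# (per-sequence stochastic removal) perturbations of observed taxonomy,
# used to compare taxonomy-aware clustering against naive clustering.

#' Pruning specification
#'
#' Per-rank removal rates for the four prunable ranks. Defaults follow the
#' empirical rates of missing classifications at each level: 10% of genera,
#' 5% of families, 2.5% of orders and 1% of classes. The species rank is
#' never pruned directly; it is erased only transitively when a shallower
#' rank is erased.
#'
#' @param genus,family,order,class Removal rates in \[0, 1\].
#' @param mode `"soft"` (per-sequence stochastic erasure) or `"hard"`
#'   (whole-clade erasure).
#' @param seed Integer seed; both pruning modes are fully reproducible.
#' @return An object of class `prune_spec`.
#' @seealso [hard_prune()], [soft_prune()]
#' @export
prune_spec <- function(genus = 0.10, family = 0.05, order = 0.025,
                       class = 0.01, mode = c("soft", "hard"), seed = 1L) {
  mode <- match.arg(mode)
  rates <- c(genus = unname(genus), family = unname(family),
             order = unname(order), class = unname(class))
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1))
    stop_ticlust("pruning rates must lie in [0, 1]")
  structure(list(rates = rates, mode = mode, seed = as.integer(seed)),
            class = "prune_spec")
}

#' @export
print.prune_spec <- function(x, ...) {
  cat(sprintf("prune_spec: mode=%s seed=%d rates: genus=%g family=%g order=%g class=%g\n",
              x$mode, x$seed, x$rates["genus"], x$rates["family"],
              x$rates["order"], x$rates["class"]))
  invisible(x)
}

# Ranks are erased shallow-to-deep so that an erasure at a shallow rank
# dominates (the deeper draws then erase nothing new). Erasing rank r also
# erases every deeper rank, keeping paths prefix-contiguous.
.PRUNABLE <- c("class", "order", "family", "genus")

#' Hard pruning: remove whole clades from the taxonomy
#'
#' For each prunable rank r (class, order, family, genus), the distinct
#' clades at r (identified by the full path down to r, computed on the
#' *input* taxonomy) are enumerated and `ceiling(rate_r * n_clades)` of them
#' are sampled without replacement; every sequence of a sampled clade loses
#' rank r and all deeper ranks. Simulates genuinely novel taxa. The ceiling
#' guarantees that a positive rate on a small dataset still removes at
#' least one clade.
#'
#' @param x A zOTU data frame with the seven rank columns (see
#'   [read_annotated_fasta()]), or any data frame containing them.
#' @param spec A [prune_spec()] with `mode = "hard"`.
#' @return `x` with pruned rank columns.
#' @export
hard_prune <- function(x, spec) {
  stopifnot(inherits(spec, "prune_spec"))
  if (spec$mode != "hard") stop_ticlust("hard_prune() requires mode = 'hard'")
  orig <- x
  with_seed(spec$seed, {
    for (rank in .PRUNABLE) {
      rate <- spec$rates[[rank]]
      if (rate == 0) next
      ri <- match(rank, .RANKS)
      key <- path_key(orig, ri)
      clades <- sort(unique(key[!is.na(key)]))
      if (length(clades) == 0L) next
      n_rm <- ceiling(rate * length(clades))
      removed <- clades[sample.int(length(clades), n_rm)]
      hit <- !is.na(key) & key %in% removed
      x[hit, .RANKS[ri:7L]] <- NA_character_
    }
  })
  x
}

#' Soft pruning: stochastic per-sequence label removal
#'
#' Independently for every sequence and every prunable rank r, with
#' probability `rate_r` rank r and all deeper ranks are erased. Simulates
#' shortcomings of the classification process. The marginal probability
#' that a sequence loses its rank-r label is
#' `1 - prod(1 - rate_q)` over ranks q at or above r.
#'
#' @inheritParams hard_prune
#' @param spec A [prune_spec()] with `mode = "soft"`.
#' @return `x` with pruned rank columns.
#' @export
soft_prune <- function(x, spec) {
  stopifnot(inherits(spec, "prune_spec"))
  if (spec$mode != "soft") stop_ticlust("soft_prune() requires mode = 'soft'")
  n <- nrow(x)
  with_seed(spec$seed, {
    for (rank in .PRUNABLE) {
      rate <- spec$rates[[rank]]
      ri <- match(rank, .RANKS)
      hit <- runif(n) < rate
      if (any(hit)) x[hit, .RANKS[ri:7L]] <- NA_character_
    }
  })
  x
}
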