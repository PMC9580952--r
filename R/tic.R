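# Taxonomy Informed Clustering (TIC).
#
# Sequences are split by the depth of their classified taxonomy and
# processed in four stages: genus-known sequences are clustered within each
# genus into molecular species (sOTUs); family-known sequences are matched
# against the sOTU centroids of their family and either join, found novel
# sOTUs inside existing genera, or (deferred) build novel sOTUs/gOTUs;
# order-known sequences add the fOTU layer; sequences without a known order
# run the same cascade within their deepest known prefix and receive
# UNKORDER/UNKCLASS/UNKPHYLUM placeholders above their novel fOTUs.
# Clustering never crosses a known taxonomic boundary, so clusters are pure
# by construction at every rank the input knows.

#' Clustering identity cutoffs
#'
#' Defaults are the popular whole-molecule 16S rRNA cutoffs: species 97%,
#' genus 95%, family 90%.
#'
#' @param species,genus,family Identity fractions with
#'   `0 < family < genus < species <= 1`.
#' @return An object of class `tic_cutoffs`.
#' @export
tic_cutoffs <- function(species = 0.97, genus = 0.95, family = 0.90) {
  if (!(family > 0 && family < genus && genus < species && species <= 1))
    stop_ticlust("cutoffs must satisfy 0 < family < genus < species <= 1")
  structure(list(species = species, genus = genus, family = family),
            class = "tic_cutoffs")
}

#' Empty TIC working state
#'
#' Holds the growing sOTU set, the sequence-to-sOTU assignment and the
#' registries that give genus- and family-level clusters their
#' deterministic ids. Stage functions take a state and return the updated
#' state; [run_tic()] wires the stages together and finalises the result.
#'
#' @param cutoffs A [tic_cutoffs()] object.
#' @return An object of class `tic_state`.
#' @export
tic_state <- function(cutoffs = tic_cutoffs()) {
  stopifnot(inherits(cutoffs, "tic_cutoffs"))
  structure(list(
    cutoffs = cutoffs,
    sotu = list(id = character(0), centroid_id = character(0),
                centroid_seq = character(0), size = numeric(0),
                tax = matrix(NA_character_, nrow = 0, ncol = 7,
                             dimnames = list(NULL, .RANKS))),
    seq_to_sotu = setNames(character(0), character(0)),
    counters = c(sotu = 0L, gotu = 0L, fotu = 0L),
    gotu_keys = setNames(character(0), character(0)),
    fotu_keys = setNames(character(0), character(0))
  ), class = "tic_state")
}

# -- internal state helpers --------------------------------------------------

st_new_sotu <- function(state, centroid_id, centroid_seq, tax) {
  state$counters["sotu"] <- state$counters["sotu"] + 1L
  id <- sprintf("sOTU_%d", state$counters["sotu"])
  tax <- as_tax_path(tax)
  tax[["species"]] <- id  # sOTUs are always TIC-defined molecular species
  state$sotu$id <- c(state$sotu$id, id)
  state$sotu$centroid_id <- c(state$sotu$centroid_id, centroid_id)
  state$sotu$centroid_seq <- c(state$sotu$centroid_seq, centroid_seq)
  state$sotu$size <- c(state$sotu$size, 0)
  state$sotu$tax <- rbind(state$sotu$tax, tax)
  if (!is.na(tax[["family"]]) && !is.na(tax[["genus"]]))
    state <- st_register(state, length(state$sotu$id))
  list(state = state, id = id)
}

st_add_member <- function(state, sotu_id, seq_id, size) {
  i <- match(sotu_id, state$sotu$id)
  state$seq_to_sotu[seq_id] <- sotu_id
  state$sotu$size[i] <- state$sotu$size[i] + size
  state
}

# Register the gOTU/fOTU registry keys of an sOTU whose genus and family
# are (now) known. Novel names carry their own id; described taxa get the
# next id from the shared counters.
st_register <- function(state, i) {
  tax <- state$sotu$tax[i, ]
  fkey <- state_key(tax, 5L)
  if (!fkey %in% names(state$fotu_keys)) {
    fam <- tax[["family"]]
    id <- if (grepl("^fOTU_[0-9]+$", fam)) fam else {
      state$counters["fotu"] <- state$counters["fotu"] + 1L
      sprintf("fOTU_%d", state$counters["fotu"])
    }
    state$fotu_keys[fkey] <- id
  }
  gkey <- state_key(tax, 6L)
  if (!gkey %in% names(state$gotu_keys)) {
    gen <- tax[["genus"]]
    id <- if (grepl("^gOTU_[0-9]+$", gen)) gen else {
      state$counters["gotu"] <- state$counters["gotu"] + 1L
      sprintf("gOTU_%d", state$counters["gotu"])
    }
    state$gotu_keys[gkey] <- id
  }
  state
}

st_new_gotu_name <- function(state) {
  state$counters["gotu"] <- state$counters["gotu"] + 1L
  list(state = state, name = sprintf("gOTU_%d", state$counters["gotu"]))
}

st_new_fotu_name <- function(state) {
  state$counters["fotu"] <- state$counters["fotu"] + 1L
  list(state = state, name = sprintf("fOTU_%d", state$counters["fotu"]))
}

# Best centroid hit among sOTU indices `cand`: highest identity, ties by
# larger cluster size then earlier creation. NULL when cand is empty.
st_best_hit <- function(state, cand, seq) {
  if (length(cand) == 0L) return(NULL)
  ident <- nw_identity_many_cpp(seq, state$sotu$centroid_seq[cand])
  best <- max(ident)
  tied <- cand[ident == best]
  if (length(tied) > 1L) tied <- tied[order(-state$sotu$size[tied], tied)]
  list(idx = tied[1L], identity = best)
}

# -- stages ------------------------------------------------------------------

#' Stage 1: cluster genus-known sequences into sOTUs
#'
#' Sequences are partitioned by their full genus path and greedy-clustered
#' within each genus at the species cutoff; every resulting sOTU inherits
#' the genus path plus a novel species name (its own id). Genera are
#' processed in lexicographic path order for deterministic numbering.
#'
#' @param x zOTU data frame; every row must have a known genus.
#' @param state A [tic_state()], or `NULL` to start fresh.
#' @param cutoffs Used only when `state` is `NULL`.
#' @return The updated `tic_state`.
#' @export
cluster_known_genera <- function(x, state = NULL, cutoffs = tic_cutoffs()) {
  state <- state %||% tic_state(cutoffs)
  if (nrow(x) == 0L) return(state)
  if (anyNA(x$genus)) stop_ticlust("cluster_known_genera(): unknown genus present")
  keys <- path_key(x, 6L)
  for (k in sort(unique(keys), method = "radix")) {
    sub <- x[keys == k, , drop = FALSE]
    gc <- greedy_cluster(sub, state$cutoffs$species)
    tax <- as_tax_path(sub[1L, .RANKS])
    for (ci in seq_along(gc$centroids)) {
      cen <- gc$centroids[ci]
      ns <- st_new_sotu(state, cen, sub$seq[match(cen, sub$id)], tax)
      state <- ns$state
      for (m in gc$members[[ci]])
        state <- st_add_member(state, ns$id, m, sub$size[match(m, sub$id)])
    }
  }
  state
}

# Shared placement cascade for sequences with incomplete taxonomy.
# `prefix_upto`: rank index of the deepest known rank of the batch (5 =
# family-known, 4 = order-known, <4 for the unranked bins). Sequences are
# matched against the sOTU centroids sharing the batch prefix:
#   identity >= species cutoff            -> join that sOTU, adopt its path
#   identity >= genus cutoff              -> novel sOTU inside the hit's genus
#   identity >= family cutoff (upto <= 4) -> novel sOTU + novel gOTU inside
#                                            the hit's family
#   otherwise                             -> deferred
# Deferred sequences are greedy-clustered at the species cutoff into novel
# sOTUs, their centroids at the genus cutoff into novel gOTUs, and (when the
# family is unknown) the gOTU centroids at the family cutoff into novel
# fOTUs; ranks still missing above the family are filled with placeholders.
place_batch <- function(state, sub, prefix_upto) {
  co <- state$cutoffs
  prefix_tax <- as_tax_path(sub[1L, .RANKS])
  key <- if (prefix_upto == 0L) "" else paste(prefix_tax[seq_len(prefix_upto)], collapse = "\r")
  allow_family_match <- prefix_upto <= 4L
  sub <- sub[canonical_order(sub), , drop = FALSE]
  deferred <- integer(0)
  for (i in seq_len(nrow(sub))) {
    cand <- which(path_key_lenient(as.data.frame(state$sotu$tax,
                                                 stringsAsFactors = FALSE), prefix_upto) == key)
    hit <- st_best_hit(state, cand, sub$seq[i])
    if (!is.null(hit) && hit$identity >= co$species) {
      state <- st_add_member(state, state$sotu$id[hit$idx], sub$id[i], sub$size[i])
    } else if (!is.null(hit) && hit$identity >= co$genus) {
      tax <- as_tax_path(state$sotu$tax[hit$idx, ])
      tax[["species"]] <- NA_character_
      ns <- st_new_sotu(state, sub$id[i], sub$seq[i], tax)
      state <- st_add_member(ns$state, ns$id, sub$id[i], sub$size[i])
    } else if (!is.null(hit) && allow_family_match && hit$identity >= co$family) {
      tax <- as_tax_path(state$sotu$tax[hit$idx, ])
      tax[c("genus", "species")] <- NA_character_
      ng <- st_new_gotu_name(state)
      tax[["genus"]] <- ng$name
      ns <- st_new_sotu(ng$state, sub$id[i], sub$seq[i], tax)
      state <- st_add_member(ns$state, ns$id, sub$id[i], sub$size[i])
    } else {
      deferred <- c(deferred, i)
    }
  }
  if (length(deferred) == 0L) return(state)

  dsub <- sub[deferred, , drop = FALSE]
  base_tax <- empty_tax_path()
  if (prefix_upto > 0L) base_tax[seq_len(prefix_upto)] <- prefix_tax[seq_len(prefix_upto)]
  gc <- greedy_cluster(dsub, co$species)
  new_idx <- integer(0)
  for (ci in seq_along(gc$centroids)) {
    cen <- gc$centroids[ci]
    ns <- st_new_sotu(state, cen, dsub$seq[match(cen, dsub$id)], base_tax)
    state <- ns$state
    new_idx <- c(new_idx, length(state$sotu$id))
    for (m in gc$members[[ci]])
      state <- st_add_member(state, ns$id, m, dsub$size[match(m, dsub$id)])
  }
  # novel gOTUs: cluster the new sOTU centroids at the genus cutoff
  cdf <- data.frame(id = state$sotu$id[new_idx],
                    seq = state$sotu$centroid_seq[new_idx],
                    size = state$sotu$size[new_idx],
                    stringsAsFactors = FALSE)
  gg <- greedy_cluster(cdf, co$genus)
  gotu_founder <- character(0)
  for (ci in seq_along(gg$centroids)) {
    ng <- st_new_gotu_name(state)
    state <- ng$state
    rows <- new_idx[match(gg$members[[ci]], cdf$id)]
    state$sotu$tax[rows, "genus"] <- ng$name
    gotu_founder[ng$name] <- gg$centroids[ci]
  }
  if (allow_family_match) {
    # novel fOTUs: cluster the gOTU founder centroids at the family cutoff
    gnames <- names(gotu_founder)
    fdf <- data.frame(
      id = gnames,
      seq = state$sotu$centroid_seq[match(gotu_founder, state$sotu$id)],
      size = vapply(gnames, function(g)
        sum(state$sotu$size[new_idx][state$sotu$tax[new_idx, "genus"] == g]),
        numeric(1)),
      stringsAsFactors = FALSE)
    ff <- greedy_cluster(fdf, co$family)
    for (ci in seq_along(ff$centroids)) {
      nf <- st_new_fotu_name(state)
      state <- nf$state
      rows <- new_idx[state$sotu$tax[new_idx, "genus"] %in% ff$members[[ci]]]
      state$sotu$tax[rows, "family"] <- nf$name
    }
    # placeholders for ranks above family that the batch prefix left unknown
    for (r in seq_len(4L)) {
      if (r <= prefix_upto) next
      rank <- .RANKS[r]
      if (rank %in% names(.PLACEHOLDERS))
        state$sotu$tax[new_idx, rank] <- .PLACEHOLDERS[[rank]]
    }
  }
  for (i in new_idx) state <- st_register(state, i)
  state
}

#' Stage 2: place family-known sequences
#'
#' Sequences with a known family but unknown genus are matched, family by
#' family (lexicographic path order), against the sOTU centroids of their
#' family: a hit at or above the species cutoff joins that sOTU and adopts
#' its full taxonomy; a hit between the genus and species cutoffs founds a
#' novel sOTU inside the hit's genus; sequences without a hit at the genus
#' cutoff are deferred and clustered into novel sOTUs and novel gOTUs
#' within the family.
#'
#' @inheritParams cluster_known_genera
#' @param x zOTU data frame; known family, unknown genus.
#' @return The updated `tic_state`.
#' @export
place_family_level <- function(x, state = NULL, cutoffs = tic_cutoffs()) {
  state <- state %||% tic_state(cutoffs)
  if (nrow(x) == 0L) return(state)
  if (anyNA(x$family)) stop_ticlust("place_family_level(): unknown family present")
  keys <- path_key(x, 5L)
  for (k in sort(unique(keys), method = "radix"))
    state <- place_batch(state, x[keys == k, , drop = FALSE], 5L)
  state
}

#' Stage 3: place order-known sequences
#'
#' Like [place_family_level()] but one layer up: sequences with a known
#' order and unknown family are matched against all sOTU centroids of their
#' order, with the added `[family, genus)` rule (novel sOTU plus novel gOTU
#' inside the hit's family) and, for deferred sequences, the added
#' family-cutoff clustering of novel gOTU centroids into novel fOTUs.
#'
#' @inheritParams cluster_known_genera
#' @param x zOTU data frame; known order, unknown family.
#' @return The updated `tic_state`.
#' @export
place_order_level <- function(x, state = NULL, cutoffs = tic_cutoffs()) {
  state <- state %||% tic_state(cutoffs)
  if (nrow(x) == 0L) return(state)
  if (anyNA(x$order)) stop_ticlust("place_order_level(): unknown order present")
  keys <- path_key(x, 4L)
  for (k in sort(unique(keys), method = "radix"))
    state <- place_batch(state, x[keys == k, , drop = FALSE], 4L)
  state
}

#' Stage 4: place sequences without a known order
#'
#' Sequences are binned by their deepest known rank (class, phylum, domain
#' or nothing), deepest bins first; within each bin the order-level cascade
#' runs against the sOTUs sharing the known prefix. Novel fOTU chains get
#' UNKORDER (and UNKCLASS, UNKPHYLUM as needed) placeholders above the
#' family rank.
#'
#' @inheritParams cluster_known_genera
#' @param x zOTU data frame; unknown order.
#' @return The updated `tic_state`.
#' @export
place_unranked <- function(x, state = NULL, cutoffs = tic_cutoffs()) {
  state <- state %||% tic_state(cutoffs)
  if (nrow(x) == 0L) return(state)
  depth <- apply(!is.na(as.matrix(x[, .RANKS, drop = FALSE])), 1L, function(r)
    if (!any(r)) 0L else max(which(r)))
  if (any(depth >= 4L)) stop_ticlust("place_unranked(): order-known sequence present")
  for (d in c(3L, 2L, 1L, 0L)) {
    bin <- x[depth == d, , drop = FALSE]
    if (nrow(bin) == 0L) next
    keys <- path_key(bin, d)
    for (k in sort(unique(keys), method = "radix"))
      state <- place_batch(state, bin[keys == k, , drop = FALSE], d)
  }
  state
}

# -- orchestration -----------------------------------------------------------

#' Run Taxonomy Informed Clustering
#'
#' Partitions the input by taxonomy depth (genus-known, family-known,
#' order-known, deeper-unknown), runs the four placement stages in that
#' order, and assembles the nested sOTU/gOTU/fOTU result. Fully
#' deterministic: independent of input row order.
#'
#' @param x zOTU data frame (see [read_annotated_fasta()]): columns `id`,
#'   `seq`, `size` and the seven rank columns, with unique ids and
#'   prefix-contiguous taxonomy.
#' @param cutoffs A [tic_cutoffs()] object.
#' @return An object of class `tic_result`: list with cluster tables
#'   `sotus`, `gotus`, `fotus` (id, centroid_id, size/n members, novelty
#'   flag, taxonomy), mappings `seq_to_sotu`, `sotu_to_gotu`,
#'   `gotu_to_fotu` (named character vectors), and `updated_taxonomy`
#'   (data frame, one row per input sequence, input taxonomy deepened by
#'   match adoption and novel names).
#' @export
run_tic <- function(x, cutoffs = tic_cutoffs()) {
  if (is.null(x) || nrow(x) == 0L) stop_ticlust("empty input dataset")
  if (anyDuplicated(x$id))
    stop_ticlust("duplicate sequence ids: ", x$id[duplicated(x$id)][1L])
  if (any(!nzchar(x$seq))) stop_ticlust("empty sequence present")
  check_contiguous(x[, .RANKS, drop = FALSE], x$id)
  state <- tic_state(cutoffs)
  gk <- !is.na(x$genus)
  fk <- !gk & !is.na(x$family)
  ok <- !gk & !fk & !is.na(x$order)
  uk <- !gk & !fk & !ok
  state <- cluster_known_genera(x[gk, , drop = FALSE], state)
  state <- place_family_level(x[fk, , drop = FALSE], state)
  state <- place_order_level(x[ok, , drop = FALSE], state)
  state <- place_unranked(x[uk, , drop = FALSE], state)
  finalize_tic(state, x)
}

#' Assemble a `tic_result` from a finished state
#'
#' @param state A `tic_state` after all stages have run.
#' @param x The input zOTU data frame.
#' @return A `tic_result`; see [run_tic()].
#' @export
finalize_tic <- function(state, x) {
  so <- state$sotu
  n_sotu <- length(so$id)
  sotu_tax <- as.data.frame(so$tax, stringsAsFactors = FALSE)
  sotus <- data.frame(id = so$id, centroid_id = so$centroid_id,
                      size = so$size,
                      n_members = as.integer(table(factor(state$seq_to_sotu, levels = so$id))),
                      novel = rep(TRUE, n_sotu), sotu_tax,
                      stringsAsFactors = FALSE, row.names = NULL)

  if (anyNA(sotu_tax$genus) || anyNA(sotu_tax$family))
    stop_ticlust("internal error: sOTU with unresolved genus/family at finalize")
  gkeys <- path_key_lenient(sotu_tax, 6L)
  fkeys <- path_key_lenient(sotu_tax, 5L)

  build_level <- function(registry, keys, upto, prefix) {
    ids <- unname(registry)
    rows <- lapply(names(registry), function(k) {
      members <- which(keys == k)
      first <- members[1L]
      tax <- empty_tax_path()
      tax[seq_len(upto)] <- as_tax_path(sotu_tax[first, ])[seq_len(upto)]
      c(list(centroid_id = so$centroid_id[first],
             size = sum(so$size[members]),
             n_members = length(members),
             novel = grepl(paste0("^", prefix, "OTU_[0-9]+$"), tax[[upto]])),
        as.list(tax))
    })
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    cbind(data.frame(id = ids, stringsAsFactors = FALSE), df)
  }
  gotus <- build_level(state$gotu_keys, gkeys, 6L, "g")
  fotus <- build_level(state$fotu_keys, fkeys, 5L, "f")

  sotu_to_gotu <- setNames(unname(state$gotu_keys[gkeys]), so$id)
  gotu_to_fotu <- setNames(
    unname(state$fotu_keys[vapply(names(state$gotu_keys), function(k)
      paste(strsplit(k, "\r", fixed = TRUE)[[1L]][1:5], collapse = "\r"),
      character(1))]),
    unname(state$gotu_keys))

  # updated taxonomy: keep known input ranks, fill unknown ones from the sOTU
  upd <- x[order(x$id, method = "radix"), c("id", .RANKS), drop = FALSE]
  sidx <- match(state$seq_to_sotu[upd$id], so$id)
  for (r in seq_along(.RANKS)) {
    col <- upd[[.RANKS[r]]]
    fill <- is.na(col)
    col[fill] <- so$tax[sidx[fill], r]
    upd[[.RANKS[r]]] <- col
  }
  rownames(upd) <- NULL

  structure(list(sotus = sotus, gotus = gotus, fotus = fotus,
                 seq_to_sotu = state$seq_to_sotu[sort(names(state$seq_to_sotu), method = "radix")],
                 sotu_to_gotu = sotu_to_gotu,
                 gotu_to_fotu = gotu_to_fotu,
                 updated_taxonomy = upd,
                 cutoffs = state$cutoffs),
            class = "tic_result")
}

#' @export
print.tic_result <- function(x, ...) {
  cat(sprintf("tic_result: %d sequences -> %d sOTUs, %d gOTUs, %d fOTUs\n",
              length(x$seq_to_sotu), nrow(x$sotus), nrow(x$gotus), nrow(x$fotus)))
  cat(sprintf("  cutoffs: species %.2f, genus %.2f, family %.2f\n",
              x$cutoffs$species, x$cutoffs$genus, x$cutoffs$family))
  cat(sprintf("  novel: %d gOTUs, %d fOTUs\n",
              sum(x$gotus$novel), sum(x$fotus$novel)))
  invisible(x)
}

#' Member sequence ids of every cluster at one level
#'
#' @param result A `tic_result`.
#' @param level `"species"`, `"genus"` or `"family"`.
#' @return Named list: cluster id -> character vector of member sequence ids.
#' @export
cluster_members <- function(result, level = c("species", "genus", "family")) {
  level <- match.arg(level)
  assign <- switch(level,
    species = result$seq_to_sotu,
    genus   = setNames(unname(result$sotu_to_gotu[result$seq_to_sotu]),
                       names(result$seq_to_sotu)),
    family  = setNames(unname(result$gotu_to_fotu[result$sotu_to_gotu[result$seq_to_sotu]]),
                       names(result$seq_to_sotu)))
  split(names(assign), assign)
}
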