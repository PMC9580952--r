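# Seeded synthetic 16S-fragment community generator with planted taxonomic
# structure. Divergence tiers are aligned to the 97/95/90% clustering
# cutoffs with guard bands, so parameter-recovery tests are exact rather
# than statistical.
#
# Construction: one random root per order. Family roots differ from each
# other only inside a reserved "barcode" block of positions, where each
# family carries a random word kept (by seeded rejection) at a pairwise
# Hamming distance inside a window whose floor alone guarantees
# cross-family identity below the family-cutoff guard band - no matter how
# the descendant mutations collide. Below each family, every edge (genus,
# species, zOTU) mutates a position set disjoint from every other edge set
# in the same family and from the barcode block, so all within-family
# pairwise divergences are exact sums of edge sizes. An exhaustive
# post-hoc Hamming audit re-checks every guard band.

#' Parameters of the synthetic community
#'
#' The default tier intervals are pairwise substitution fractions chosen so
#' that the standard cutoffs separate the tiers with a guard band of at
#' least 0.005: same species > 97.5% identity; same genus, different
#' species within 95.5-96.5%; same family, different genus within
#' 90.5-94.5%; different families below 89.5%. The family tier is realised
#' through a reserved barcode block whose minimum pairwise distance alone
#' keeps every cross-family pair below the guard band, which requires a
#' wider divergence interval (default up to 0.22) than the shallower tiers.
#'
#' @param n_families,genera_per_family,species_per_genus,zotus_per_species
#'   Positive integers shaping the planted lineage tree.
#' @param seq_length Fragment length in nt (default 300, the scale of an
#'   extracted 16S V-region).
#' @param within_species Maximum pairwise divergence among zOTUs of one
#'   species (default 0.01).
#' @param between_species,between_genera,between_families Closed intervals
#'   of pairwise divergence for the three higher tiers.
#' @param n_samples Number of samples for the abundance table (default 10).
#' @param dispersion Log-normal abundance dispersion (sdlog; default 1;
#'   0 gives equal counts).
#' @param seed Integer seed; the whole community is reproducible from it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_families = 20L, genera_per_family = 5L,
                       species_per_genus = 5L, zotus_per_species = 3L,
                       seq_length = 300L,
                       within_species = 0.01,
                       between_species = c(0.035, 0.045),
                       between_genera = c(0.06, 0.09),
                       between_families = c(0.12, 0.22),
                       n_samples = 10L, dispersion = 1, seed = 42L) {
  p <- list(n_families = as.integer(n_families),
            genera_per_family = as.integer(genera_per_family),
            species_per_genus = as.integer(species_per_genus),
            zotus_per_species = as.integer(zotus_per_species),
            seq_length = as.integer(seq_length),
            within_species = within_species,
            between_species = between_species,
            between_genera = between_genera,
            between_families = between_families,
            n_samples = as.integer(n_samples),
            dispersion = dispersion, seed = as.integer(seed))
  if (any(unlist(p[1:5]) < 1L)) stop_ticlust("tree shape parameters must be positive")
  tiers <- c(p$within_species, p$between_species, p$between_genera, p$between_families)
  if (any(diff(tiers) <= 0))
    stop_ticlust("divergence tiers must be strictly ordered and non-overlapping")
  edges <- tier_edge_sizes(p)  # validates feasibility
  p$edges <- edges
  structure(p, class = "sim_params")
}

# Translate pairwise-divergence tiers into per-edge substitution counts.
# A pair in tier t differs at the sum of the (disjoint) edge sets on the
# two paths from their last common ancestor, so per-edge counts are half
# the pairwise target, corrected for the deeper edges' contributions.
tier_edge_sizes <- function(p) {
  L <- p$seq_length
  m_z <- floor(p$within_species * L / 2)
  m_s <- round(mean(p$between_species) * L / 2) - m_z
  if (m_s < 1L)
    stop_ticlust("seq_length too short to separate species tier; increase seq_length")
  sp_pair <- 2 * (m_s + m_z)
  if (sp_pair < p$between_species[1] * L || sp_pair > p$between_species[2] * L)
    stop_ticlust("between_species tier infeasible at this seq_length")
  g_lo <- ceiling((p$between_genera[1] * L - sp_pair) / 2)
  g_hi <- floor((p$between_genera[2] * L - sp_pair) / 2)
  if (g_lo > g_hi || g_lo < 1L)
    stop_ticlust("between_genera tier infeasible at this seq_length")
  # family barcode block: the code-distance floor alone must guarantee
  # cross-family identity below (family cutoff - guard band), because
  # descendant mutations of two families can in principle collide entirely
  guard <- 0.005
  code_lo <- max(ceiling((1 - (tic_cutoffs()$family - guard)) * L),
                 ceiling(p$between_families[1] * L) - 2L * (g_lo + m_s + m_z))
  code_hi <- floor(p$between_families[2] * L) - 2L * (g_hi + m_s + m_z)
  if (code_lo > code_hi)
    stop_ticlust("between_families tier infeasible at this seq_length")
  u <- round(2 * (code_lo + code_hi) / 3)  # random words average 3/4 * u apart
  u <- max(u, code_lo + 2L)
  # barcode block plus the positions below one family edge must fit in L
  need <- u + p$genera_per_family * g_hi +
    p$genera_per_family * p$species_per_genus * m_s +
    p$genera_per_family * p$species_per_genus * p$zotus_per_species * m_z
  if (need > L)
    stop_ticlust("tier separation needs ", need, " distinct positions but ",
                 "seq_length is ", L, "; increase seq_length")
  list(m_z = m_z, m_s = m_s, g_lo = g_lo, g_hi = g_hi,
       code_lo = code_lo, code_hi = code_hi, u = u)
}

#' Planted lineage tree
#'
#' Deterministically named families, genera and species (one synthetic
#' domain/phylum/class/order above them), with one leaf row per zOTU
#' carrying its full 7-rank true taxonomy.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `synthetic_truth`: list with `taxonomy`
#'   (data frame: `id` + the seven rank columns, one row per zOTU),
#'   `tree` (leaf table with family/genus/species indices) and `counts`
#'   (planted numbers of families, genera and species).
#' @export
simulate_lineages <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  Fn <- params$n_families; G <- params$genera_per_family
  S <- params$species_per_genus; Z <- params$zotus_per_species
  grid <- expand.grid(z = seq_len(Z), s = seq_len(S), g = seq_len(G),
                      f = seq_len(Fn))
  grid <- grid[, c("f", "g", "s", "z")]
  fam <- sprintf("Fam%02d", grid$f)
  gen <- sprintf("%s_Gen%02d", fam, grid$g)
  spc <- sprintf("%s_Sp%02d", gen, grid$s)
  id <- sprintf("zotu_%05d", seq_len(nrow(grid)))
  taxonomy <- data.frame(id = id,
                         domain = "Bacteria", phylum = "SimPhylum",
                         class = "SimClass", order = "SimOrder",
                         family = fam, genus = gen, species = spc,
                         stringsAsFactors = FALSE)
  structure(list(taxonomy = taxonomy,
                 tree = cbind(grid, data.frame(id = id, family = fam,
                                               genus = gen, species = spc,
                                               stringsAsFactors = FALSE)),
                 counts = c(families = Fn, genera = Fn * G,
                            species = Fn * G * S)),
            class = "synthetic_truth")
}

mutate_positions <- function(seq_chars, pos) {
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- bases[bases != seq_chars[p]]
    seq_chars[p] <- alt[sample.int(3L, 1L)]
  }
  seq_chars
}

#' Evolve sequences down the planted tree
#'
#' One random root per order; families differ inside a reserved barcode
#' block at a guaranteed pairwise distance; each genus, species and zOTU
#' edge substitutes a drawn number of distinct positions (without
#' replacement, no back-mutation within a family subtree by construction).
#' Realised pairwise identities are audited exhaustively against the tier
#' guard bands; a violating community is regenerated (bounded retries).
#'
#' @param truth A [simulate_lineages()] result.
#' @param params The matching [sim_params()].
#' @return zOTU data frame: `id`, `seq`, `size` (1), and the seven rank
#'   columns holding the true taxonomy.
#' @export
evolve_sequences <- function(truth, params) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(params, "sim_params"))
  for (attempt in seq_len(5L)) {
    x <- with_seed(params$seed + (attempt - 1L) * 7919L,
                   evolve_once(truth, params))
    aud <- audit_tiers(x, truth, params)
    if (aud$ok) {
      attr(x, "tier_audit") <- aud$ranges
      return(x)
    }
  }
  stop_ticlust("tier guard bands could not be met after 5 attempts; ",
               "increase seq_length")
}

evolve_once <- function(truth, params) {
  L <- params$seq_length
  e <- params$edges
  Fn <- params$n_families; G <- params$genera_per_family
  S <- params$species_per_genus; Z <- params$zotus_per_species
  bases <- c("A", "C", "G", "T")
  root <- bases[sample.int(4L, L, replace = TRUE)]
  block <- sample.int(L, e$u)  # family barcode block
  # family words: seeded rejection keeps every pairwise Hamming distance
  # inside [code_lo, code_hi]
  words <- matrix(NA_character_, nrow = Fn, ncol = e$u)
  for (f in seq_len(Fn)) {
    ok <- FALSE
    for (try in seq_len(5000L)) {
      w <- bases[sample.int(4L, e$u, replace = TRUE)]
      if (f == 1L) { ok <- TRUE } else {
        d <- apply(words[seq_len(f - 1L), , drop = FALSE], 1L,
                   function(prev) sum(prev != w))
        ok <- all(d >= e$code_lo & d <= e$code_hi)
      }
      if (ok) { words[f, ] <- w; break }
    }
    if (!ok)
      stop_ticlust("could not place ", Fn, " family barcodes at the ",
                   "required distances; increase seq_length")
  }
  seqs <- character(Fn * G * S * Z)
  k <- 0L
  for (f in seq_len(Fn)) {
    fam_seq <- root
    fam_seq[block] <- words[f, ]
    m_g <- if (e$g_lo == e$g_hi) rep(e$g_lo, G) else
      sample(e$g_lo:e$g_hi, G, replace = TRUE)
    need <- sum(m_g) + G * S * e$m_s + G * S * Z * e$m_z
    pool <- setdiff(seq_len(L), block)
    pool <- pool[sample.int(length(pool), need)]
    off <- 0L
    for (g in seq_len(G)) {
      gen_seq <- mutate_positions(fam_seq, pool[seq_len(m_g[g]) + off])
      off <- off + m_g[g]
      for (s in seq_len(S)) {
        sp_seq <- mutate_positions(gen_seq, pool[seq_len(e$m_s) + off])
        off <- off + e$m_s
        for (z in seq_len(Z)) {
          zs <- if (e$m_z > 0L) {
            out <- mutate_positions(sp_seq, pool[seq_len(e$m_z) + off])
            off <- off + e$m_z
            out
          } else sp_seq
          k <- k + 1L
          seqs[k] <- paste(zs, collapse = "")
        }
      }
    }
  }
  out <- truth$taxonomy
  out$seq <- seqs
  out$size <- 1L
  out[, c("id", "seq", "size", .RANKS)]
}

# Exhaustive pairwise identity audit, stratified by planted tier. Hamming
# identity is exact for the substitution-only model; because an optimal
# global alignment can only match MORE columns (realigning around
# substitution runs), the band edges that alignment lift could cross - the
# upper edges of the three cross-clade tiers and the lower edge of the
# within-species tier - are re-verified with the full alignment identity
# on the extreme pairs of each tier.
audit_tiers <- function(x, truth, params) {
  tr <- truth$tree
  fam <- as.integer(factor(tr$family))
  gen <- as.integer(factor(tr$genus))
  sp <- as.integer(factor(tr$species))
  rng <- tier_identity_range_cpp(x$seq, fam, gen, sp)
  rownames(rng) <- c("within_species", "between_species", "between_genera",
                     "between_families")
  colnames(rng) <- c("min", "max", "n_pairs")
  guard <- 0.005
  co <- tic_cutoffs()
  ok <- TRUE
  chk <- function(cond) if (!isTRUE(cond) && !is.na(cond)) ok <<- FALSE
  if (!is.na(rng[1, 1])) chk(rng[1, 1] >= co$species + guard)
  if (!is.na(rng[2, 1])) {
    chk(rng[2, 2] <= co$species - guard)
    chk(rng[2, 1] >= co$genus + guard)
  }
  if (!is.na(rng[3, 1])) {
    chk(rng[3, 2] <= co$genus - guard)
    chk(rng[3, 1] >= co$family + guard)
  }
  if (!is.na(rng[4, 1])) chk(rng[4, 2] <= co$family - guard)
  if (ok) {
    ext <- tier_extreme_pairs_cpp(x$seq, fam, gen, sp, 25L)
    upper <- c(NA, co$species - guard, co$genus - guard, co$family - guard)
    for (r in seq_len(nrow(ext))) {
      t <- ext[r, 1] + 1L
      nw <- nw_identity_cpp(x$seq[ext[r, 2]], x$seq[ext[r, 3]])
      if (t == 1L) chk(nw >= co$species + guard)
      else chk(nw <= upper[t])
    }
  }
  list(ok = ok, ranges = rng)
}

#' Simulate a per-sample abundance table
#'
#' Heavy-tailed log-normal counts (meanlog = log(100), sdlog =
#' `dispersion`), integerised with a floor of 1 so every sequence is
#' present in every sample (the whole community is the designated presence
#' set).
#'
#' @param x zOTU data frame.
#' @param params A [sim_params()] object.
#' @return Integer matrix, rows = sequence ids, columns = samples.
#' @export
simulate_counts <- function(x, params) {
  stopifnot(inherits(params, "sim_params"))
  n <- nrow(x); s <- params$n_samples
  counts <- with_seed(params$seed + 1000003L, {
    m <- matrix(rlnorm(n * s, meanlog = log(100), sdlog = params$dispersion),
                nrow = n, ncol = s)
    matrix(pmax(1L, as.integer(round(m))), nrow = n, ncol = s)
  })
  dimnames(counts) <- list(x$id, sprintf("sample_%02d", seq_len(s)))
  counts
}

#' Generate a complete synthetic benchmark
#'
#' Composes [simulate_lineages()], [evolve_sequences()] and
#' [simulate_counts()], then optionally prunes the *observed* taxonomy
#' while keeping the unpruned truth. The default parameters are the
#' standard acceptance fixture: 20 families x 5 genera x 5 species x
#' 3 zOTUs = 1,500 sequences.
#'
#' @param params A [sim_params()] object.
#' @param prune A [prune_spec()], or `NULL` for no pruning.
#' @return List with `dataset` (zOTU data frame; observed, possibly pruned
#'   taxonomy; `size` = abundance row sums), `truth`
#'   (a `synthetic_truth`) and `counts` (abundance matrix).
#' @export
make_benchmark <- function(params = sim_params(), prune = NULL) {
  truth <- simulate_lineages(params)
  x <- evolve_sequences(truth, params)
  counts <- simulate_counts(x, params)
  x$size <- as.integer(rowSums(counts))
  if (!is.null(prune)) {
    x <- switch(prune$mode,
                hard = hard_prune(x, prune),
                soft = soft_prune(x, prune))
  }
  list(dataset = x, truth = truth, counts = counts)
}
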