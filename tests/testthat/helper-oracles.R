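# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive every quantity through a different route
# than the package (R matrix DP vs C++ kernel, pair counting vs
# contingency-table formulas, direct recounts vs incremental state).

# Needleman-Wunsch identity oracle: full score matrix in R, same pinned
# scoring (match +1 / mismatch -1 / gap -2), traceback preferring
# substitution, then a gap consuming the first sequence; identity excludes
# terminal gap columns; N never matches. Operands are ordered canonically
# (shorter, then lexicographically smaller first) exactly as the package
# pins them, so the tie rule cannot break symmetry.
oracle_nw_identity <- function(a, b) {
  if (nchar(a) > nchar(b) ||
      (nchar(a) == nchar(b) && sort(c(a, b), method = "radix")[1L] != a)) {
    tmp <- a; a <- b; b <- tmp
  }
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  S <- matrix(0L, n + 1L, m + 1L)
  S[1L, ] <- -2L * (0:m); S[, 1L] <- -2L * (0:n)
  sc <- function(i, j) if (A[i] == B[j] && A[i] != "N") 1L else -1L
  for (i in seq_len(n)) for (j in seq_len(m))
    S[i + 1L, j + 1L] <- max(S[i, j] + sc(i, j), S[i, j + 1L] - 2L,
                             S[i + 1L, j] - 2L)
  i <- n; j <- m; cols <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && S[i + 1L, j + 1L] == S[i, j] + sc(i, j)) {
      cols <- c(if (A[i] == B[j] && A[i] != "N") "M" else "X", cols)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] - 2L) {
      cols <- c("G", cols); i <- i - 1L
    } else {
      cols <- c("G", cols); j <- j - 1L
    }
  }
  s <- 1L; e <- length(cols)
  while (s <= e && cols[s] == "G") s <- s + 1L
  while (e >= s && cols[e] == "G") e <- e - 1L
  if (e < s) return(0)
  sum(cols[s:e] == "M") / (e - s + 1L)
}

# ARI oracle: explicit O(n^2) pair counting (Hubert-Arabie identity),
# no contingency table.
oracle_ari <- function(a, b) {
  ids <- names(a); b <- b[ids]; n <- length(ids)
  if (n < 2L) return(1)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  denom <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (denom == 0) return(1)
  2 * (s11 * s00 - s10 * s01) / denom
}

# NMI oracle: explicit loops over label pairs.
oracle_nmi <- function(a, b) {
  ids <- names(a); b <- b[ids]; n <- length(ids)
  la <- unique(a); lb <- unique(b)
  pa <- vapply(la, function(x) sum(a == x) / n, numeric(1))
  pb <- vapply(lb, function(x) sum(b == x) / n, numeric(1))
  ha <- -sum(pa * log(pa)); hb <- -sum(pb * log(pb))
  if (ha == 0 && hb == 0) return(1)
  mi <- 0
  for (x in la) for (y in lb) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (pa[[x]] * pb[[y]]))
  }
  mi / mean(c(ha, hb))
}

random_partition <- function(n, k, ids = sprintf("s%03d", seq_len(n))) {
  setNames(as.character(sample.int(k, n, replace = TRUE)), ids)
}

rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")

# Deterministic mutation: rotates the base (A->C->G->T->A) at the given
# positions, so the result always differs from the input there, and two
# rotations of disjoint position sets differ at their union.
rotate_at <- function(seq, pos) {
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  ch <- strsplit(seq, "")[[1L]]
  ch[pos] <- rot[ch[pos]]
  paste(ch, collapse = "")
}

# k isolated positions spread evenly over 1..L. Isolated substitutions
# cannot be absorbed by gapped realignment (a gap pair costs more than it
# can recover), so rotate_at() at spread positions yields an alignment
# identity of exactly (L - k) / L.
spread_pos <- function(L, k, phase = 0L) {
  p <- unique(round(seq(1 + phase, L - 1, length.out = k)))
  stopifnot(length(p) == k)
  p
}

make_zotu <- function(id, seq, size = 1L, tax = NULL) {
  row <- data.frame(id = id, seq = seq, size = rep_len(size, length(id)),
                    stringsAsFactors = FALSE)
  tm <- matrix(NA_character_, nrow = length(id), ncol = 7L,
               dimnames = list(NULL, tax_ranks()))
  if (!is.null(tax)) {
    tax <- as.matrix(tax)
    tm[, colnames(tax)] <- tax
  }
  cbind(row, as.data.frame(tm, stringsAsFactors = FALSE))
}

# Full 7-rank path row builder for dataset taxonomy columns.
full_tax <- function(domain = "Bacteria", phylum = "P1", class = "C1",
                     order = "O1", family = "F1", genus = "G1",
                     species = "S1") {
  cbind(domain = domain, phylum = phylum, class = class, order = order,
        family = family, genus = genus, species = species)
}

random_tax_path <- function() {
  depth <- sample(0:7, 1L)
  p <- empty_tax_path()
  if (depth > 0L)
    p[seq_len(depth)] <- paste0(substr(tax_ranks()[seq_len(depth)], 1, 2),
                                sample.int(1000L, depth))
  p
}

small_params <- function(seed = 7L, ...) {
  sim_params(n_families = 4L, genera_per_family = 3L, species_per_genus = 3L,
             zotus_per_species = 2L, seed = seed, ...)
}
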