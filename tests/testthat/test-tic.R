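# Constructed-sequence tests for the four TIC stages, plus whole-pipeline
# invariants on small synthetic benchmarks. Identities of constructed
# pairs are exact: rotating k distinct positions of an L-mer gives
# identity (L - k) / L, verified against global_identity() where it
# matters.

base300 <- local({ set.seed(71); rand_seq(300) })

test_that("cluster_known_genera clusters within each genus only", {
  g1 <- full_tax(genus = "G1"); g2 <- full_tax(genus = "G2")
  x <- rbind(
    make_zotu("a1", base300, 10L, g1),
    make_zotu("a2", rotate_at(base300, spread_pos(300, 3)), 8L, g1),     # 0.99
    make_zotu("b1", rotate_at(base300, spread_pos(300, 3, 2L)), 9L, g2), # 0.99, other genus
    make_zotu("b2", rotate_at(base300, spread_pos(300, 5, 4L)), 7L, g2))
  st <- cluster_known_genera(x)
  res <- finalize_tic(st, x)
  expect_equal(nrow(res$sotus), 2L)  # one per genus, never merged cross-genus
  expect_equal(nrow(res$gotus), 2L)
  expect_equal(res$seq_to_sotu[["a1"]], res$seq_to_sotu[["a2"]])
  expect_false(res$seq_to_sotu[["a1"]] == res$seq_to_sotu[["b1"]])

  # two 96%-identical sequences in one genus -> 2 sOTUs
  y <- rbind(make_zotu("c1", base300, 5L, g1),
             make_zotu("c2", rotate_at(base300, spread_pos(300, 12)), 4L, g1))
  expect_equal(global_identity(y$seq[1], y$seq[2]), 0.96)
  res2 <- finalize_tic(cluster_known_genera(y), y)
  expect_equal(nrow(res2$sotus), 2L)
  expect_equal(nrow(res2$gotus), 1L)

  expect_error(cluster_known_genera(make_zotu("u", base300, 1L,
                                              full_tax(genus = NA))),
               "unknown genus")
})

test_that("place_family_level joins, adopts, creates and defers correctly", {
  g1 <- full_tax(genus = "G1", species = "Sp1")
  seed <- make_zotu("seed", base300, 20L, g1)
  fam <- full_tax(genus = NA, species = NA)

  st <- cluster_known_genera(seed)
  defApos <- spread_pos(300, 30, 3L)
  extra12 <- setdiff(spread_pos(300, 40, 7L), defApos)[1:12]
  x <- rbind(
    make_zotu("join98", rotate_at(base300, spread_pos(300, 6)), 5L, fam),     # 0.98 -> joins
    make_zotu("novel96", rotate_at(base300, spread_pos(300, 12, 1L)), 4L, fam), # 0.96 -> novel sOTU in G1
    make_zotu("defA", rotate_at(base300, defApos), 6L, fam),                  # 0.90 -> deferred
    make_zotu("defB", rotate_at(base300, c(defApos, extra12)), 3L, fam))      # 0.96 to defA
  expect_equal(global_identity(seed$seq, x$seq[1]), 0.98)
  expect_equal(global_identity(seed$seq, x$seq[2]), 0.96)
  expect_equal(global_identity(seed$seq, x$seq[3]), 0.90)
  expect_equal(global_identity(x$seq[3], x$seq[4]), 0.96)
  st <- place_family_level(x, st)
  res <- finalize_tic(st, rbind(seed, x))

  # join98 joined the seed sOTU and adopted its full taxonomy
  expect_equal(res$seq_to_sotu[["join98"]], res$seq_to_sotu[["seed"]])
  upd <- res$updated_taxonomy
  expect_equal(upd$genus[upd$id == "join98"], "G1")
  # novel96 founded a new sOTU inside genus G1
  expect_false(res$seq_to_sotu[["novel96"]] == res$seq_to_sotu[["seed"]])
  expect_equal(upd$genus[upd$id == "novel96"], "G1")
  # deferred pair: 2 novel sOTUs under 1 novel gOTU in the family
  expect_false(res$seq_to_sotu[["defA"]] == res$seq_to_sotu[["defB"]])
  gA <- res$sotu_to_gotu[[res$seq_to_sotu[["defA"]]]]
  gB <- res$sotu_to_gotu[[res$seq_to_sotu[["defB"]]]]
  expect_equal(gA, gB)
  expect_true(is_novel_name(upd$genus[upd$id == "defA"]))
  expect_equal(nrow(res$gotus), 2L)
  expect_equal(nrow(res$fotus), 1L)

  expect_error(place_family_level(make_zotu("q", base300, 1L,
                                            full_tax(family = NA, genus = NA))),
               "unknown family")
})

test_that("place_order_level adds the fOTU layer", {
  g1 <- full_tax(genus = "G1", species = "Sp1")
  seed <- make_zotu("seed", base300, 20L, g1)
  ord <- full_tax(family = NA, genus = NA, species = NA)
  st <- cluster_known_genera(seed)

  x <- rbind(
    make_zotu("gotu93", rotate_at(base300, spread_pos(300, 21)), 5L, ord),     # 0.93 -> novel gOTU in F1
    make_zotu("fotu85", rotate_at(base300, spread_pos(300, 45, 2L)), 4L, ord)) # 0.85 -> novel fOTU
  expect_equal(global_identity(seed$seq, x$seq[1]), 0.93)
  expect_equal(global_identity(seed$seq, x$seq[2]), 0.85)
  st <- place_order_level(x, st)
  res <- finalize_tic(st, rbind(seed, x))
  upd <- res$updated_taxonomy

  expect_equal(upd$family[upd$id == "gotu93"], "F1")  # adopted hit's family
  expect_true(is_novel_name(upd$genus[upd$id == "gotu93"]))
  expect_true(is_novel_name(upd$family[upd$id == "fotu85"]))
  expect_equal(nrow(res$fotus), 2L)

  # degenerate: single order-known sequence, empty state -> full novel chain
  solo <- make_zotu("solo", base300, 1L, ord)
  res1 <- finalize_tic(place_order_level(solo), solo)
  expect_equal(nrow(res1$sotus), 1L)
  expect_equal(nrow(res1$gotus), 1L)
  expect_equal(nrow(res1$fotus), 1L)
  expect_true(all(res1$fotus$novel))
  expect_error(place_order_level(make_zotu("q", base300, 1L,
                                           full_tax(order = NA, family = NA,
                                                    genus = NA))),
               "unknown order")
})

test_that("place_unranked fills placeholders above novel fOTUs", {
  none <- matrix(NA_character_, 1, 7, dimnames = list(NULL, tax_ranks()))
  solo <- make_zotu("solo", base300, 1L, none)
  res <- finalize_tic(place_unranked(solo), solo)
  upd <- res$updated_taxonomy
  expect_equal(upd$phylum, "UNKPHYLUM")
  expect_equal(upd$class, "UNKCLASS")
  expect_equal(upd$order, "UNKORDER")
  expect_true(is_novel_name(upd$family))
  expect_true(is.na(upd$domain))

  # two unclassified sequences at 85% -> 2 fOTUs under placeholders
  pair <- rbind(solo, make_zotu("far", rotate_at(base300, spread_pos(300, 45)),
                                1L, none))
  res2 <- finalize_tic(place_unranked(pair), pair)
  expect_equal(nrow(res2$fotus), 2L)

  # class-known sequence matching an existing sOTU at 98% adopts its path
  g1 <- full_tax(genus = "G1", species = "Sp1")
  seed <- make_zotu("seed", base300, 9L, g1)
  st <- cluster_known_genera(seed)
  ck <- make_zotu("ck", rotate_at(base300, spread_pos(300, 6)), 2L,
                  full_tax(order = NA, family = NA, genus = NA, species = NA))
  res3 <- finalize_tic(place_unranked(ck, st), rbind(seed, ck))
  upd3 <- res3$updated_taxonomy
  expect_equal(res3$seq_to_sotu[["ck"]], res3$seq_to_sotu[["seed"]])
  expect_equal(upd3$genus[upd3$id == "ck"], "G1")
})

test_that("run_tic satisfies conservation, purity and naming invariants", {
  bm <- make_benchmark(small_params(seed = 23),
                       prune_spec(mode = "soft", seed = 3))
  x <- bm$dataset
  res <- run_tic(x)
  tr <- bm$truth$taxonomy

  # conservation through the hierarchy
  expect_setequal(names(res$seq_to_sotu), x$id)
  expect_setequal(unique(unname(res$seq_to_sotu)), res$sotus$id)
  expect_setequal(unique(unname(res$sotu_to_gotu)), res$gotus$id)
  expect_setequal(unique(unname(res$gotu_to_fotu)), res$fotus$id)
  expect_equal(sum(res$sotus$n_members), nrow(x))

  # purity by construction at genus and family (known input labels)
  for (rank in c("genus", "family")) {
    members <- cluster_members(res, rank)
    obs <- setNames(x[[rank]], x$id)
    for (mem in members) {
      labs <- obs[mem]
      expect_lte(length(unique(labs[!is.na(labs)])), 1L)
    }
  }

  # updated taxonomy never contradicts known input ranks
  upd <- res$updated_taxonomy
  xin <- x[match(upd$id, x$id), ]
  for (rank in tax_ranks()) {
    known <- !is.na(xin[[rank]])
    expect_identical(upd[[rank]][known], xin[[rank]][known])
  }

  # novel names unique, deterministic shape
  expect_equal(anyDuplicated(res$sotus$id), 0L)
  expect_true(all(grepl("^sOTU_[0-9]+$", res$sotus$id)))
  expect_true(all(grepl("^gOTU_[0-9]+$", res$gotus$id)))
  expect_true(all(grepl("^fOTU_[0-9]+$", res$fotus$id)))

  # zero impurity against the unpruned truth
  expect_equal(count_mixed_clusters(res, tr, "genus"), 0L)
  expect_equal(count_mixed_clusters(res, tr, "family"), 0L)
})

test_that("run_tic recovers planted structure and is order-invariant", {
  bm <- make_benchmark(small_params(seed = 29))
  x <- bm$dataset
  res <- run_tic(x)
  expect_equal(nrow(res$fotus), unname(bm$truth$counts["families"]))
  expect_equal(nrow(res$gotus), unname(bm$truth$counts["genera"]))
  expect_equal(nrow(res$sotus), unname(bm$truth$counts["species"]))
  expect_true(all(!res$gotus$novel))

  # idempotence of knowledge: zero-rate pruning changes nothing
  x0 <- soft_prune(x, prune_spec(0, 0, 0, 0, mode = "soft", seed = 1))
  expect_equal(run_tic(x0), res)

  # determinism under input shuffling
  set.seed(5)
  expect_equal(run_tic(x[sample(nrow(x)), ]), res)

  expect_error(run_tic(rbind(x, x[1, ])), "duplicate")
  expect_error(run_tic(x[0, ]), "empty")
})

test_that("empty-taxonomy dataset equals running place_unranked alone", {
  bm <- make_benchmark(small_params(seed = 31))
  x <- bm$dataset
  x[, tax_ranks()] <- NA_character_
  res_all <- run_tic(x)
  res_unr <- finalize_tic(place_unranked(x), x)
  expect_equal(res_all, res_unr)
})

test_that("taxonomy-blind greedy mixes at least as many genera as TIC", {
  bm <- make_benchmark(small_params(seed = 37),
                       prune_spec(mode = "soft", seed = 4))
  tr <- bm$truth$taxonomy
  res <- run_tic(bm$dataset)
  tic_mixed <- count_mixed_clusters(res, tr, "genus")
  expect_equal(tic_mixed, 0L)
  blind <- greedy_cluster(bm$dataset, 0.95)
  blind_mixed <- count_mixed_clusters(blind$members, tr, "genus")
  expect_gte(blind_mixed, tic_mixed)
})
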