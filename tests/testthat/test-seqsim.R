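test_that("global_identity matches hand-checked examples", {
  expect_equal(global_identity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(global_identity("ACGT", "ACGA"), 0.75)  # 3 matches / 4 columns
  expect_error(global_identity("", "ACGT"), "non-empty")
  expect_error(global_identity("ACGT", ""), "non-empty")
})

test_that("global_identity equals the brute-force DP oracle and is symmetric", {
  set.seed(21)
  seqs <- replicate(12, rand_seq(20))
  for (i in 1:11) for (j in (i + 1):12) {
    expect_equal(global_identity(seqs[i], seqs[j]),
                 oracle_nw_identity(seqs[i], seqs[j]),
                 info = paste(i, j))
    expect_equal(global_identity(seqs[i], seqs[j]),
                 global_identity(seqs[j], seqs[i]))
  }
  # unequal lengths too
  for (k in 1:20) {
    a <- rand_seq(sample(8:25, 1)); b <- rand_seq(sample(8:25, 1))
    expect_equal(global_identity(a, b), oracle_nw_identity(a, b))
  }
})

test_that("N never counts as a match", {
  expect_lt(global_identity("ANGT", "ANGT"), 1.0)
  expect_equal(global_identity("ANGT", "ANGT"), 0.75)
  expect_equal(global_identity("NNNN", "NNNN"), 0.0)
})

test_that("top_hits ranks exhaustively with the pinned tie rules", {
  set.seed(31)
  base <- rand_seq(100)
  refs <- make_zotu(sprintf("r%02d", 1:50),
                    vapply(1:50, function(i) rotate_at(base, sample.int(100, i)),
                           character(1)),
                    size = sample.int(50, 50, replace = TRUE))
  hits <- top_hits(base, refs, k = 50, min_identity = 0)
  ident <- vapply(refs$seq, function(s) global_identity(base, s), numeric(1))
  ord <- order(-ident, -refs$size, refs$id, method = "radix")
  expect_equal(hits$target_id, refs$id[ord])
  expect_equal(hits$identity, unname(ident[ord]))

  self <- top_hits(base, rbind(refs, make_zotu("self", base)), k = 3)
  expect_equal(self$target_id[1], "self")
  expect_equal(self$identity[1], 1.0)

  expect_equal(nrow(top_hits(base, refs, k = 5, min_identity = 1.0000001)), 0L)
  expect_equal(nrow(top_hits(base, refs[0, ], k = 5)), 0L)

  # ties: equal identity resolved by larger size, then id
  tied <- make_zotu(c("b", "a", "c"), rep(rotate_at(base, 1:5), 3),
                    size = c(7L, 7L, 9L))
  th <- top_hits(base, tied, k = 3)
  expect_equal(th$target_id, c("c", "a", "b"))
})

test_that("greedy_cluster founds and joins per the canonical order", {
  one <- make_zotu("a", "ACGTACGTAC")
  gc1 <- greedy_cluster(one, 0.97)
  expect_equal(gc1$centroids, "a")
  expect_equal(unname(gc1$assignment), "a")

  three <- make_zotu(c("x", "y", "z"), rep("ACGTACGTAC", 3))
  gc3 <- greedy_cluster(three, 0.97)
  expect_equal(length(gc3$centroids), 1L)
  expect_equal(sort(unlist(gc3$members)), c("x", "y", "z"))

  # {A, B at 98% to A, C at 80% to both}, threshold 0.97 -> {A,B},{C}
  set.seed(41)
  A <- rand_seq(100)
  B <- rotate_at(A, spread_pos(100, 2))       # 0.98 to A
  C <- rotate_at(A, spread_pos(100, 20, 1L))  # 0.80 to A
  expect_equal(global_identity(A, B), 0.98)
  expect_equal(global_identity(A, C), 0.80)
  x <- make_zotu(c("A", "B", "C"), c(A, B, C), size = c(10L, 5L, 3L))
  gc <- greedy_cluster(x, 0.97)
  expect_equal(length(gc$centroids), 2L)
  expect_equal(gc$assignment[["B"]], "A")
  expect_equal(gc$assignment[["C"]], "C")

  expect_error(greedy_cluster(x[0, ], 0.97), "no sequences")
  expect_error(greedy_cluster(x, 0), "threshold")
})

test_that("greedy_cluster invariants: conservation, threshold, determinism", {
  set.seed(51)
  base <- rand_seq(120)
  x <- make_zotu(sprintf("q%02d", 1:30),
                 vapply(1:30, function(i) rotate_at(base, sample.int(120, sample(1:40, 1))),
                        character(1)),
                 size = sample.int(20, 30, replace = TRUE))
  gc <- greedy_cluster(x, 0.9)
  # conservation
  expect_setequal(names(gc$assignment), x$id)
  expect_equal(anyDuplicated(unlist(gc$members)), 0L)
  # post-hoc: every member within threshold of its own centroid
  for (ci in seq_along(gc$centroids)) {
    cen <- x$seq[x$id == gc$centroids[ci]]
    for (m in gc$members[[ci]])
      expect_gte(global_identity(x$seq[x$id == m], cen), 0.9)
  }
  # input order invariance
  sh <- x[sample(nrow(x)), ]
  gc2 <- greedy_cluster(sh, 0.9)
  expect_identical(gc$centroids, gc2$centroids)
  expect_identical(gc$assignment[sort(names(gc$assignment))],
                   gc2$assignment[sort(names(gc2$assignment))])
})

test_that("greedy_cluster recovers a planted partition straddling the threshold", {
  bm <- make_benchmark(small_params(seed = 19))
  gc <- greedy_cluster(bm$dataset, 0.97)
  truth <- setNames(bm$truth$taxonomy$species, bm$truth$taxonomy$id)
  expect_equal(length(gc$centroids), length(unique(truth)))
  # clusters == planted species exactly
  for (mem in gc$members)
    expect_equal(length(unique(truth[mem])), 1L)
})
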