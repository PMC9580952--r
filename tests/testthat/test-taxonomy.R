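test_that("parse_taxonomy maps the header dialect onto rank vectors", {
  p <- parse_taxonomy("tax=d:Bacteria,p:Actinobacteriota,f:Bifidobacteriaceae,g:Bifidobacterium")
  expect_equal(unname(p[c("domain", "phylum", "family", "genus")]),
               c("Bacteria", "Actinobacteriota", "Bifidobacteriaceae",
                 "Bifidobacterium"))
  expect_true(all(is.na(p[c("class", "order", "species")])))
  expect_equal(tax_depth(p), 6L)

  expect_equal(parse_taxonomy(""), empty_tax_path())
  expect_equal(tax_depth(parse_taxonomy("")), 0L)

  expect_error(parse_taxonomy("tax=d:Bacteria,g:Foo,g:Bar"), "duplicate")
  expect_error(parse_taxonomy("tax=q:Nope"), "q:Nope")
  expect_error(parse_taxonomy("tax=d:Bacteria,junk"), "junk")
})

test_that("format_taxonomy round-trips and renders placeholders", {
  expect_equal(format_taxonomy(empty_tax_path()), "")
  p <- parse_taxonomy("tax=d:Bacteria,p:P,c:C,o:UNKORDER,f:fOTU_3")
  expect_match(format_taxonomy(p), "o:UNKORDER", fixed = TRUE)
  set.seed(11)
  for (i in 1:500) {
    p <- random_tax_path()
    expect_identical(parse_taxonomy(format_taxonomy(p)), p)
  }
})

test_that("lca returns the deepest shared prefix", {
  p <- parse_taxonomy("tax=d:Bacteria,p:P,c:C,o:O,f:F,g:G,s:S")
  expect_identical(lca(list(p, p)), p)

  q <- p; q[["genus"]] <- "Other"; q[["species"]] <- NA_character_
  r <- lca(list(p, q))
  expect_equal(tax_depth(r), 5L)
  expect_equal(unname(r[["family"]]), "F")

  # truncations of one lineage: lca == shallowest input (rank-wise scan)
  set.seed(4)
  truncs <- lapply(sample(0:7, 10, replace = TRUE), function(d) {
    t <- p; if (d < 7L) t[(d + 1L):7L] <- NA_character_; t
  })
  depths <- vapply(truncs, tax_depth, integer(1))
  expect_identical(lca(truncs), truncs[[which.min(depths)]])

  expect_error(lca(list()), "non-empty")
})

make_pruned_world <- function(n_genera = 10L, per = 3L) {
  tax <- do.call(rbind, lapply(seq_len(n_genera), function(g)
    full_tax(family = sprintf("F%02d", (g - 1L) %/% 5L + 1L),
             genus = sprintf("G%02d", g),
             species = sprintf("G%02d_S", g))))
  tax <- tax[rep(seq_len(n_genera), each = per), ]
  make_zotu(sprintf("z%03d", seq_len(n_genera * per)),
            replicate(n_genera * per, "ACGT"), tax = tax)
}

test_that("hard_prune removes whole clades, seeded and clade-consistent", {
  x <- make_pruned_world()
  spec0 <- prune_spec(0, 0, 0, 0, mode = "hard", seed = 1)
  expect_identical(hard_prune(x, spec0), x)

  spec <- prune_spec(genus = 0.10, family = 0, order = 0, class = 0,
                     mode = "hard", seed = 5)
  y <- hard_prune(x, spec)
  erased <- is.na(y$genus)
  expect_equal(sum(tapply(erased, x$genus, any)), 1L)  # ceil(0.1 * 10) clades
  expect_true(all(is.na(y$species[erased])))           # deeper ranks erased too
  # clade consistency: a genus is erased for all or none of its members
  expect_true(all(tapply(erased, x$genus, function(e) all(e) || !any(e))))
  expect_identical(hard_prune(x, spec), y)             # seeded determinism

  all_gone <- hard_prune(x, prune_spec(1, 0, 0, 0, mode = "hard", seed = 2))
  expect_true(all(is.na(all_gone$genus)))
  expect_true(all(!is.na(all_gone$family)))
})

test_that("soft_prune erasure matches the closed-form binomial rate", {
  x <- make_pruned_world(n_genera = 100L, per = 100L)  # n = 10,000
  spec <- prune_spec(mode = "soft", seed = 9)
  y <- soft_prune(x, spec)
  # marginal genus-erasure: triggered by the genus draw or any shallower one
  p <- 1 - prod(1 - c(0.10, 0.05, 0.025, 0.01))
  n <- nrow(x)
  expect_lt(abs(sum(is.na(y$genus)) - n * p), 3 * sqrt(n * p * (1 - p)))
  expect_identical(soft_prune(x, spec), y)
  expect_identical(soft_prune(x, prune_spec(0, 0, 0, 0, mode = "soft", seed = 1)), x)
})

test_that("pruning never adds taxonomy and keeps prefix-contiguity", {
  x <- make_pruned_world()
  depth_of <- function(d) apply(!is.na(as.matrix(d[, tax_ranks()])), 1, sum)
  for (mode in c("soft", "hard")) {
    y <- switch(mode,
                soft = soft_prune(x, prune_spec(0.3, 0.2, 0.1, 0.05, mode = "soft", seed = 3)),
                hard = hard_prune(x, prune_spec(0.3, 0.2, 0.1, 0.05, mode = "hard", seed = 3)))
    expect_true(all(depth_of(y) <= depth_of(x)))
    m <- !is.na(as.matrix(y[, tax_ranks()]))
    expect_true(all(apply(m, 1, function(r) all(diff(which(r)) == 1L) || sum(r) <= 1L)))
  }
  expect_error(prune_spec(genus = 1.2), "0, 1")
  expect_error(hard_prune(x, prune_spec(mode = "soft")), "hard")
  expect_error(soft_prune(x, prune_spec(mode = "hard")), "soft")
})
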