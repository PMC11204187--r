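test_that("a homoplasy-free matrix scores CI = RI = 1 on its tree", {
  tr <- random_tree(7, seed = 21)
  pm <- perfect_matrix(tr)
  ei <- ensemble_indices(tr, pm)
  expect_equal(ei$CI, 1)
  expect_equal(ei$RI, 1)
  expect_false(any(homoplasy_flags(tr, pm)))
  expect_true(all(ei$fits$s == 1L & ei$fits$m == 1L))
})

test_that("ensemble indices recompute exactly from brute-force ingredients", {
  set.seed(67)
  for (rep in 1:6) {
    m <- random_matrix(6, 8, n_states = 3, missing_frac = 0.1)
    tr <- random_tree(6, seed = 200 + rep, labels = m$taxa)
    s <- vapply(seq_len(m$n_chars), function(j)
      brute_force_length(tr, stats::setNames(m$states[, j], m$taxa)), 0L)
    mm <- apply(m$states, 2, min_steps)
    gg <- apply(m$states, 2, max_steps)
    ei <- ensemble_indices(tr, m)
    expect_equal(ei$L, sum(s))
    expect_equal(ei$CI, sum(mm) / sum(s))
    expect_equal(ei$RI, (sum(gg) - sum(s)) / (sum(gg) - sum(mm)))
    # homoplasy flag is definitionally ci < 1
    expect_equal(homoplasy_flags(tr, m), unname(s > mm))
  }
})

test_that("indices are invariant under character and taxon reordering", {
  set.seed(73)
  m <- random_matrix(7, 10, n_states = 3, missing_frac = 0.1)
  tr <- random_tree(7, seed = 301, labels = m$taxa)
  ei <- ensemble_indices(tr, m)
  mp <- char_matrix(m$states[, sample(10)], taxa = m$taxa)
  perm <- sample(7)
  mt <- char_matrix(m$states[perm, ], taxa = m$taxa[perm])
  for (alt in list(mp, mt)) {
    ei2 <- ensemble_indices(tr, alt)
    expect_equal(ei2$CI, ei$CI)
    expect_equal(ei2$RI, ei$RI)
  }
})

test_that("strict consensus is the intersection of bipartitions", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  expect_equal(topo_key(strict_consensus(list(t1))), topo_key(t1))
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  cons <- strict_consensus(list(t1, t2))
  expect_length(bipartitions(cons), 0L)   # total conflict -> star
  t3 <- ape::read.tree(text = "(((a,b),c),(d,e));")
  t4 <- ape::read.tree(text = "(((a,b),d),(c,e));")
  cons2 <- strict_consensus(list(t3, t4))
  expect_equal(vapply(bipartitions(cons2), paste, "", collapse = ","),
               "c,d,e")   # only {a,b} (reported as its complement) survives
  # property: consensus splits are a subset of every input's splits
  set.seed(83)
  for (rep in 1:5) {
    trees <- lapply(1:4, function(i) random_tree(8, seed = rep * 10 + i))
    cs <- vapply(bipartitions(strict_consensus(trees)), paste, "", collapse = ",")
    for (tr in trees)
      expect_true(all(cs %in% vapply(bipartitions(tr), paste, "", collapse = ",")))
  }
})

test_that("strict consensus agrees with an independent implementation", {
  set.seed(89)
  for (rep in 1:5) {
    trees <- lapply(1:3, function(i) random_tree(7, seed = rep * 31 + i))
    mine <- strict_consensus(trees)
    cl <- do.call(c, trees); class(cl) <- "multiPhylo"
    theirs <- ape::consensus(cl, p = 1)
    expect_setequal(vapply(bipartitions(mine), paste, "", collapse = ","),
                    vapply(bipartitions(theirs), paste, "", collapse = ","))
  }
})

test_that("majority rule counts frequencies and respects its threshold", {
  t1 <- ape::read.tree(text = "(((a,b),c),(d,e));")
  t2 <- ape::read.tree(text = "(((a,b),d),(c,e));")
  trees <- list(t1, t1, t1, t2)
  mr <- majority_rule(trees, threshold = 0.6)
  splits <- vapply(bipartitions(mr), paste, "", collapse = ",")
  expect_true("c,d,e" %in% splits)          # the {a,b} clade, canonical side
  # the t1-only clade {a,b,c} (canonical side {d,e}) appears at 0.75 >= 0.6
  expect_true("d,e" %in% splits)
  expect_true(all(as.numeric(mr$node.label[mr$node.label != ""]) >= 0.6))
  expect_error(majority_rule(trees, threshold = 0.4), "argument error")
  # threshold 1 reproduces the strict consensus
  set.seed(97)
  trees2 <- lapply(1:3, function(i) random_tree(7, seed = 400 + i))
  expect_equal(topo_key(majority_rule(trees2, 1)),
               topo_key(strict_consensus(trees2)))
  # included bipartitions are mutually compatible: they form a tree, so
  # every pair is nested or disjoint
  sp <- bipartitions(majority_rule(trees2, 0.6))
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i >= j) next
    a <- sp[[i]]; b <- sp[[j]]
    expect_true(!length(intersect(a, b)) || all(a %in% b) || all(b %in% a))
  }
})

test_that("mismatched leaf sets are refused", {
  t1 <- random_tree(6, seed = 1)
  t2 <- random_tree(7, seed = 2)
  expect_error(strict_consensus(list(t1, t2)), "label error")
})

test_that("fit table has one row per character with coherent flags", {
  m <- bundled_matrix()
  mpts <- branch_and_bound(m)
  tab <- character_fit_table(mpts$trees[[1]], m)
  expect_equal(nrow(tab), 24L)
  expect_equal(tab$homoplastic, tab$s > tab$m)
  expect_equal(sum(tab$s), 42L)
})
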