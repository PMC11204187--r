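test_that("topology enumeration yields each tree once, (2n-5)!! in total", {
  expect_equal(length(enumerate_topologies(letters[1:4])), 3L)
  expect_equal(length(enumerate_topologies(letters[1:6])), 105L)
  keys <- character(0)
  n7 <- enumerate_topologies(letters[1:7],
                             fun = function(t) keys <<- c(keys, topo_key(t)))
  expect_equal(n7, 945L)
  expect_equal(length(unique(keys)), 945L)
  expect_equal(num_topologies(10), 2027025)
  expect_error(enumerate_topologies(letters[1:2]), "size error")
})

test_that("rearrangement neighborhoods have the right sizes and nest", {
  tr4 <- random_tree(4, seed = 3)
  expect_length(neighbors(tr4, "nni"), 2L)          # 2(n-3)
  set.seed(19)
  for (n in c(6, 7)) {
    tr <- random_tree(n, seed = n * 13)
    nn <- vapply(neighbors(tr, "nni"), topo_key, "")
    sp <- vapply(neighbors(tr, "spr"), topo_key, "")
    tb <- vapply(neighbors(tr, "tbr"), topo_key, "")
    expect_length(nn, 2L * (n - 3L))
    expect_true(all(nn %in% sp))
    expect_true(all(sp %in% tb))
    expect_false(topo_key(tr) %in% tb)
  }
})

test_that("branch and bound equals exhaustive search", {
  # fixed 4-taxon case: identical optimum set as scoring every topology
  set.seed(47)
  m4 <- random_matrix(4, 8, n_states = 3)
  ex4 <- exhaustive_optimum(m4)
  bb4 <- branch_and_bound(m4)
  expect_equal(bb4$score, ex4$score)
  expect_setequal(vapply(bb4$trees, topo_key, ""), ex4$keys)
  # random 7-taxon matrices: same score and same optimal tree set
  for (rep in 1:12) {
    m7 <- random_matrix(7, sample(6:14, 1), n_states = sample(2:4, 1),
                        missing_frac = 0.1)
    ex <- exhaustive_optimum(m7)
    bb <- branch_and_bound(m7)
    expect_equal(bb$score, ex$score)
    expect_setequal(vapply(bb$trees, topo_key, ""), ex$keys)
  }
})

test_that("heuristic search never beats the exact optimum and usually matches", {
  set.seed(59)
  hits <- 0L
  n_mat <- 25L
  for (rep in seq_len(n_mat)) {
    m8 <- random_matrix(8, 12, n_states = 3, missing_frac = 0.1)
    exact <- branch_and_bound(m8)$score
    heur <- heuristic_search(m8, search_config(seed = rep, n_replicates = 3,
                                               move = "spr"))$score
    expect_gte(heur, exact)
    if (heur == exact) hits <- hits + 1L
  }
  expect_gte(hits / n_mat, 0.95)
})

test_that("search is deterministic for a fixed configuration", {
  set.seed(61)
  m <- random_matrix(8, 10, n_states = 3, missing_frac = 0.1)
  cfg <- search_config(seed = 123, n_replicates = 4, move = "tbr")
  a <- heuristic_search(m, cfg)
  b <- heuristic_search(m, cfg)
  expect_identical(a$score, b$score)
  expect_identical(vapply(a$trees, ape::write.tree, ""),
                   vapply(b$trees, ape::write.tree, ""))
})

test_that("a single-character constant matrix makes every topology optimal", {
  m <- char_matrix(matrix(0L, 6, 1), taxa = sprintf("t%d", 1:6))
  hs <- heuristic_search(m, search_config(seed = 7, n_replicates = 1,
                                          move = "nni", max_trees = 20))
  expect_equal(hs$score, 0)
  expect_true(hs$hit_cap)
  bb <- branch_and_bound(m, max_trees = 50)
  expect_equal(bb$score, 0L)
  expect_true(bb$hit_cap)
  expect_equal(length(bb$trees), 50L)
})

test_that("zero-minimum-length collapsing behaves at the extremes", {
  tr <- random_tree(7, seed = 101)
  pm <- perfect_matrix(tr)
  kept <- collapse_min_length_zero(tr, pm)
  expect_equal(topo_key(kept), topo_key(tr))   # every edge carries a change
  const <- char_matrix(matrix(1L, 7, 3), taxa = gsub("_", " ", tr$tip.label))
  star <- collapse_min_length_zero(tr, const)
  expect_length(bipartitions(star), 0L)        # fully collapsed
})

test_that("search_config validates its arguments", {
  expect_error(search_config(), "seed")
  expect_error(search_config(seed = 1, n_replicates = 0), ">= 1")
  cfg <- search_config(seed = 1)
  expect_equal(cfg$move, "tbr")
  expect_true(cfg$steepest)
})
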