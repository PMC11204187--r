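test_that("generators are deterministic per seed", {
  t1 <- random_tree(9, seed = 12)
  t2 <- random_tree(9, seed = 12)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(random_tree(9, seed = 13)),
                         ape::write.tree(t1)))
  cfg <- sim_config(n_chars = 20, change_prob = 0.1, missing_frac = 0.1, seed = 4)
  m1 <- simulate_matrix(t1, cfg)
  m2 <- simulate_matrix(t1, cfg)
  expect_identical(m1$states, m2$states)
  expect_identical(ape::write.tree(attr(m1, "true_tree")), ape::write.tree(t1))
})

test_that("degenerate simulator settings behave as promised", {
  tr <- random_tree(6, seed = 9)
  frozen <- simulate_matrix(tr, sim_config(n_chars = 10, change_prob = 0,
                                           missing_frac = 0, seed = 2))
  expect_equal(fitch_length(tr, frozen)$length, 0L)
  expect_true(all(apply(frozen$states, 2, function(x) length(unique(x)) == 1L)))
  blank <- simulate_matrix(tr, sim_config(n_chars = 5, change_prob = 0.2,
                                          missing_frac = 1, seed = 2))
  expect_true(all(is.na(blank$states)))
  expect_true(all(validate_matrix(blank)$type == "all_missing" |
                    validate_matrix(blank)$type == "duplicate_row"))
  expect_equal(sum(validate_matrix(blank)$type == "all_missing"), 5L)
})

test_that("random topologies are uniform across the 15 five-leaf trees", {
  keys <- vapply(1:4500, function(s) topo_key(random_tree(5, seed = s)), "")
  tab <- table(keys)
  expect_equal(length(tab), 15L)
  p <- stats::chisq.test(as.vector(tab))$p.value
  expect_gt(p, 0.001)
})

test_that("the three-leaf topology is unique and the guard fires", {
  expect_length(bipartitions(random_tree(3, seed = 1)), 0L)
  expect_error(random_tree(2, seed = 1), "size error")
  expect_error(perfect_matrix(random_tree(3, seed = 1)), "size error")
})

test_that("perfect matrices pin their generating tree as the unique optimum", {
  tr <- random_tree(6, seed = 91)
  pm <- perfect_matrix(tr)
  expect_equal(ncol(pm$states), 3L)      # one character per internal edge
  f <- fitch_length(tr, pm)$fits
  expect_true(all(f$s == 1L & f$m == 1L))
  bb <- branch_and_bound(pm)
  expect_equal(bb$score, 3L)
  expect_length(bb$trees, 1L)
  expect_equal(topo_key(bb$trees[[1]]), topo_key(tr))
})

test_that("simulated signal is recoverable and fades with noise", {
  tr <- random_tree(10, seed = 11)
  m <- simulate_matrix(tr, sim_config(n_taxa = 10, n_chars = 60, n_states = 3,
                                      change_prob = 0.05, missing_frac = 0,
                                      seed = 13))
  cons <- strict_consensus(heuristic_search(m, search_config(seed = 3,
                                                             n_replicates = 5)))
  truth <- vapply(bipartitions(tr), paste, "", collapse = ",")
  got <- vapply(bipartitions(cons), paste, "", collapse = ",")
  expect_gte(mean(truth %in% got), 0.8)

  # heavier noise cannot (in tendency) recover more of the tree
  recov <- function(cp, seed) {
    mm <- simulate_matrix(tr, sim_config(n_taxa = 10, n_chars = 60, n_states = 3,
                                         change_prob = cp, missing_frac = 0,
                                         seed = seed))
    cc <- strict_consensus(heuristic_search(mm, search_config(seed = seed,
                                                              n_replicates = 3)))
    mean(truth %in% vapply(bipartitions(cc), paste, "", collapse = ","))
  }
  lo <- mean(vapply(1:2, function(s) recov(0.03, s), 0))
  hi <- mean(vapply(1:2, function(s) recov(0.45, s), 0))
  expect_gte(lo, hi)
})
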