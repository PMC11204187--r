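test_that("trivial step counts are exact", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  # constant character: no change anywhere
  m0 <- char_matrix(matrix(0L, 4, 1), taxa = letters[1:4])
  expect_equal(fitch_length(tr, m0)$length, 0L)
  expect_equal(brute_force_length(tr, c(a = 0L, b = 0L, c = 0L, d = 0L)), 0L)
  # one change on the internal edge
  expect_equal(brute_force_length(tr, c(a = 0L, b = 0L, c = 1L, d = 1L)), 1L)
  m1 <- char_matrix(matrix(c(0L, 0L, 1L, 1L), 4, 1), taxa = letters[1:4])
  expect_equal(fitch_length(tr, m1)$length, 1L)
})

test_that("min and max conceivable steps follow their definitions", {
  m <- bundled_matrix()
  expect_equal(min_steps(m$states[, 3]), 3L)       # four observed states
  expect_equal(min_steps(rep(NA_integer_, 6)), 0L)
  expect_equal(max_steps(rep(NA_integer_, 6)), 0L)
  col <- c(rep(0L, 4), rep(1L, 3))
  expect_equal(min_steps(col), 1L)
  expect_equal(max_steps(col), 3L)
})

test_that("Fitch equals the brute-force oracle on random small instances", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(4:6, 1)
    tr <- random_tree(n, seed = sample.int(1e6, 1))
    col <- sample(c(0:3, NA), n, replace = TRUE)
    mm <- char_matrix(matrix(col, ncol = 1), taxa = tip_labels <- gsub("_", " ", tr$tip.label))
    expect_equal(fitch_length(tr, mm)$length,
                 brute_force_length(tr, stats::setNames(col, tip_labels)))
  }
})

test_that("fitch length is invariant to traversal rooting and column order", {
  set.seed(5)
  m <- random_matrix(7, 12, n_states = 4, missing_frac = 0.15)
  tr <- random_tree(7, seed = 9, labels = m$taxa)
  base <- fitch_length(tr, m)$length
  for (tip in tr$tip.label) {
    rooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_length(rooted, m)$length, base)
  }
  perm <- sample(m$n_chars)
  mp <- char_matrix(m$states[, perm], taxa = m$taxa)
  expect_equal(fitch_length(tr, mp)$length, base)
})

test_that("per-character fits satisfy m <= s <= g with indices in [0,1]", {
  set.seed(17)
  for (rep in 1:10) {
    m <- random_matrix(8, 10, n_states = sample(2:4, 1), missing_frac = 0.2)
    tr <- random_tree(8, seed = rep, labels = m$taxa)
    f <- fitch_length(tr, m)$fits
    expect_true(all(f$m <= f$s))
    expect_true(all(f$s <= f$g | f$g == 0))
    expect_true(all(f$ci >= 0 & f$ci <= 1))
    expect_true(all(f$ri >= 0 & f$ri <= 1))
  }
})

test_that("missing leaves and guards are handled", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  # all-missing column costs nothing
  mq <- char_matrix(matrix(NA_integer_, 4, 1), taxa = letters[1:4])
  expect_equal(fitch_length(tr, mq)$length, 0L)
  # unknown leaf
  m <- char_matrix(matrix(0L, 3, 1), taxa = c("a", "b", "c"))
  expect_error(fitch_length(tr, m), "lookup error")
  # enumeration guard on the brute force
  big <- random_tree(9, seed = 1)
  expect_error(brute_force_length(big, rep(0L, 9)), "size error")
  # polytomies are refused
  poly <- ape::read.tree(text = "(a,b,c,d,e);")
  m5 <- char_matrix(matrix(0L, 5, 1), taxa = letters[1:5])
  expect_error(fitch_length(poly, m5), "shape error")
})

test_that("fitch agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  for (rep in 1:10) {
    m <- random_matrix(8, 15, n_states = 4, missing_frac = 0.1)
    tr <- random_tree(8, seed = 100 + rep, labels = m$taxa)
    chr <- matrix(ifelse(is.na(m$states), "?", as.character(m$states)),
                  nrow = 8, dimnames = list(gsub(" ", "_", m$taxa), NULL))
    pd <- phangorn::phyDat(chr, type = "USER", levels = as.character(0:3),
                           ambiguity = "?")
    expect_equal(fitch_length(tr, m)$length,
                 as.integer(phangorn::parsimony(tr, pd)))
  }
})
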