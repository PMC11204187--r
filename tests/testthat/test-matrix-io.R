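test_that("bundled matrix matches its printed transcription", {
  m <- bundled_matrix()
  expect_s3_class(m, "char_matrix")
  expect_equal(dim(m), c(13L, 24L))
  expect_equal(sum(is.na(m$states)), 36L)

  # the outgroup row is state 1 at characters 4 and 9 and 0 elsewhere
  eu <- m$states["Euhagla saurensis", ]
  expect_equal(unname(which(eu == 1L)), c(4L, 9L))
  expect_true(all(eu[-c(4, 9)] == 0L))

  # one new species is missing only at character 13
  orn <- m$states["Archaboilus ornatus sp. n.", ]
  expect_equal(unname(which(is.na(orn))), 13L)

  # character 3 shows all four states
  expect_equal(length(unique(na.omit(m$states[, 3]))), 4L)

  # transcription is pinned and bit-stable across calls
  expect_identical(matrix_checksum(m), "6d21f6f14860619f578b6e6a9f924b5a")
  expect_identical(bundled_matrix()$states, m$states)

  # character metadata for all 24 characters
  expect_equal(nrow(m$char_defs), 24L)
})

test_that("taxon metadata and groups fixtures are coherent", {
  md <- taxon_metadata()
  m <- bundled_matrix()
  expect_setequal(md$taxon[md$role != "excluded"], m$taxa)
  expect_equal(sum(md$role == "excluded"), 2L)
  expect_true(all(na.omit(md$age_code) %in% c("J1", "J2", "J3", "K1")))
  # the misspelled published name carries a corrected alias
  expect_equal(md$alias[md$taxon == "Vitmoilus gigantus sp. n."],
               "Vitimoilus gigantus sp. n.")
  g <- named_groups()
  expect_length(g$archaboilinae, 10L)
  expect_length(g$vitimoilus, 3L)
  expect_length(g$cyrtophyllitinae_sensu_lato, 11L)
  expect_true(all(unlist(g) %in% m$taxa))
})

test_that("write/parse round-trips are the identity in all three dialects", {
  m <- bundled_matrix()
  for (d in c("nexus", "tnt", "csv")) {
    m2 <- parse_matrix(write_matrix(m, d), d)
    expect_identical(m2$states, m$states, label = d)
    expect_identical(m2$taxa, m$taxa, label = d)
  }
  # property: random matrices with spaced labels survive every dialect
  set.seed(71)
  for (i in 1:8) {
    n <- sample(4:9, 1)
    mm <- random_matrix(n, sample(3:12, 1), n_states = 4, missing_frac = 0.1,
                        taxa = paste("taxon", LETTERS[seq_len(n)], "x"))
    for (d in c("nexus", "tnt", "csv")) {
      m2 <- parse_matrix(write_matrix(mm, d), d)
      expect_identical(m2$states, mm$states)
      expect_identical(m2$taxa, mm$taxa)
    }
  }
})

test_that("minimal csv and dialect errors behave as specified", {
  m1 <- parse_matrix("t1,0", "csv")
  expect_equal(dim(m1), c(1L, 1L))
  expect_equal(unname(m1$states[1, 1]), 0L)

  expect_error(parse_matrix(c("a,0,1", "b,0"), "csv"), "dimension error")
  expect_error(parse_matrix(c("a,0,1", "b,0,x"), "csv"), "state error.*'b'.*2")
  expect_error(parse_matrix("no matrix here", "nexus"), "parse error")
  expect_error(
    parse_matrix(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=3 NCHAR=2;",
                   "MATRIX", "a 01", "b 00", ";", "END;"), "nexus"),
    "dimension error")
  # reserved label characters are refused, never emitted unparseably
  bad <- char_matrix(matrix(0L, 2, 2), taxa = c("a_b", "c"))
  expect_error(write_matrix(bad, "nexus"), "label error")
  expect_error(write_matrix(char_matrix(matrix(0L, 1, 1), taxa = "a,b"), "csv"),
               "label error")
})

test_that("nexus writer agrees with an independent nexus reader", {
  m <- bundled_matrix()
  f <- tempfile(fileext = ".nex")
  writeLines(write_matrix(m, "nexus"), f)
  nx <- ape::read.nexus.data(f)
  expect_equal(length(nx), 13L)
  got <- t(vapply(nx, function(x) x, character(24)))
  expect_equal(unname(got[, 1]),
               unname(ifelse(is.na(m$states[, 1]), "?", as.character(m$states[, 1]))))
  expect_equal(gsub("_", " ", names(nx)), m$taxa)
})

test_that("validate_matrix reports analytic findings, not errors", {
  m <- bundled_matrix()
  f <- validate_matrix(m)
  # the two identical Table rows are flagged by name; nothing structural
  expect_true(any(f$type == "duplicate_row"))
  expect_match(f$message[f$type == "duplicate_row"], "Archaboilus shurabicus")
  expect_match(f$message[f$type == "duplicate_row"], "Archaboilus martynovi")
  expect_false(any(f$type %in% c("constant", "all_missing")))

  allq <- char_matrix(matrix(NA_integer_, 3, 2), taxa = c("a", "b", "c"))
  expect_equal(sum(validate_matrix(allq)$type == "all_missing"), 2L)
  const <- char_matrix(matrix(1L, 3, 1), taxa = c("a", "b", "c"))
  expect_true(any(validate_matrix(const)$type == "constant"))
  clean <- char_matrix(matrix(c(0L, 1L, 0L, 0L, 1L, 1L), 3, 2),
                       taxa = c("a", "b", "c"))
  expect_equal(nrow(validate_matrix(clean)), 0L)
})

test_that("construction rejects structural violations", {
  expect_error(char_matrix(matrix(0L, 2, 2), taxa = c("a", "a")), "unique")
  expect_error(char_matrix(matrix(c("0", "x"), 1, 2), taxa = "a"), "state error")
  expect_error(char_matrix(matrix(11L, 1, 1), taxa = "a"), "state")
})
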