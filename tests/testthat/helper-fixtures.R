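# shared fixtures and small oracles, built in code at test time

topo_key <- function(tree) {
  paste(vapply(bipartitions(tree), paste, "", collapse = ","), collapse = ";")
}

# random character matrix in the shape the package targets
random_matrix <- function(n_taxa, n_chars, n_states = 3, missing_frac = 0,
                          taxa = sprintf("t%d", seq_len(n_taxa))) {
  st <- matrix(sample.int(n_states, n_taxa * n_chars, replace = TRUE) - 1L,
               n_taxa, n_chars)
  if (missing_frac > 0)
    st[matrix(runif(length(st)) < missing_frac, nrow(st))] <- NA_integer_
  char_matrix(st, taxa = taxa)
}

# exhaustive optimum over every topology, via the internal fast path
exhaustive_optimum <- function(matrix) {
  taxa <- matrix$taxa
  trees <- enumerate_topologies(taxa)
  scores <- vapply(trees, function(t) fitch_length(t, matrix)$length, 0)
  best <- min(scores)
  list(score = best,
       keys = sort(vapply(trees[scores == best], topo_key, "")))
}

# the published most-parsimonious topology classes share these clades
bundled_outgroup <- "Euhagla saurensis"
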