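#' Nonparametric bootstrap over characters
#'
#' Resamples the matrix columns with replacement, re-runs the heuristic
#' search on each pseudo-replicate, takes the strict consensus of that
#' replicate's equally best trees, and tallies how often each non-trivial
#' bipartition appears. Support is tallied from each replicate's consensus
#' (not from one arbitrarily chosen tree) so tie-breaking order cannot bias
#' the frequencies. Deterministic for fixed inputs.
#'
#' @param matrix a [char_matrix()].
#' @param n_replicates number of bootstrap replicates.
#' @param search a [search_config()] for the within-replicate searches; its
#'   seed field is ignored (per-replicate seeds are derived from `seed`).
#'   Defaults to a light 10-replicate TBR search.
#' @param seed RNG seed driving both the resampling and the searches.
#' @return a `bootstrap_result`: list with `n_replicates`, `frequencies`
#'   (data frame: `split` label string, `members` list, `freq`), `seed`,
#'   `per_replicate_scores`.
#' @export
run_bootstrap <- function(matrix, n_replicates, search = NULL, seed) {
  if (n_replicates < 1) stop("argument error: n_replicates must be >= 1")
  if (missing(seed)) stop("a seed is required")
  # resampled matrices can have very flat landscapes; the within-replicate
  # tree cap stays small so no replicate chases an enormous tie set
  if (is.null(search))
    search <- search_config(seed = 1, n_replicates = 10, max_trees = 16)
  if (search$max_trees > 64) search$max_trees <- 64L
  seeds <- derive_seeds(seed, 2L * n_replicates)
  counts <- new.env(parent = emptyenv())
  scores <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- with_seed(seeds[r],
                      sample.int(matrix$n_chars, matrix$n_chars, replace = TRUE))
    bm <- char_matrix(matrix$states[, cols, drop = FALSE], taxa = matrix$taxa)
    cfg <- search
    cfg$seed <- seeds[n_replicates + r]
    res <- heuristic_search(bm, cfg)
    scores[r] <- res$score
    cons <- strict_consensus(res$trees)
    labels <- tip_to_label(cons$tip.label)
    n <- length(labels)
    for (nd in seq_len(cons$Nnode)) {
      tips <- labels[descendant_tips(cons, n + nd)]
      side <- canonical_split_side(tips, labels)
      if (is.null(side)) next
      key <- split_key(side)
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], 0L) / n_replicates
  ord <- order(-freq, keys)
  structure(list(
    n_replicates = n_replicates,
    frequencies = data.frame(
      split = vapply(keys[ord], function(k)
        paste(split_members(k), collapse = " | "), ""),
      freq = as.numeric(freq[ord]),
      row.names = NULL)[, c("split", "freq")],
    splits = stats::setNames(as.numeric(freq[ord]), keys[ord]),
    taxa = matrix$taxa,
    seed = seed,
    per_replicate_scores = scores),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %d replicates, %d splits observed\n",
              x$n_replicates, nrow(x$frequencies)))
  print(utils::head(x$frequencies, 10))
  invisible(x)
}

#' Bootstrap support of one taxon set
#'
#' @param result a `bootstrap_result`.
#' @param members taxon labels of either side of the bipartition.
#' @return frequency in `[0, 1]` (0 when never sampled).
#' @export
split_support <- function(result, members) {
  side <- canonical_split_side(squish(members), result$taxa)
  if (is.null(side)) stop("argument error: trivial bipartition")
  key <- split_key(side)
  if (key %in% names(result$splits)) unname(result$splits[[key]]) else 0
}

#' Annotate a tree with bootstrap frequencies
#'
#' Labels every internal edge of the tree with its bootstrap frequency
#' (0 when the bipartition was never observed).
#'
#' @param tree a `phylo` whose leaves match the bootstrapped matrix taxa.
#' @param result a `bootstrap_result`.
#' @return the tree with node labels set to frequencies.
#' @export
annotate_support <- function(tree, result) {
  tree_taxa <- sort(tip_to_label(tree$tip.label))
  if (!setequal(tree_taxa, result$taxa))
    stop("label error: tree leaves do not match the bootstrapped taxon set")
  annotate_splits(tree, result$splits)
}
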