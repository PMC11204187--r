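#' Simulation configuration
#'
#' Settings for [simulate_matrix()], emulating the shape of small fossil
#' morphology matrices: a handful of taxa, a few dozen unordered characters
#' with 2--4 states, and sparse missingness.
#'
#' @param n_taxa number of taxa (>= 3).
#' @param n_chars number of characters.
#' @param n_states states per character (2--4).
#' @param change_prob per-branch, per-character probability of switching to a
#'   different state, in `[0, 1)`.
#' @param missing_frac fraction of leaf cells masked as missing, in `[0, 1]`.
#' @param seed RNG seed (required).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa = 13, n_chars = 24, n_states = 3,
                       change_prob = 0.1, missing_frac = 0.05, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_taxa >= 3, n_chars >= 1, n_states >= 2, n_states <= 4,
            change_prob >= 0, change_prob < 1,
            missing_frac >= 0, missing_frac <= 1)
  structure(list(n_taxa = as.integer(n_taxa), n_chars = as.integer(n_chars),
                 n_states = as.integer(n_states), change_prob = change_prob,
                 missing_frac = missing_frac, seed = as.integer(seed)),
            class = "sim_config")
}

#' Uniform random unrooted binary topology
#'
#' Sequential random edge attachment: each new leaf is inserted on an edge
#' drawn uniformly, which yields the uniform distribution over unrooted
#' binary topologies. Deterministic per seed.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param seed RNG seed.
#' @param labels optional leaf labels (default `t1..tn`).
#' @return a `phylo`.
#' @export
random_tree <- function(n_taxa, seed, labels = NULL) {
  if (n_taxa < 3) stop("size error: need at least 3 taxa")
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n_taxa))
  n <- as.integer(n_taxa)
  with_seed(seed, {
    parent <- integer(2L * n - 2L)
    parent[n + 1L] <- 1L; parent[2L] <- n + 1L; parent[3L] <- n + 1L
    if (n > 3L) for (t in 4L:n) {
      m <- n + t - 2L
      cand <- c(seq_len(t - 1L)[-1], (n + 1L):(n + t - 3L))
      c <- cand[sample.int(length(cand), 1L)]
      p <- parent[c]
      parent[m] <- p; parent[c] <- m; parent[t] <- m
    }
    ptree_to_phylo(ptree(parent, labels))
  })
}

#' Simulate a character matrix on a known tree
#'
#' For each character a root state is drawn uniformly; along every branch the
#' state switches, with probability `change_prob`, to a different state drawn
#' uniformly; finally each leaf cell is masked missing with probability
#' `missing_frac`. The generating tree is recorded in the result so recovery
#' experiments never have to re-derive it.
#'
#' @param tree binary `phylo` (the generating tree).
#' @param config a [sim_config()].
#' @return a [char_matrix()] with attributes `true_tree` (the generating
#'   `phylo`) and `config`.
#' @export
simulate_matrix <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  labels <- tip_to_label(tree$tip.label)
  pt <- ptree_from_phylo(tree, labels = sort(labels))
  n <- pt$ntip
  ch <- ptree_children(pt)
  depth <- ptree_depths(pt)
  ord <- order(depth)                      # parents before children
  with_seed(config$seed, {
    states <- matrix(NA_integer_, n, config$n_chars)
    for (j in seq_len(config$n_chars)) {
      st <- integer(length(pt$parent))
      st[1] <- sample.int(config$n_states, 1L) - 1L
      for (v in seq_along(pt$parent)[ord][-1]) {
        p <- pt$parent[v]
        if (p == 0L) next
        s <- st[p]
        if (runif(1) < config$change_prob) {
          others <- setdiff(0:(config$n_states - 1L), s)
          s <- others[sample.int(length(others), 1L)]
        }
        st[v] <- s
      }
      states[, j] <- st[seq_len(n)]
    }
    mask <- matrix(runif(n * config$n_chars) < config$missing_frac,
                   n, config$n_chars)
    states[mask] <- NA_integer_
    out <- char_matrix(states, taxa = pt$labels)
    attr(out, "true_tree") <- tree
    attr(out, "config") <- config
    out
  })
}

#' Homoplasy-free matrix for a tree
#'
#' One binary character per internal edge, with state 1 exactly on one side
#' of that edge. The generating tree is the unique most parsimonious tree
#' for the matrix, every character fits it perfectly (s = m = 1), and CI and
#' RI are both 1 on it.
#'
#' @param tree binary `phylo` with at least 4 leaves.
#' @return a [char_matrix()] with attribute `true_tree`.
#' @export
perfect_matrix <- function(tree) {
  labels <- tip_to_label(tree$tip.label)
  n <- length(labels)
  if (n < 4) stop("size error: no internal edges on fewer than 4 leaves")
  pt <- ptree_from_phylo(tree, labels = sort(labels))
  keys <- ptree_split_keys(pt)
  states <- matrix(0L, n, length(keys))
  rownames(states) <- sort(labels)
  for (j in seq_along(keys))
    states[split_members(keys[j]), j] <- 1L
  out <- char_matrix(states, taxa = sort(labels))
  attr(out, "true_tree") <- tree
  out
}
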