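#' Search configuration
#'
#' Settings for [heuristic_search()]. Defaults are desk-scale: the 13-taxon
#' problem the package ships converges in far fewer random-addition
#' replicates than the large production settings (1000 replicates, 10,000
#' retained trees) that remain reachable here.
#'
#' @param seed RNG seed (required; every run is reproducible).
#' @param n_replicates number of random-addition-sequence replicates.
#' @param max_trees cap on equally optimal trees retained.
#' @param move rearrangement neighborhood: `"nni"`, `"spr"` or `"tbr"`.
#' @param steepest if `TRUE` (default) move to the best neighbor each round;
#'   otherwise accept the first improving neighbor.
#' @return a `search_config` list.
#' @export
search_config <- function(seed, n_replicates = 20, max_trees = 10000,
                          move = c("tbr", "spr", "nni"), steepest = TRUE) {
  move <- match.arg(move)
  if (missing(seed) || !is.finite(seed)) stop("a numeric seed is required")
  if (n_replicates < 1 || max_trees < 1) stop("replicates and max_trees must be >= 1")
  structure(list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
                 max_trees = as.integer(max_trees), move = move,
                 steepest = isTRUE(steepest)),
            class = "search_config")
}

#' Enumerate all unrooted binary topologies
#'
#' Generates every unrooted binary tree on the given leaves exactly once, by
#' recursive leaf insertion; there are (2n-5)!! of them. Guarded to n <= 10.
#'
#' @param taxa character vector of leaf labels (3 to 10 of them).
#' @param fun optional callback applied to each `phylo`; when supplied, trees
#'   are streamed rather than accumulated and the call returns the count.
#' @return list of `phylo` trees, or (with `fun`) the integer count.
#' @export
enumerate_topologies <- function(taxa, fun = NULL) {
  n <- length(taxa)
  if (n < 3 || n > 10) stop("size error: enumeration supported for 3..10 taxa")
  out <- if (is.null(fun)) vector("list", num_topologies(n))
  count <- 0L
  parent <- integer(2L * n - 2L)
  parent[n + 1L] <- 1L; parent[2L] <- n + 1L; parent[3L] <- n + 1L
  emit <- function(parent) {
    count <<- count + 1L
    tr <- ptree_to_phylo(ptree(parent, taxa))
    if (is.null(fun)) out[[count]] <<- tr else fun(tr)
  }
  recurse <- function(parent, k) {
    if (k == n) { emit(parent); return(invisible()) }
    t <- k + 1L; m <- n + t - 2L
    for (c in c(seq_len(k)[-1], if (k > 2L) (n + 1L):(n + k - 2L))) {
      p <- parent[c]
      parent[m] <- p; parent[c] <- m; parent[t] <- m
      recurse(parent, k + 1L)
      parent[c] <- p; parent[m] <- 0L; parent[t] <- 0L
    }
  }
  if (n == 3L) emit(parent) else recurse(parent, 3L)
  if (is.null(fun)) out else count
}

#' Number of unrooted binary topologies
#'
#' The double factorial (2n-5)!!.
#'
#' @param n_taxa number of leaves (>= 3).
#' @return numeric count.
#' @export
num_topologies <- function(n_taxa) {
  if (n_taxa < 3) stop("size error: need at least 3 taxa")
  if (n_taxa == 3) return(1)
  prod(seq(3, 2 * n_taxa - 5, by = 2))
}

# max-divergence addition order: seed with the most divergent pair, then
# greedily append the taxon with the largest summed mismatch to those chosen
addition_order <- function(matrix) {
  st <- matrix$states
  n <- nrow(st)
  dist <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cmp <- st[i, ] != st[j, ]
    d <- sum(cmp, na.rm = TRUE)
    dist[i, j] <- dist[j, i] <- d
  }
  pick <- which(dist == max(dist), arr.ind = TRUE)[1, ]
  order <- as.integer(pick)
  while (length(order) < n) {
    rest <- setdiff(seq_len(n), order)
    gain <- vapply(rest, function(r) sum(dist[r, order]), 0)
    order <- c(order, rest[which.max(gain)])
  }
  order
}

# per-level lower bound on extra steps from taxa not yet added: each state
# seen only among later additions costs at least one further step, except
# that a character with no state seen yet gets one state for free (its root)
level_lower_bounds <- function(matrix, order) {
  st <- matrix$states[order, , drop = FALSE]
  n <- nrow(st)
  lb <- integer(n + 1L)
  for (k in 0:n) {
    extra <- 0L
    for (j in seq_len(ncol(st))) {
      seen <- unique(st[seq_len(k), j]); seen <- seen[!is.na(seen)]
      later <- unique(st[setdiff(seq_len(n), seq_len(k)), j])
      later <- later[!is.na(later)]
      new_states <- length(setdiff(later, seen))
      if (!length(seen)) new_states <- max(0L, new_states - 1L)
      extra <- extra + new_states
    }
    lb[k + 1L] <- extra
  }
  lb
}

#' Exact maximum parsimony search by branch and bound
#'
#' Finds the optimal tree length and every binary topology attaining it.
#' Taxa are added in a max-divergence order for tight early bounds; the
#' initial upper bound comes from a greedy addition tree. Exact for the
#' matrix sizes the package targets (guarded to 16 taxa).
#'
#' @param matrix a [char_matrix()].
#' @param max_trees cap on retained optimal topologies.
#' @return an `mpt_set`: list with `score`, `trees` (list of `phylo`),
#'   `exact = TRUE` and `hit_cap`.
#' @export
branch_and_bound <- function(matrix, max_trees = 10000) {
  n <- n_taxa(matrix)
  if (n > 16) stop("size error: branch and bound guarded to 16 taxa; use heuristic_search()")
  if (n < 4) stop("size error: need at least 4 taxa")
  ord <- addition_order(matrix)
  taxa_ord <- matrix$taxa[ord]
  masks <- tip_masks(matrix, tip_order = taxa_ord)
  lb <- level_lower_bounds(matrix, ord)
  # greedy upper bound: insert each taxon at its best position
  ub <- greedy_addition_score(masks, n)
  res <- bab_cpp(masks, lb, ub, as.integer(max_trees))
  trees <- lapply(res$trees, function(par) ptree_to_phylo(ptree(par, taxa_ord)))
  structure(list(score = res$score, trees = trees, exact = TRUE,
                 hit_cap = res$hit_cap, nodes_visited = res$nodes_visited),
            class = "mpt_set")
}

#' @export
print.mpt_set <- function(x, ...) {
  cat(sprintf("mpt_set: %d tree(s) at score %d (%s%s)\n", length(x$trees),
              x$score, if (x$exact) "exact" else "heuristic",
              if (isTRUE(x$hit_cap)) ", tree cap hit" else ""))
  invisible(x)
}

greedy_addition_score <- function(masks, n) {
  parent <- integer(2L * n - 2L)
  parent[n + 1L] <- 1L; parent[2L] <- n + 1L; parent[3L] <- n + 1L
  for (t in seq(4L, n)) {
    m <- n + t - 2L
    cand <- c(seq_len(t - 1L)[-1], if (t > 4L) (n + 1L):(n + t - 3L) else (n + 1L))
    best_len <- Inf; best <- NULL
    for (c in cand) {
      p <- parent[c]
      parent[m] <- p; parent[c] <- m; parent[t] <- m
      len <- sum(fitch_steps_cpp(parent, n, masks))
      if (len < best_len) { best_len <- len; best <- c }
      parent[c] <- p; parent[m] <- 0L; parent[t] <- 0L
    }
    p <- parent[best]
    parent[m] <- p; parent[best] <- m; parent[t] <- m
  }
  sum(fitch_steps_cpp(parent, n, masks))
}

# one random-addition-sequence tree; ties among equal-score insertions are
# broken by a seeded RNG draw
random_addition_ptree <- function(masks, labels) {
  n <- length(labels)
  perm <- sample.int(n)
  masks_p <- masks[perm, , drop = FALSE]
  parent <- integer(2L * n - 2L)
  parent[n + 1L] <- 1L; parent[2L] <- n + 1L; parent[3L] <- n + 1L
  for (t in seq_len(n)[-seq_len(3L)]) {
    m <- n + t - 2L
    cand <- c(seq_len(t - 1L)[-1], (n + 1L):(n + t - 3L))
    lens <- numeric(length(cand))
    for (i in seq_along(cand)) {
      c <- cand[i]; p <- parent[c]
      parent[m] <- p; parent[c] <- m; parent[t] <- m
      lens[i] <- sum(fitch_steps_cpp(parent, n, masks_p))
      parent[c] <- p; parent[m] <- 0L; parent[t] <- 0L
    }
    ties <- which(lens == min(lens))
    pickd <- if (length(ties) > 1L) sample(ties, 1L) else ties
    best <- cand[pickd]
    p <- parent[best]
    parent[m] <- p; parent[best] <- m; parent[t] <- m
  }
  ptree(parent, labels[perm])
}

#' Rearrangement neighborhoods
#'
#' All distinct topologies one NNI, SPR or TBR move away from a binary tree.
#' The neighborhoods nest: every NNI neighbor is an SPR neighbor, every SPR
#' neighbor a TBR neighbor.
#'
#' @param tree binary `phylo`, n >= 4.
#' @param move `"nni"`, `"spr"` or `"tbr"`.
#' @return list of `phylo` trees (the input topology excluded).
#' @export
neighbors <- function(tree, move = c("nni", "spr", "tbr")) {
  move <- match.arg(move)
  labels <- sort(tip_to_label(tree$tip.label))
  pt <- ptree_from_phylo(tree, labels)
  at <- atree_from_ptree(pt)
  pts <- switch(move,
                nni = nni_moves(at),
                spr = spr_moves(at),
                tbr = tbr_moves(at))
  self <- topology_key(pt)
  keys <- vapply(pts, topology_key, "")
  keep <- !duplicated(keys) & keys != self
  lapply(pts[keep], ptree_to_phylo)
}

nni_moves <- function(at) {
  n <- at$ntip
  out <- list()
  ed <- atree_edges(at)
  for (e in seq_len(nrow(ed))) {
    u <- ed[e, 1]; v <- ed[e, 2]
    if (u <= n || v <= n) next
    a_nb <- setdiff(at$adj[[u]], v)
    c_nb <- setdiff(at$adj[[v]], u)
    for (cn in c_nb) {
      adj2 <- at$adj
      a <- a_nb[1]
      adj2 <- adj_del(adj2, u, a); adj2 <- adj_del(adj2, v, cn)
      adj2 <- adj_add(adj2, u, cn); adj2 <- adj_add(adj2, v, a)
      out[[length(out) + 1L]] <- ptree_from_atree(list(adj = adj2, ntip = n, labels = at$labels))
    }
  }
  out
}

spr_moves <- function(at) {
  n <- at$ntip
  out <- list()
  ed <- atree_edges(at)
  for (e in seq_len(nrow(ed))) {
    for (dir in 1:2) {
      u <- ed[e, dir]; v <- ed[e, 3 - dir]   # prune the u-side, regraft into v-side
      side_u <- atree_side(at, u, v)
      adj2 <- adj_del(at$adj, u, v)
      vn <- adj2[[v]]
      if (length(vn) == 2L) adj2 <- adj_suppress(adj2, v)
      # candidate regraft edges in the v-side component
      for (x in seq_along(adj2)) {
        if (side_u[x]) next
        for (w in adj2[[x]]) {
          if (w < x || side_u[w]) next
          new_node <- length(adj2) + 1L
          adj3 <- c(adj2, list(integer(0)))
          adj3 <- adj_del(adj3, x, w)
          adj3 <- adj_add(adj3, x, new_node)
          adj3 <- adj_add(adj3, w, new_node)
          adj3 <- adj_add(adj3, u, new_node)
          out[[length(out) + 1L]] <-
            ptree_from_atree(list(adj = adj3, ntip = n, labels = at$labels))
        }
      }
    }
  }
  out
}

tbr_moves <- function(at) {
  n <- at$ntip
  out <- list()
  ed <- atree_edges(at)
  for (e in seq_len(nrow(ed))) {
    u <- ed[e, 1]; v <- ed[e, 2]
    side_u <- atree_side(at, u, v)
    adj0 <- adj_del(at$adj, u, v)
    fix_side <- function(adj, node) {
      if (length(adj[[node]]) == 2L) adj_suppress(adj, node) else adj
    }
    adj0 <- fix_side(adj0, u); adj0 <- fix_side(adj0, v)
    # attachment points per side: every edge (as pair) or, for a bare leaf /
    # cherry root, the dangling node itself
    points <- function(in_side) {
      pts <- list()
      nodes <- which(if (in_side) side_u else !side_u)
      deg <- lengths(adj0)
      for (x in nodes) {
        if (deg[x] == 0L && x <= n) pts[[length(pts) + 1L]] <- x   # isolated leaf
        for (w in adj0[[x]]) if (w > x) pts[[length(pts) + 1L]] <- c(x, w)
      }
      if (!length(pts)) pts <- list(if (in_side) u else v)
      pts
    }
    pu <- points(TRUE); pv <- points(FALSE)
    for (a in pu) for (b in pv) {
      adj3 <- adj0
      attach <- integer(2)
      for (k in 1:2) {
        pt_k <- if (k == 1) a else b
        if (length(pt_k) == 1L) attach[k] <- pt_k
        else {
          new_node <- length(adj3) + 1L
          adj3 <- c(adj3, list(integer(0)))
          adj3 <- adj_del(adj3, pt_k[1], pt_k[2])
          adj3 <- adj_add(adj3, pt_k[1], new_node)
          adj3 <- adj_add(adj3, pt_k[2], new_node)
          attach[k] <- new_node
        }
      }
      adj3 <- adj_add(adj3, attach[1], attach[2])
      out[[length(out) + 1L]] <-
        ptree_from_atree(list(adj = adj3, ntip = n, labels = at$labels))
    }
  }
  out
}

#' Heuristic maximum parsimony search
#'
#' Random-addition-sequence starting trees (taxa shuffled by the seeded RNG,
#' each inserted at its best position) refined by hill-climbing with the
#' configured rearrangement move, replicated, pooled and deduplicated; a
#' final sweep collects equally optimal neighbors of the pooled trees. The
#' result is deterministic for a given matrix and configuration.
#'
#' @param matrix a [char_matrix()].
#' @param config a [search_config()].
#' @return an `mpt_set` (with `exact = FALSE`).
#' @export
heuristic_search <- function(matrix, config) {
  stopifnot(inherits(config, "search_config"))
  taxa <- matrix$taxa
  n <- length(taxa)
  masks_by_label <- tip_masks(matrix, tip_order = taxa)
  eval_pt <- function(pt) {
    masks <- masks_by_label[match(pt$labels, taxa), , drop = FALSE]
    sum(fitch_steps_cpp(pt$parent, pt$ntip, masks))
  }
  climb <- function(pt) {
    len <- eval_pt(pt)
    repeat {
      at <- atree_from_ptree(pt)
      cand <- switch(config$move, nni = nni_moves(at), spr = spr_moves(at),
                     tbr = tbr_moves(at))
      best_len <- len; best <- NULL
      for (q in cand) {
        l <- eval_pt(q)
        if (l < best_len ||
            (!config$steepest && l < len)) { best_len <- l; best <- q }
        if (!config$steepest && !is.null(best)) break
      }
      if (is.null(best)) break
      pt <- best; len <- best_len
    }
    list(pt = pt, len = len)
  }
  pool <- list(); pool_keys <- character(0); best <- Inf
  with_seed(config$seed, {
    for (r in seq_len(config$n_replicates)) {
      start <- random_addition_ptree(masks_by_label, taxa)
      res <- climb(start)
      if (res$len < best) { best <- res$len; pool <- list(); pool_keys <- character(0) }
      if (res$len == best) {
        k <- topology_key(res$pt)
        if (!(k %in% pool_keys) && length(pool) < config$max_trees) {
          pool[[length(pool) + 1L]] <- res$pt; pool_keys <- c(pool_keys, k)
        }
      }
    }
  })
  # final pass: absorb equally optimal neighbors of the pooled trees,
  # sweeping additions too, until closure or the tree cap
  i <- 1L
  while (i <= length(pool) && length(pool) < config$max_trees) {
    at <- atree_from_ptree(pool[[i]])
    cand <- switch(config$move, nni = nni_moves(at), spr = spr_moves(at),
                   tbr = tbr_moves(at))
    for (q in cand) {
      if (length(pool) >= config$max_trees) break
      if (eval_pt(q) == best) {
        k <- topology_key(q)
        if (!(k %in% pool_keys)) {
          pool[[length(pool) + 1L]] <- q; pool_keys <- c(pool_keys, k)
        }
      }
    }
    i <- i + 1L
  }
  ord <- order(pool_keys)
  structure(list(score = best, trees = lapply(pool[ord], ptree_to_phylo),
                 exact = FALSE, hit_cap = length(pool) >= config$max_trees,
                 config = config),
            class = "mpt_set")
}

#' Collapse internal edges with zero minimum length
#'
#' Contracts every internal edge whose minimum number of changes, summed over
#' characters and minimized over all most-parsimonious reconstructions, is
#' zero. Used to deduplicate most-parsimonious trees under the collapsed
#' convention and as input to consensus methods.
#'
#' @param tree binary `phylo` over the matrix taxa.
#' @param matrix a [char_matrix()].
#' @return a (possibly multifurcating) `phylo`.
#' @export
collapse_min_length_zero <- function(tree, matrix) {
  leaves <- tip_to_label(tree$tip.label)
  order_in_matrix <- matrix$taxa[matrix$taxa %in% leaves]
  pt <- ptree_from_phylo(tree, labels = order_in_matrix)
  keep <- collapse_kept_clusters(pt, matrix)
  tree_from_clusters(keep, pt$labels)
}

# clusters (label sets) of internal edges carrying at least one forced change
collapse_kept_clusters <- function(pt, matrix) {
  n <- pt$ntip
  forced_total <- integer(length(pt$parent))
  for (j in seq_len(matrix$n_chars)) {
    allowed <- allowed_states(matrix, pt$labels, j)
    dp <- dp_one_char(pt, allowed)
    prof <- edge_change_profile(pt, dp)
    for (v in seq_along(prof))
      if (!is.null(prof[[v]]) && prof[[v]]$forced)
        forced_total[v] <- forced_total[v] + 1L
  }
  sets <- ptree_clades(pt)
  keep <- list()
  for (v in seq_along(sets)) {
    s <- sets[[v]]
    if (is.null(s) || length(s) < 2L || length(s) > n - 2L) next
    if (forced_total[v] > 0L) keep[[length(keep) + 1L]] <- sort(pt$labels[s])
  }
  keep
}
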