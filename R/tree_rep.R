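## Internal tree encoding
##
## Unrooted binary trees are handled internally as "ptree" objects: a parent
## vector over node ids 1..2n-2 where tips are 1..n (in the order of a label
## vector) and the tree is rooted, for traversal only, at tip 1 (parent 0).
## Rooting at a leaf adds no node, so the encoding is in bijection with
## unrooted topologies and every internal node has exactly two children.

ptree <- function(parent, labels) {
  list(parent = as.integer(parent), ntip = length(labels), labels = labels)
}

ptree_children <- function(pt) {
  n_nodes <- length(pt$parent)
  ch <- vector("list", n_nodes)
  for (v in seq_len(n_nodes)[-1]) {
    p <- pt$parent[v]
    if (p > 0) ch[[p]] <- c(ch[[p]], v)
  }
  ch
}

# phylo (ape) -> ptree; `labels` fixes the tip-index order (printed-form labels)
ptree_from_phylo <- function(phy, labels = NULL) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' tree")
  phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  if (n < 3) stop("trees with fewer than 3 leaves are not supported here")
  if (phy$Nnode != n - 2L || nrow(phy$edge) != 2L * n - 3L)
    stop("shape error: tree is not an unrooted binary topology")
  tips <- tip_to_label(phy$tip.label)
  if (is.null(labels)) labels <- sort(tips)
  idx <- match(tips, labels)
  if (anyNA(idx) || length(labels) != n)
    stop("label error: tree leaves do not match the supplied taxon labels")
  # adjacency in phylo ids
  adj <- vector("list", n + phy$Nnode)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1]; b <- phy$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  start <- which(idx == 1L)          # phylo id of our tip 1
  parent <- integer(2L * n - 2L)
  next_internal <- n
  new_id <- integer(length(adj))
  for (t in seq_len(n)) new_id[t] <- idx[t]
  visited <- logical(length(adj))
  stack <- list(c(start, 0L))        # (phylo node, our parent id)
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- top[1]; par_our <- top[2]
    visited[v] <- TRUE
    if (v > n && new_id[v] == 0L) {
      next_internal <- next_internal + 1L
      new_id[v] <- next_internal
    }
    parent[new_id[v]] <- par_our
    for (w in adj[[v]]) if (!visited[w])
      stack[[length(stack) + 1L]] <- c(w, new_id[v])
  }
  ptree(parent, labels)
}

ptree_to_phylo <- function(pt) {
  ch <- ptree_children(pt)
  labs <- label_to_tip(pt$labels)
  rec <- function(v) {
    if (v <= pt$ntip) return(labs[v])
    paste0("(", paste(vapply(ch[[v]], rec, ""), collapse = ","), ")")
  }
  v <- ch[[1]][1]
  nwk <- if (pt$ntip == 3L || is.null(ch[[v]])) {
    paste0("(", paste(labs, collapse = ","), ");")
  } else {
    paste0("(", labs[1], ",",
           paste(vapply(ch[[v]], rec, ""), collapse = ","), ");")
  }
  ape::read.tree(text = nwk)
}

# descendant tip-index sets for every internal node (rooted at tip 1)
ptree_clades <- function(pt) {
  n <- pt$ntip
  ch <- ptree_children(pt)
  sets <- vector("list", length(pt$parent))
  # process internal nodes deepest-first
  depth <- integer(length(pt$parent))
  for (v in seq_along(pt$parent)) {
    d <- 0L; u <- v
    while (pt$parent[u] > 0L) { u <- pt$parent[u]; d <- d + 1L }
    depth[v] <- d
  }
  internals <- which(seq_along(pt$parent) > n & vapply(ch, length, 0L) > 0)
  for (v in internals[order(depth[internals], decreasing = TRUE)]) {
    s <- integer(0)
    for (c in ch[[v]]) s <- c(s, if (c <= n) c else sets[[c]])
    sets[[v]] <- sort(s)
  }
  sets
}

# non-trivial bipartitions as canonical label keys: the side not containing
# the alphabetically first leaf (stable across tip orderings)
ptree_split_keys <- function(pt) {
  n <- pt$ntip
  sets <- ptree_clades(pt)
  keys <- character(0)
  for (v in seq_along(sets)) {
    s <- sets[[v]]
    if (is.null(s) || length(s) < 2L || length(s) > n - 2L) next
    side <- canonical_split_side(pt$labels[s], pt$labels)
    if (is.null(side)) next
    keys <- c(keys, split_key(side))
  }
  sort(keys)
}

split_key <- function(members) paste(sort(members), collapse = "\r")
split_members <- function(key) strsplit(key, "\r", fixed = TRUE)[[1]]

# canonical topology identity (two trees equal iff equal split sets)
topology_key <- function(pt) paste(ptree_split_keys(pt), collapse = "\n")

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the leaves in two; the split
#' is reported as the side that does not contain the reference taxon (the
#' alphabetically first leaf). Pendant (trivial) splits are omitted.
#'
#' @param tree a `phylo` tree.
#' @return list of character vectors of taxon labels.
#' @export
bipartitions <- function(tree) {
  labels <- tip_to_label(tree$tip.label)
  n <- length(labels)
  keys <- character(0)
  for (nd in seq_len(tree$Nnode)) {
    tips <- labels[descendant_tips(tree, n + nd)]
    side <- canonical_split_side(tips, labels)
    if (is.null(side)) next
    keys <- c(keys, split_key(side))
  }
  lapply(sort(unique(keys)), split_members)
}

# Build a (possibly multifurcating) phylo realizing exactly the given
# compatible clusters (label sets not containing the reference leaf).
tree_from_clusters <- function(clusters, labels) {
  labels <- unique(labels)
  clusters <- unique(lapply(clusters, sort))
  sizes <- vapply(clusters, length, 0L)
  clusters <- clusters[order(-sizes)]
  build <- function(members, avail) {
    inside <- avail[vapply(avail, function(cl) all(cl %in% members), TRUE)]
    parts <- character(0)
    used <- character(0)
    while (length(inside)) {
      cl <- inside[[1]]
      inside <- inside[-1]
      sub <- inside[vapply(inside, function(x) all(x %in% cl), TRUE)]
      inside <- inside[!vapply(inside, function(x) all(x %in% cl), TRUE)]
      parts <- c(parts, build(cl, sub))
      used <- c(used, cl)
    }
    singles <- setdiff(members, used)
    items <- c(parts, label_to_tip(singles))
    if (length(items) == 1L) items else paste0("(", paste(items, collapse = ","), ")")
  }
  nwk <- paste0(build(labels, clusters), ";")
  ape::read.tree(text = nwk)
}

## ---- adjacency form for rearrangement surgery ----

atree_from_ptree <- function(pt) {
  adj <- vector("list", length(pt$parent))
  for (v in seq_along(pt$parent)) {
    p <- pt$parent[v]
    if (p > 0) { adj[[v]] <- c(adj[[v]], p); adj[[p]] <- c(adj[[p]], v) }
  }
  list(adj = adj, ntip = pt$ntip, labels = pt$labels)
}

ptree_from_atree <- function(at) {
  n <- at$ntip
  parent <- integer(2L * n - 2L)
  new_id <- integer(length(at$adj))
  for (t in seq_len(n)) new_id[t] <- t
  next_internal <- n
  visited <- logical(length(at$adj))
  stack <- list(c(1L, 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- top[1]; par_our <- top[2]
    visited[v] <- TRUE
    if (v > n) {
      if (new_id[v] == 0L) { next_internal <- next_internal + 1L; new_id[v] <- next_internal }
    }
    parent[new_id[v]] <- par_our
    for (w in at$adj[[v]]) if (!visited[w])
      stack[[length(stack) + 1L]] <- c(w, new_id[v])
  }
  ptree(parent, at$labels)
}

adj_del <- function(adj, u, v) {
  adj[[u]] <- adj[[u]][adj[[u]] != v]
  adj[[v]] <- adj[[v]][adj[[v]] != u]
  adj
}
adj_add <- function(adj, u, v) {
  adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  adj
}
# remove a now degree-2 node, joining its two neighbors
adj_suppress <- function(adj, v) {
  nb <- adj[[v]]
  stopifnot(length(nb) == 2L)
  adj <- adj_del(adj, v, nb[1]); adj <- adj_del(adj, v, nb[2])
  adj_add(adj, nb[1], nb[2])
}

atree_edges <- function(at) {
  out <- NULL
  for (v in seq_along(at$adj)) for (w in at$adj[[v]]) if (v < w)
    out <- rbind(out, c(v, w))
  out
}

# component membership after deleting edge (u,v): TRUE for nodes on u's side
atree_side <- function(at, u, v) {
  side <- logical(length(at$adj))
  stack <- u; side[u] <- TRUE
  while (length(stack)) {
    x <- stack[[1]]; stack <- stack[-1]
    for (w in at$adj[[x]]) {
      if (x == u && w == v) next
      if (!side[w]) { side[w] <- TRUE; stack <- c(stack, w) }
    }
  }
  side
}
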