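#' Ensemble fit indices of a tree
#'
#' Tree length `L = sum(s)`, ensemble consistency index `CI = sum(m)/sum(s)`
#' and ensemble retention index `RI = (sum(g)-sum(s))/(sum(g)-sum(m))`,
#' computed from the per-character fits of [fitch_length()]. By default all
#' characters enter the sums (the convention of the classic parsimony
#' programs); `informative_only = TRUE` restricts them to
#' parsimony-informative characters (`g > m`). Unrounded values are returned;
#' use [round_half_up()] (2 decimals) at the reporting layer.
#'
#' @param tree binary `phylo` over the matrix taxa.
#' @param matrix a [char_matrix()].
#' @param informative_only drop parsimony-uninformative characters from the
#'   ensemble sums.
#' @return list with `L`, `CI`, `RI` and the per-character `fits` data frame.
#' @export
ensemble_indices <- function(tree, matrix, informative_only = FALSE) {
  fl <- fitch_length(tree, matrix)
  f <- fl$fits
  use <- if (informative_only) f$g > f$m else rep(TRUE, nrow(f))
  S <- sum(f$s[use]); M <- sum(f$m[use]); G <- sum(f$g[use])
  if (S == 0) {
    warning("no variation: total observed steps is zero; CI reported as 1")
    ci <- 1
  } else ci <- M / S
  ri <- if (G == M) 1 else (G - S) / (G - M)
  list(L = fl$length, CI = ci, RI = ri, fits = f)
}

#' Flag homoplastic characters on a tree
#'
#' A character is homoplastic on a tree when it needs more steps there than
#' its conceivable minimum (`s > m`, i.e. per-character `ci < 1`).
#'
#' @inheritParams ensemble_indices
#' @return logical vector, one flag per character.
#' @export
homoplasy_flags <- function(tree, matrix) {
  f <- fitch_length(tree, matrix)$fits
  f$s > f$m
}

#' Character changes supporting a branch
#'
#' Lists the characters whose most-parsimonious reconstruction places a state
#' change on the branch subtending the given taxon set, with the derived
#' state(s). With `policy = "any"` (default) a character is listed when at
#' least one most-parsimonious reconstruction puts a change there; with
#' `"acctran"` or `"deltran"` only the changes of that specific
#' reconstruction count.
#'
#' @param tree binary `phylo` over the matrix taxa.
#' @param matrix a [char_matrix()].
#' @param branch character vector of taxon labels: the clade side of the
#'   branch (not containing `root_taxon`).
#' @param policy `"any"`, `"acctran"` or `"deltran"`.
#' @param root_taxon taxon whose pendant edge carries the display root;
#'   defaults to the first matrix taxon on the tree.
#' @return data frame with columns `char` and `derived_state` (one row per
#'   change; a character can appear with several feasible derived states
#'   under `"any"`).
#' @export
synapomorphies <- function(tree, matrix, branch,
                           policy = c("any", "acctran", "deltran"),
                           root_taxon = NULL) {
  policy <- match.arg(policy)
  leaves <- tip_to_label(tree$tip.label)
  branch <- squish(branch)
  if (!all(branch %in% leaves))
    stop("lookup error: branch taxa absent from tree: ",
         paste(setdiff(branch, leaves), collapse = ", "))
  ord <- matrix$taxa[matrix$taxa %in% leaves]
  if (is.null(root_taxon)) root_taxon <- setdiff(ord, branch)[1]
  root_taxon <- squish(root_taxon)
  if (root_taxon %in% branch) stop("argument error: root taxon inside the branch")
  ord <- c(root_taxon, setdiff(ord, root_taxon))
  pt <- ptree_from_phylo(tree, labels = ord)
  sets <- ptree_clades(pt)
  want <- sort(match(branch, pt$labels))
  v <- NULL
  for (i in seq_along(sets))
    if (!is.null(sets[[i]]) && identical(sets[[i]], want)) { v <- i; break }
  if (length(branch) == 1L) v <- match(branch, pt$labels)
  if (is.null(v)) stop("lookup error: branch not present in tree")
  rows <- list()
  for (j in seq_len(matrix$n_chars)) {
    allowed <- allowed_states(matrix, pt$labels, j)
    if (policy == "any") {
      dp <- dp_one_char(pt, allowed)
      prof <- edge_change_profile(pt, dp)[[v]]
      if (!is.null(prof) && prof$can_change && length(prof$derived))
        rows[[length(rows) + 1L]] <- data.frame(char = j,
                                                derived_state = prof$derived)
    } else {
      state <- if (policy == "acctran") acctran_assign(pt, allowed)
               else deltran_assign(pt, dp_one_char(pt, allowed))
      if (state[v] != state[pt$parent[v]])
        rows[[length(rows) + 1L]] <- data.frame(char = j,
                                                derived_state = state[v])
    }
  }
  if (!length(rows)) return(data.frame(char = integer(0), derived_state = integer(0)))
  do.call(rbind, rows)
}

#' Ancestral state reconstruction for one character
#'
#' Most-parsimonious node states on the display-rooted tree under a chosen
#' resolution policy. `"acctran"` accelerates transformations (changes pulled
#' toward the root), `"deltran"` delays them, `"unambiguous"` reports the full
#' MPR state set of every node (singletons are the states shared by all
#' most-parsimonious reconstructions). The implied number of changes always
#' equals the character's Fitch step count.
#'
#' @inheritParams synapomorphies
#' @param char_index 1-based character index.
#' @param policy `"acctran"`, `"deltran"` or `"unambiguous"`.
#' @return list with `node_states` (data frame: node, clade label string,
#'   states), `changes` (data frame: node, from, to — empty for
#'   `"unambiguous"`) and `steps`.
#' @export
ancestral_states <- function(tree, matrix, char_index,
                             policy = c("acctran", "deltran", "unambiguous"),
                             root_taxon = NULL) {
  policy <- match.arg(policy)
  if (char_index < 1 || char_index > matrix$n_chars)
    stop("argument error: invalid character index")
  leaves <- tip_to_label(tree$tip.label)
  ord <- matrix$taxa[matrix$taxa %in% leaves]
  if (is.null(root_taxon)) root_taxon <- ord[1]
  ord <- c(squish(root_taxon), setdiff(ord, squish(root_taxon)))
  pt <- ptree_from_phylo(tree, labels = ord)
  allowed <- allowed_states(matrix, pt$labels, char_index)
  dp <- dp_one_char(pt, allowed)
  sets <- ptree_clades(pt)
  clade_of <- function(v) {
    if (v <= pt$ntip) pt$labels[v]
    else paste(sort(pt$labels[sets[[v]]]), collapse = "+")
  }
  nn <- length(pt$parent)
  if (policy == "unambiguous") {
    mpr <- dp_mpr_sets(dp)
    node_states <- data.frame(
      node = seq_len(nn),
      clade = vapply(seq_len(nn), clade_of, ""),
      states = vapply(mpr, function(s) paste(s, collapse = "/"), ""))
    changes <- data.frame(node = integer(0), from = integer(0), to = integer(0))
  } else {
    state <- if (policy == "acctran") acctran_assign(pt, allowed)
             else deltran_assign(pt, dp)
    node_states <- data.frame(node = seq_len(nn),
                              clade = vapply(seq_len(nn), clade_of, ""),
                              states = as.character(state))
    changes <- assignment_changes(pt, state)
    changes$clade <- vapply(changes$node, clade_of, "")
  }
  list(node_states = node_states, changes = changes, steps = dp$L)
}

#' Strict consensus tree
#'
#' The tree whose internal bipartitions are exactly those shared by every
#' input tree.
#'
#' @param trees list of `phylo` trees (or an `mpt_set`) on one leaf set.
#' @return a `phylo` (multifurcating where the inputs disagree).
#' @export
strict_consensus <- function(trees) {
  trees <- as_tree_list(trees)
  keys <- shared_leafset_keys(trees)
  common <- Reduce(intersect, keys)
  labels <- sort(tip_to_label(trees[[1]]$tip.label))
  tree_from_clusters(lapply(common, split_members), labels)
}

#' Majority-rule consensus tree
#'
#' Contains the bipartitions occurring in at least a `threshold` fraction of
#' the input trees, annotated with their frequencies (as node labels).
#' Threshold 1 reproduces the strict consensus.
#'
#' @param trees list of `phylo` trees (or an `mpt_set`) on one leaf set.
#' @param threshold fraction in (0.5, 1]; values at or below 0.5 are refused
#'   because incompatible bipartitions could then co-occur.
#' @return a `phylo` with node labels giving split frequencies.
#' @export
majority_rule <- function(trees, threshold = 0.5 + 1e-9) {
  if (threshold <= 0.5 || threshold > 1)
    stop("argument error: threshold must be in (0.5, 1]")
  trees <- as_tree_list(trees)
  keys <- shared_leafset_keys(trees)
  tab <- table(unlist(keys)) / length(trees)
  keep <- names(tab)[tab >= threshold]
  labels <- sort(tip_to_label(trees[[1]]$tip.label))
  cons <- tree_from_clusters(lapply(keep, split_members), labels)
  annotate_splits(cons, stats::setNames(as.numeric(tab[keep]), keep))
}

as_tree_list <- function(trees) {
  if (inherits(trees, "mpt_set")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("argument error: empty tree set")
  trees
}

shared_leafset_keys <- function(trees) {
  leafsets <- lapply(trees, function(t) sort(tip_to_label(t$tip.label)))
  if (length(unique(vapply(leafsets, paste, "", collapse = "\r"))) != 1L)
    stop("label error: trees do not share one leaf set")
  lapply(trees, function(t)
    ptree_split_keys(ptree_from_phylo(t, labels = leafsets[[1]])))
}

# canonical split side: the side not containing the reference (alphabetically
# first) taxon; NULL when trivial
canonical_split_side <- function(tips, labels) {
  ref <- sort(labels)[1]
  side <- if (ref %in% tips) setdiff(labels, tips) else tips
  if (length(side) < 2L || length(side) > length(labels) - 2L) return(NULL)
  sort(side)
}

# write per-split values into the node labels of a phylo
annotate_splits <- function(tree, values) {
  labels <- tip_to_label(tree$tip.label)
  n <- length(labels)
  tree$node.label <- rep("", tree$Nnode)
  for (nd in seq_len(tree$Nnode)) {
    tips <- labels[descendant_tips(tree, n + nd)]
    side <- canonical_split_side(tips, labels)
    if (is.null(side)) next
    key <- split_key(side)
    tree$node.label[nd] <- if (key %in% names(values))
      format(round(values[[key]], 3)) else "0"
  }
  tree
}

descendant_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
  }
  sort(out)
}

#' Per-character fit table
#'
#' One row per character: observed steps, bounds, indices and homoplasy flag
#' on the given tree; suitable for CSV export.
#'
#' @inheritParams ensemble_indices
#' @return data frame with columns `char`, `m`, `s`, `g`, `ci`, `ri`,
#'   `homoplastic`.
#' @export
character_fit_table <- function(tree, matrix) {
  f <- fitch_length(tree, matrix)$fits
  data.frame(char = f$char, m = f$m, s = f$s, g = f$g, ci = f$ci, ri = f$ri,
             homoplastic = f$s > f$m)
}
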