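## Fitch parsimony engine

# Bitmask encoding of leaf states for the C++ kernel. A missing cell enters
# the pass as the union of the states observed among the non-missing leaves of
# that character (an all-missing character gets a single dummy state and so
# contributes zero steps).
tip_masks <- function(matrix, tip_order = matrix$taxa) {
  st <- matrix$states[match(tip_order, matrix$taxa), , drop = FALSE]
  if (anyNA(match(tip_order, matrix$taxa)))
    stop("lookup error: tree leaf not present in the character matrix")
  masks <- matrix(0L, nrow = nrow(st), ncol = ncol(st))
  for (j in seq_len(ncol(st))) {
    col <- st[, j]
    obs <- unique(col[!is.na(col)])
    full <- if (length(obs)) sum(bitwShiftL(1L, obs)) else 1L
    masks[, j] <- ifelse(is.na(col), full, bitwShiftL(1L, col))
  }
  masks
}

# evaluate a ptree against precomputed masks
ptree_steps <- function(pt, masks) {
  fitch_steps_cpp(pt$parent, pt$ntip, masks)
}

#' Parsimony length of a tree
#'
#' Computes the minimum number of state changes (steps) each unordered,
#' equally weighted character requires on a binary tree, by the Fitch
#' bottom-up pass, together with the per-character fit quantities: observed
#' steps `s`, minimum conceivable steps `m`, maximum conceivable (star-tree)
#' steps `g`, and the derived consistency (`ci = m/s`) and retention
#' (`ri = (g-s)/(g-m)`) indices. The result does not depend on where the
#' unrooted tree is rooted for traversal.
#'
#' @param tree a binary `phylo` tree whose leaves are (a subset of) the
#'   matrix taxa.
#' @param matrix a [char_matrix()].
#' @return list with `length` (total steps) and `fits`, a data frame with one
#'   row per character (`char`, `s`, `m`, `g`, `ci`, `ri`).
#' @export
fitch_length <- function(tree, matrix) {
  leaves <- tip_to_label(tree$tip.label)
  order_in_matrix <- matrix$taxa[matrix$taxa %in% leaves]
  if (length(order_in_matrix) != length(leaves))
    stop("lookup error: tree leaves absent from the matrix: ",
         paste(setdiff(leaves, matrix$taxa), collapse = ", "))
  pt <- ptree_from_phylo(tree, labels = order_in_matrix)
  masks <- tip_masks(matrix, tip_order = order_in_matrix)
  s <- as.integer(ptree_steps(pt, masks))
  sub <- matrix$states[match(order_in_matrix, matrix$taxa), , drop = FALSE]
  m <- apply(sub, 2, min_steps)
  g <- apply(sub, 2, max_steps)
  ci <- ifelse(s == 0, 1, m / s)
  ri <- ifelse(g == m, 1, (g - s) / (g - m))
  fits <- data.frame(char = seq_len(matrix$n_chars), s = s, m = m, g = g,
                     ci = ci, ri = ri)
  list(length = sum(s), fits = fits)
}

#' Minimum conceivable steps of a character
#'
#' The number of distinct non-missing states minus one (never negative): any
#' tree needs at least this many changes to exhibit all observed states.
#'
#' @param char_column vector of states with `NA` for missing.
#' @return integer.
#' @export
min_steps <- function(char_column) {
  obs <- char_column[!is.na(char_column)]
  max(0L, length(unique(obs)) - 1L)
}

#' Maximum conceivable steps of a character
#'
#' The star-tree (worst-case) step count: the number of non-missing leaves
#' minus the frequency of the most common state.
#'
#' @param char_column vector of states with `NA` for missing.
#' @return integer.
#' @export
max_steps <- function(char_column) {
  obs <- char_column[!is.na(char_column)]
  if (!length(obs)) return(0L)
  length(obs) - max(tabulate(match(obs, unique(obs))))
}

#' Brute-force parsimony length of one character
#'
#' Exact minimum, over all assignments of single states to internal nodes
#' (and to missing leaves), of the number of tree edges whose endpoints
#' differ. Enumerative oracle for [fitch_length()]; guarded to small trees.
#'
#' @param tree a binary `phylo` with at most 8 leaves.
#' @param char_column states per leaf, named by taxon label (or in the order
#'   of the tree's tip labels); `NA` = missing.
#' @return integer minimum step count.
#' @export
brute_force_length <- function(tree, char_column) {
  n <- length(tree$tip.label)
  if (n > 8) stop("size error: brute force enumeration is limited to 8 leaves")
  labs <- tip_to_label(tree$tip.label)
  if (!is.null(names(char_column))) {
    char_column <- char_column[match(labs, squish(names(char_column)))]
  }
  if (length(char_column) != n) stop("one state per leaf required")
  states <- sort(unique(char_column[!is.na(char_column)]))
  if (length(states) <= 1L) return(0L)
  pt <- ptree_from_phylo(tree, labels = labs)
  edges <- cbind(which(pt$parent > 0), pt$parent[pt$parent > 0])
  free <- c(which(is.na(char_column)), (n + 1):(2L * n - 2L))
  ncomb <- length(states)^length(free)
  if (ncomb > 2e6) stop("size error: assignment grid too large")
  assign_grid <- as.matrix(expand.grid(rep(list(states), length(free))))
  g <- nrow(assign_grid)
  node_states <- matrix(rep(c(char_column, integer(n - 2L)), each = g),
                        nrow = g)
  node_states[, free] <- assign_grid
  len <- integer(g)
  for (e in seq_len(nrow(edges)))
    len <- len + (node_states[, edges[e, 1]] != node_states[, edges[e, 2]])
  as.integer(min(len))
}
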