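#' Root a tree on an outgroup's pendant edge
#'
#' Returns a rooted orientation of the (unrooted) tree with the root placed
#' on the pendant edge of the chosen outgroup taxon; the underlying unrooted
#' topology is unchanged.
#'
#' @param tree a `phylo`.
#' @param outgroup_taxon taxon label (printed form, spaces allowed).
#' @return a rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup_taxon) {
  tip <- label_to_tip(squish(outgroup_taxon))
  if (!(tip %in% tree$tip.label))
    stop("label error: unknown taxon '", outgroup_taxon, "'")
  ape::root(tree, outgroup = tip, resolve.root = TRUE)
}

#' Is a taxon set monophyletic?
#'
#' TRUE when the group members form exactly one complete clade of the tree
#' rooted at `root_taxon`. Equivalently (and computed this way), when the
#' member set appears as one side of a bipartition of the unrooted tree, the
#' root taxon lying on the other side; singleton groups are always
#' monophyletic.
#'
#' @param tree a `phylo`.
#' @param group character vector of taxon labels (or a name from
#'   [named_groups()]).
#' @param root_taxon outgroup taxon used to orient the tree; must not belong
#'   to the group.
#' @return logical.
#' @export
is_monophyletic <- function(tree, group, root_taxon) {
  if (length(group) == 1L && group %in% names(named_groups()))
    group <- named_groups()[[group]]
  group <- squish(group)
  root_taxon <- squish(root_taxon)
  leaves <- tip_to_label(tree$tip.label)
  missing_leaves <- setdiff(group, leaves)
  if (length(missing_leaves))
    stop("label error: group members absent from tree: ",
         paste(missing_leaves, collapse = ", "))
  if (root_taxon %in% group)
    stop("argument error: root taxon belongs to the queried group")
  if (!(root_taxon %in% leaves))
    stop("label error: unknown root taxon '", root_taxon, "'")
  if (length(group) <= 1L) return(TRUE)
  if (setequal(group, setdiff(leaves, root_taxon))) return(TRUE)
  ord <- c(root_taxon, sort(setdiff(leaves, root_taxon)))
  pt <- ptree_from_phylo(tree, labels = ord)
  side <- canonical_split_side(group, leaves)
  if (is.null(side)) return(TRUE)   # trivial split: complement is a singleton
  split_key(side) %in% ptree_split_keys(pt)
}

#' Percentage coverage of a taxon universe
#'
#' `100 * |included| / |universe|`, rounded half-up to the nearest integer.
#'
#' @param included character vector (subset of `universe`).
#' @param universe non-empty character vector.
#' @return integer percentage.
#' @export
coverage_percent <- function(included, universe) {
  universe <- unique(squish(universe))
  included <- unique(squish(included))
  if (!length(universe)) stop("argument error: empty universe")
  if (!all(included %in% universe))
    stop("argument error: included taxa outside the universe")
  as.integer(round_half_up(100 * length(included) / length(universe)))
}
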