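# Tree utilities shared by the parsimony/likelihood searches and the
# classification rule: exhaustive topology enumeration, nearest-neighbor
# interchange, bipartition bookkeeping and monophyly tests.
# Trees are ape "phylo" objects throughout.

#' Enumerate all unrooted binary topologies over a label set
#'
#' Stepwise-addition enumeration; the number of topologies is
#' (2n-5)!! so this is only feasible for small n (guarded at n <= 8,
#' i.e. 10395 trees).
#'
#' @param labels Character vector of >= 3 unique leaf labels.
#' @return List of unrooted `phylo` trees without branch lengths.
#' @export
enumerate_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3, n <= 8, !anyDuplicated(labels))
  trees <- list(list(labels[1], labels[2], labels[3]))
  if (n > 3) {
    for (k in 4:n) {
      newtrees <- list()
      for (tr in trees)
        newtrees <- c(newtrees, insert_on_each_edge(tr, labels[k]))
      trees <- newtrees
    }
  }
  lapply(trees, function(tr)
    ape::read.tree(text = paste0(nested_to_newick(tr), ";")))
}

# A tree here is a nested list: top level has 3 children; internal nodes
# are lists of 2; leaves are label strings. Every child slot is an edge.
insert_on_each_edge <- function(tr, x) {
  out <- list()
  recurse <- function(node, path) {
    for (i in seq_along(node)) {
      child <- node[[i]]
      out[[length(out) + 1L]] <<- modify_at(tr, c(path, i), x)
      if (is.list(child)) recurse(child, c(path, i))
    }
  }
  recurse(tr, integer(0))
  out
}

modify_at <- function(tr, path, x) {
  if (length(path) == 1L) {
    tr[[path]] <- list(tr[[path]], x)
    return(tr)
  }
  tr[[path[1]]] <- modify_at(tr[[path[1]]], path[-1], x)
  tr
}

nested_to_newick <- function(node) {
  if (!is.list(node)) return(quote_newick(node))
  paste0("(", paste(vapply(node, nested_to_newick, ""), collapse = ","), ")")
}

# Unroot only when needed (ape::unroot is comparatively expensive and
# most trees here are already unrooted).
unroot_fast <- function(tree) {
  if (tree$Nnode <= length(tree$tip.label) - 2L) tree
  else ape::unroot(tree)
}

# Children map of a phylo edge matrix.
children_of <- function(tree) {
  split(tree$edge[, 2], factor(tree$edge[, 1],
                               levels = seq_len(length(tree$tip.label) + tree$Nnode)))
}

# Serialize a (possibly re-wired) edge matrix back to newick, topology only.
edge_to_newick <- function(edge, tip_label, root) {
  kids <- split(edge[, 2], edge[, 1])
  ntip <- length(tip_label)
  rec <- function(node) {
    if (node <= ntip) return(quote_newick(tip_label[node]))
    paste0("(", paste(vapply(kids[[as.character(node)]], rec, ""),
                      collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Nearest-neighbor-interchange neighborhood of an unrooted tree
#'
#' @param tree An unrooted binary `phylo` with >= 4 tips.
#' @return List of unrooted `phylo` topologies (branch lengths dropped),
#'   two per internal edge.
#' @export
nni_neighbors <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4) return(list())
  rt <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[1],
                  resolve.root = TRUE)
  rt$edge.length <- NULL
  E <- rt$edge
  rootnode <- ntip + 1L
  internal <- which(E[, 2] > ntip & E[, 1] != rootnode)
  out <- list()
  for (k in internal) {
    u <- E[k, 1]; v <- E[k, 2]
    rows_v <- which(E[, 1] == v)
    row_c <- setdiff(which(E[, 1] == u), k)
    for (sw in rows_v) {
      E2 <- E
      E2[sw, 1] <- u
      E2[row_c, 1] <- v
      nwk <- edge_to_newick(E2, rt$tip.label, rootnode)
      out[[length(out) + 1L]] <- ape::unroot(ape::read.tree(text = nwk))
    }
  }
  out
}

# Canonical bipartition keys for the internal edges of an unrooted tree.
# Each key is the comma-joined sorted tip set on the side *not* containing
# the alphabetically first tip.
tree_splits <- function(tree) {
  tree <- unroot_fast(tree)
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- character(0)
  nodes <- integer(0)
  for (i in seq_along(pp)) {
    node <- ntip + i
    if (node == ntip + 1L) next  # root pseudo-clade = trivial split
    tips <- labs[pp[[i]]]
    if (anchor %in% tips) tips <- setdiff(labs, tips)
    if (length(tips) < 2 || length(tips) > ntip - 2) next
    keys <- c(keys, paste(sort(tips), collapse = ","))
    nodes <- c(nodes, node)
  }
  names(keys) <- nodes
  keys
}

split_key <- function(tips, all_labels) {
  anchor <- sort(all_labels)[1]
  if (anchor %in% tips) tips <- setdiff(all_labels, tips)
  paste(sort(tips), collapse = ",")
}

# Tip labels below a node of a (rooted) phylo.
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- children_of(tree)
  acc <- character(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd <= ntip) acc <- c(acc, tree$tip.label[nd])
    else stack <- c(stack, kids[[nd]])
  }
  acc
}

#' Test whether two leaves form an exclusive clade after rooting
#'
#' Roots the tree at `outgroup` and asks whether the smallest clade
#' containing `a` and `b` contains no other leaves, i.e. whether `a` and
#' `b` are sisters in the rooted tree.
#'
#' @param tree A `phylo`.
#' @param a,b Leaf labels of the pair.
#' @param outgroup Leaf label used to root the tree.
#' @return `TRUE` or `FALSE`.
#' @export
is_monophyletic_pair <- function(tree, a, b, outgroup) {
  labs <- tree$tip.label
  missing <- setdiff(c(a, b, outgroup), labs)
  if (length(missing))
    stop("labels not in tree: ", paste(missing, collapse = ", "))
  if (a == b || a == outgroup || b == outgroup)
    stop("a, b and outgroup must be distinct leaves")
  rt <- ape::root(ape::unroot(tree), outgroup = outgroup,
                  resolve.root = TRUE)
  m <- ape::getMRCA(rt, c(a, b))
  setequal(clade_tips(rt, m), c(a, b))
}

# The single-leaf sister of `tip` in the unrooted tree, or NA if its
# neighborhood does not form a two-leaf split.
sister_leaf <- function(tree, tip) {
  tree <- unroot_fast(tree)
  ntip <- length(tree$tip.label)
  t_idx <- match(tip, tree$tip.label)
  if (is.na(t_idx)) stop("tip not in tree: ", tip)
  p <- tree$edge[tree$edge[, 2] == t_idx, 1]
  sibs <- setdiff(tree$edge[tree$edge[, 1] == p, 2], t_idx)
  if (p == ntip + 1L) {
    # basal trichotomy: {tip, x, rest} still carries the pair split
    # {tip, x} when exactly one of the other two children is a leaf
    tip_sibs <- sibs[sibs <= ntip]
    if (length(sibs) == 2 && length(tip_sibs) == 1)
      return(tree$tip.label[tip_sibs])
    return(NA_character_)
  }
  if (length(sibs) == 1 && sibs <= ntip) tree$tip.label[sibs]
  else NA_character_
}

# Least-squares branch lengths for a fixed topology given a distance
# matrix; negative estimates are clamped to a small positive floor.
# An edge lies on the i-j path iff exactly one of i, j is in the tip set
# below that edge.
ls_branch_lengths <- function(tree, d, floor = 1e-8) {
  tree <- stats::reorder(unroot_fast(tree), "postorder")
  labs <- tree$tip.label
  n <- length(labs)
  E <- tree$edge
  ne <- nrow(E)
  # tips-below membership per edge (tips x edges)
  below <- matrix(FALSE, n + tree$Nnode, n)
  below[cbind(seq_len(n), seq_len(n))] <- TRUE
  M <- matrix(FALSE, n, ne)
  for (k in seq_len(ne)) {
    M[, k] <- below[E[k, 2], ]
    below[E[k, 1], ] <- below[E[k, 1], ] | below[E[k, 2], ]
  }
  pairs <- utils::combn(n, 2)
  A <- (M[pairs[1, ], , drop = FALSE] + M[pairs[2, ], , drop = FALSE]) == 1
  y <- d[cbind(labs[pairs[1, ]], labs[pairs[2, ]])]
  bl <- tryCatch(as.numeric(qr.solve(A * 1, y)),
                 error = function(e) rep(mean(y) / 2, ne))
  bl[!is.finite(bl) | bl < floor] <- floor
  tree$edge.length <- bl
  tree
}
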