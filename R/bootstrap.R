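# Nonparametric bootstrap support for tree bipartitions.

#' Phylogenetic analysis configuration
#'
#' Bootstrap replicate numbers follow the original in-group analysis
#' protocol: 1000 replicates for neighbor-joining trees and 100 for
#' maximum-parsimony trees; maximum-likelihood support is computed as the
#' bootstrap of the likelihood search, with 100 replicates by default.
#'
#' @param nj_reps,mp_reps,ml_reps Bootstrap replicate counts (>= 1).
#' @param exhaustive_cap Largest number of taxa for which tree searches
#'   enumerate all topologies (hard limit 8).
#' @param mp_restarts Seeded random restarts of the parsimony hill-climb.
#' @param ml_refine_k Number of screened topologies refined by full
#'   branch-length optimization in the exhaustive likelihood search.
#' @param ml_tol Tolerance of the per-edge branch-length optimization.
#' @param seed Integer seed controlling all stochastic steps.
#' @return A list of class `phylo_config`.
#' @export
phylo_config <- function(nj_reps = 1000, mp_reps = 100, ml_reps = 100,
                         exhaustive_cap = 8, mp_restarts = 2,
                         ml_refine_k = 3, ml_tol = 1e-4, seed = 1) {
  stopifnot(nj_reps >= 1, mp_reps >= 1, ml_reps >= 1,
            exhaustive_cap >= 4, exhaustive_cap <= 8)
  structure(list(nj_reps = nj_reps, mp_reps = mp_reps, ml_reps = ml_reps,
                 exhaustive_cap = exhaustive_cap, mp_restarts = mp_restarts,
                 ml_refine_k = ml_refine_k, ml_tol = ml_tol, seed = seed),
            class = "phylo_config")
}

#' Bootstrap support for the bipartitions of a point-estimate tree
#'
#' Alignment columns are resampled with replacement `reps` times; each
#' replicate alignment is passed to `rep_builder` and the fraction of
#' replicate trees containing each internal bipartition of the point
#' estimate (built by `builder` on the original alignment) is attached as
#' integer percentages in the tree's node labels. Reproducible for a fixed
#' seed.
#'
#' @param aln A [motif_alignment()].
#' @param builder Function alignment -> `phylo`, the point estimate.
#' @param reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param focus Optional tip label: additionally counts, for every other
#'   tip `r`, the fraction of replicate trees in which `focus` and `r`
#'   form a two-leaf split (used by the orthology decision rule).
#' @param rep_builder Tree builder used on the replicates; defaults to
#'   `builder`. Heuristic searches typically use a faster variant here.
#' @return List with `tree` (point estimate, support in `$node.label`),
#'   `support` (named vector, split key -> percentage), `pair_support`
#'   (if `focus` given: named percentage vector over the other tips) and
#'   `reps`.
#' @export
bootstrap_support <- function(aln, builder, reps = 100, seed = 1,
                              focus = NULL, rep_builder = builder) {
  stopifnot(reps >= 1)
  point <- ape::unroot(builder(aln))
  splits_pt <- tree_splits(point)
  counts <- stats::setNames(numeric(length(splits_pt)), splits_pt)
  pair_counts <- NULL
  if (!is.null(focus)) {
    others <- setdiff(aln$ids, focus)
    pair_counts <- stats::setNames(numeric(length(others)), others)
  }
  set.seed(seed)
  L <- aln$ncol
  used <- 0L
  for (r in seq_len(reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    baln <- structure(list(ids = aln$ids,
                           mat = aln$mat[, cols, drop = FALSE],
                           ncol = L), class = "motif_alignment")
    btree <- tryCatch(rep_builder(baln), error = function(e) NULL)
    if (is.null(btree)) next
    used <- used + 1L
    ks <- tree_splits(btree)
    hit <- names(counts) %in% ks
    counts[hit] <- counts[hit] + 1
    if (!is.null(focus)) {
      sis <- sister_leaf(btree, focus)
      if (!is.na(sis) && sis %in% names(pair_counts))
        pair_counts[sis] <- pair_counts[sis] + 1
    }
  }
  denom <- max(used, 1L)
  support <- round(100 * counts / denom)
  node_ids <- as.integer(names(splits_pt))
  ntip <- length(point$tip.label)
  labels <- rep("", point$Nnode)
  labels[node_ids - ntip] <- as.character(support[splits_pt])
  point$node.label <- labels
  out <- list(tree = point, support = support, reps = reps)
  if (!is.null(focus)) out$pair_support <- round(100 * pair_counts / denom)
  out
}
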