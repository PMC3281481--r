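# Fitch parsimony scoring and maximum-parsimony topology search.

ALL20_MASK <- bitwShiftL(1L, 20L) - 1L

# Bitmask encoding of alignment rows: one integer per cell, gaps and
# non-standard letters as the full (missing) state set.
alignment_masks <- function(aln) {
  idx <- match(aln$mat, AA_ALPHABET20)
  m <- matrix(bitwShiftL(1L, idx - 1L), nrow = nrow(aln$mat))
  m[is.na(m)] <- ALL20_MASK
  rownames(m) <- aln$ids
  m
}

#' Fitch parsimony score of a tree
#'
#' Sum over alignment columns of the minimal number of state changes under
#' Fitch's algorithm; gap and ambiguous characters are treated as missing
#' data (the full state set, contributing no forced change).
#'
#' @param tree A `phylo` whose tip labels equal the alignment row ids.
#' @param aln A [motif_alignment()].
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, aln) {
  if (!setequal(tree$tip.label, aln$ids))
    stop("tree tips and alignment rows do not match")
  masks <- alignment_masks(aln)
  tree <- stats::reorder(unroot_fast(tree), "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  L <- ncol(masks)
  S <- matrix(NA_integer_, nnode, L)
  S[seq_len(ntip), ] <- masks[tree$tip.label, , drop = FALSE]
  changes <- 0L
  E <- tree$edge
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]; ch <- E[k, 2]
    if (is.na(S[p, 1])) {
      S[p, ] <- S[ch, ]
    } else {
      inter <- bitwAnd(S[p, ], S[ch, ])
      empty <- inter == 0L
      changes <- changes + sum(empty)
      S[p, ] <- ifelse(empty, bitwOr(S[p, ], S[ch, ]), inter)
    }
  }
  changes
}

#' Maximum-parsimony tree search
#'
#' Exhaustive enumeration of unrooted topologies for small label sets
#' (<= `exhaustive_cap` taxa), otherwise a nearest-neighbor-interchange
#' hill-climb started from the neighbor-joining tree plus seeded random
#' restarts. Deterministic for fixed input and seed.
#'
#' @param aln A [motif_alignment()] with >= 4 rows.
#' @param config A [phylo_config()].
#' @param level `"full"` (default) or `"quick"`; `"quick"` always uses the
#'   NNI hill-climb without restarts (used inside bootstrap replicates).
#' @return A `phylo` topology with attribute `"score"` (the Fitch score).
#' @export
mp_search <- function(aln, config = phylo_config(), level = c("full", "quick")) {
  level <- match.arg(level)
  n <- length(aln$ids)
  if (n < 4) stop("need >= 4 sequences for a tree search")
  if (level == "full" && n <= config$exhaustive_cap) {
    trees <- enumerate_topologies(aln$ids)
    scores <- vapply(trees, fitch_score, 0L, aln = aln)
    ties <- which(scores == min(scores))
    if (length(ties) > 1) {
      # parsimony landscapes are flat on short motif alignments: break
      # score ties deterministically by least-squares fit to the
      # step-distance matrix
      d <- step_distance(aln)
      rss <- vapply(ties, function(k) {
        fit <- ls_branch_lengths(trees[[k]], d)
        sum((ape::cophenetic.phylo(fit)[rownames(d), colnames(d)] - d)^2)
      }, 0)
      ties <- ties[which.min(rss)]
    }
    best <- trees[[ties[1]]]
    attr(best, "score") <- min(scores)
    return(best)
  }
  start <- ape::unroot(neighbor_joining(step_distance(aln)))
  start$edge.length <- NULL
  climb <- function(tree) {
    sc <- fitch_score(tree, aln)
    repeat {
      nb <- nni_neighbors(tree)
      nsc <- vapply(nb, fitch_score, 0L, aln = aln)
      if (!length(nsc) || min(nsc) >= sc) break
      k <- which.min(nsc)
      tree <- nb[[k]]; sc <- nsc[k]
    }
    list(tree = tree, score = sc)
  }
  best <- climb(start)
  if (level == "full" && config$mp_restarts > 0) {
    for (r in seq_len(config$mp_restarts)) {
      set.seed(config$seed + r)
      rnd <- ape::rtopology(n, rooted = FALSE, tip.label = sample(aln$ids))
      rnd$edge.length <- NULL
      cand <- climb(ape::unroot(rnd))
      if (cand$score < best$score) best <- cand
    }
  }
  out <- best$tree
  attr(out, "score") <- best$score
  out
}
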