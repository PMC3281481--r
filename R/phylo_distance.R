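# Step-matrix distances from an alignment and deterministic
# neighbor-joining tree construction.

#' Step-matrix cost table from a similarity matrix
#'
#' Converts a similarity matrix S into substitution costs via
#' `cost(a, b) = (S(a,a) + S(b,b)) / 2 - S(a,b)`, the standard conversion
#' from log-odds similarities to a non-negative step matrix.
#'
#' @param S Symmetric similarity matrix over the 20 residues
#'   (default PAM250).
#' @return Symmetric non-negative cost matrix with zero diagonal.
#' @export
step_cost_matrix <- function(S = pam250_matrix()) {
  stopifnot(isSymmetric(unname(S)))
  self <- diag(S)
  cost <- (outer(self, self, "+")) / 2 - S
  dimnames(cost) <- dimnames(S)
  cost
}

#' Pairwise step-matrix distances between alignment rows
#'
#' Distance between two rows is the mean substitution cost over columns
#' where both rows have a residue (pairwise deletion of gaps), using a step
#' matrix derived from PAM250 by default.
#'
#' @param aln A [motif_alignment()].
#' @param S Similarity matrix used for the step-cost conversion.
#' @return Symmetric distance matrix with row/column labels.
#' @export
step_distance <- function(aln, S = pam250_matrix()) {
  if (length(aln$ids) < 2) stop("need at least 2 aligned sequences")
  cost <- step_cost_matrix(S)
  idx <- matrix(match(aln$mat, rownames(cost)), nrow = nrow(aln$mat))
  n <- nrow(idx)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sel <- !is.na(idx[i, ]) & !is.na(idx[j, ])
      if (!any(sel))
        stop("no shared non-gap columns between '", aln$ids[i], "' and '",
             aln$ids[j], "'")
      d[i, j] <- d[j, i] <- mean(cost[cbind(idx[i, sel], idx[j, sel])])
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining with deterministic tie-breaking
#' (the joined pair with the minimal Q value, ties resolved by the smallest
#' index pair) and negative branch lengths clamped to zero.
#'
#' @param d Symmetric distance matrix with unique labels (>= 3 taxa).
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(d) {
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels) || anyDuplicated(labels)) stop("labels must be unique")
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  frag <- sprintf("%s", quote_newick(labels))  # newick fragment per cluster
  D <- d
  fmt <- function(x) sprintf("%.10g", max(0, x))
  while (n > 3) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(bi), frag[j], fmt(bj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    n <- n - 1
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- D[1, 2] - b1
  b3 <- D[1, 3] - b1
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(b1), frag[2], fmt(b2),
                 frag[3], fmt(b3))
  ape::read.tree(text = nwk)
}

# Quote labels that would break newick syntax.
quote_newick <- function(x) {
  bad <- grepl("[,:;()\\[\\]' ]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}
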