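# Felsenstein pruning log-likelihood under the JTT model and a
# maximum-likelihood topology search with per-edge branch-length
# optimization.

# Integer-coded alignment (1..20, NA for gap/unknown).
alignment_codes <- function(aln) {
  m <- matrix(match(aln$mat, AA_ALPHABET20), nrow = nrow(aln$mat))
  rownames(m) <- aln$ids
  m
}

#' Log-likelihood of an alignment on a tree under the JTT model
#'
#' Felsenstein pruning with the empirical Jones-Taylor-Thornton rate
#' matrix and its stationary frequencies; sites are independent and gaps
#' are treated as missing data. Branch lengths are expected substitutions
#' per site.
#'
#' @param tree A `phylo` with non-negative branch lengths, tips matching
#'   the alignment rows.
#' @param aln A [motif_alignment()].
#' @return The log-likelihood (a single number).
#' @export
jtt_likelihood <- function(tree, aln) {
  if (!setequal(tree$tip.label, aln$ids))
    stop("tree tips and alignment rows do not match")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  codes <- alignment_codes(aln)
  e <- jtt_eigen()
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  L <- ncol(codes)
  lik <- vector("list", ntip + tree$Nnode)
  tipcodes <- codes[tree$tip.label, , drop = FALSE]
  E <- tree$edge
  bl <- tree$edge.length
  logscale <- 0
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]; ch <- E[k, 2]
    P <- e$U1 %*% (exp(e$lambda * bl[k]) * e$U2)
    P[P < 0] <- 0
    if (ch <= ntip) {
      cc <- tipcodes[ch, ]
      Lc <- matrix(0, 20, L)
      known <- !is.na(cc)
      Lc[cbind(cc[known], which(known))] <- 1
      Lc[, !known] <- 1
    } else {
      Lc <- lik[[ch]]
    }
    contrib <- P %*% Lc
    lik[[p]] <- if (is.null(lik[[p]])) contrib else lik[[p]] * contrib
    mx <- max(lik[[p]])
    if (mx < 1e-200 && mx > 0) {  # guard against underflow on deep trees
      lik[[p]] <- lik[[p]] / mx
      logscale <- logscale + log(mx)
    }
  }
  root <- E[nrow(E), 1]
  sum(log(colSums(e$pi * lik[[root]]))) + logscale
}

#' Optimize branch lengths of a fixed topology by coordinate ascent
#'
#' Each edge in turn is optimized by bounded one-dimensional search
#' (Brent) holding the others fixed, for a fixed number of sweeps.
#'
#' @param tree A `phylo` with starting branch lengths.
#' @param aln A [motif_alignment()].
#' @param tol Convergence tolerance of each one-dimensional search.
#' @param sweeps Number of passes over all edges.
#' @param max_bl Upper bound of a branch length.
#' @return List with `tree` (optimized lengths) and `loglik`.
#' @export
optimize_branch_lengths <- function(tree, aln, tol = 1e-4, sweeps = 2,
                                    max_bl = 10) {
  for (s in seq_len(sweeps)) {
    for (k in seq_len(nrow(tree$edge))) {
      f <- function(t) {
        tree$edge.length[k] <- t
        jtt_likelihood(tree, aln)
      }
      opt <- stats::optimize(f, c(1e-8, max_bl), maximum = TRUE, tol = tol)
      if (opt$objective >= f(tree$edge.length[k]))
        tree$edge.length[k] <- opt$maximum
    }
  }
  list(tree = tree, loglik = jtt_likelihood(tree, aln))
}

# Convert step-matrix distances to approximate substitutions per site:
# divide by the stationary expected cost of one substitution, then apply
# a Poisson multiple-hit correction.
step_to_subst <- function(d) {
  ec <- .bhlh_cache$expected_step_cost
  if (is.null(ec)) {
    cost <- step_cost_matrix()
    pi <- jtt_rate_matrix()$pi
    w <- pi %o% pi
    diag(w) <- 0
    ec <- sum(w * cost) / sum(w)
    .bhlh_cache$expected_step_cost <- ec
  }
  p <- pmin(d / ec, 0.95)
  t <- -log(1 - p)
  diag(t) <- 0
  t
}

# LS branch lengths from the step-distance matrix (converted to
# substitutions per site), then one likelihood evaluation: the quick
# score used to screen topologies.
screen_loglik <- function(topo, aln, d) {
  tr <- ls_branch_lengths(topo, step_to_subst(d))
  list(tree = tr, loglik = jtt_likelihood(tr, aln))
}

#' Maximum-likelihood tree search under the JTT model
#'
#' Topologies are enumerated exhaustively for small label sets
#' (<= `exhaustive_cap` taxa) and explored by nearest-neighbor-interchange
#' hill-climbing from the neighbor-joining tree otherwise. Candidate
#' topologies are screened with least-squares branch lengths; the best
#' candidates are then refined by per-edge branch-length optimization.
#'
#' @param aln A [motif_alignment()] with >= 4 rows.
#' @param config A [phylo_config()].
#' @param level `"full"` (default) refines the best screened topologies;
#'   `"quick"` returns the best screened topology with one fast refinement
#'   sweep (used inside bootstrap replicates).
#' @return A `phylo` with optimized branch lengths and attribute
#'   `"loglik"`.
#' @export
ml_search <- function(aln, config = phylo_config(), level = c("full", "quick")) {
  level <- match.arg(level)
  n <- length(aln$ids)
  if (n < 4) stop("need >= 4 sequences for a tree search")
  d <- step_distance(aln)
  if (level == "full" && n <= config$exhaustive_cap) {
    topos <- enumerate_topologies(aln$ids)
    screened <- lapply(topos, screen_loglik, aln = aln, d = d)
    lls <- vapply(screened, `[[`, 0, "loglik")
    keep <- order(lls, decreasing = TRUE)[seq_len(min(config$ml_refine_k, length(lls)))]
    best <- NULL
    for (k in keep) {
      ref <- optimize_branch_lengths(screened[[k]]$tree, aln,
                                     tol = config$ml_tol, sweeps = 2)
      # near-ties keep the higher-screened topology (stable tie-break)
      if (is.null(best) || ref$loglik > best$loglik + 1e-4) best <- ref
    }
  } else {
    start <- ape::unroot(neighbor_joining(d))
    cur <- screen_loglik(start, aln, d)
    repeat {
      nb <- nni_neighbors(cur$tree)
      if (!length(nb)) break
      cand <- lapply(nb, screen_loglik, aln = aln, d = d)
      lls <- vapply(cand, `[[`, 0, "loglik")
      if (max(lls) <= cur$loglik + 1e-9) break
      cur <- cand[[which.max(lls)]]
    }
    # support values depend on the topology only, so bootstrap replicates
    # ("quick") skip the branch-length refinement
    best <- if (level == "quick") cur
            else optimize_branch_lengths(cur$tree, aln, tol = config$ml_tol,
                                         sweeps = 2)
  }
  out <- best$tree
  attr(out, "loglik") <- best$loglik
  out
}
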