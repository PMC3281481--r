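# Motif alignment container and a simplified progressive aligner
# (guide tree from pairwise distances, profile-profile Needleman-Wunsch
# with sum-of-pairs PAM250 scoring).

#' Construct a motif alignment
#'
#' @param x Named character vector of equal-length gapped amino-acid strings
#'   (gap character `-`), or a character matrix with row names.
#' @return Object of class `motif_alignment`: a list with `ids`, `mat`
#'   (character matrix, one row per sequence) and `ncol`.
#' @export
motif_alignment <- function(x) {
  if (is.matrix(x)) {
    mat <- x
  } else {
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop("alignment rows must have unique names")
    n <- nchar(x)
    if (length(unique(n)) != 1L)
      stop("alignment rows must have equal length")
    mat <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(mat) <- names(x)
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("alignment rows must have unique names")
  all_gap <- apply(mat == "-", 2, all)
  if (any(all_gap)) mat <- mat[, !all_gap, drop = FALSE]
  structure(list(ids = rownames(mat), mat = mat, ncol = ncol(mat)),
            class = "motif_alignment")
}

#' @export
print.motif_alignment <- function(x, ...) {
  cat("motif_alignment:", length(x$ids), "sequences x", x$ncol, "columns\n")
  invisible(x)
}

#' Alignment rows as gapped strings
#' @param aln A `motif_alignment`.
#' @return Named character vector.
#' @export
alignment_strings <- function(aln) {
  stats::setNames(apply(aln$mat, 1, paste, collapse = ""), aln$ids)
}

#' Majority-rule consensus sequence of an alignment
#'
#' Per column, the most frequent non-gap residue (ties broken
#' alphabetically); columns that are entirely gaps are dropped.
#'
#' @param aln A `motif_alignment`.
#' @return List with `seq` (consensus string) and `columns` (the alignment
#'   column index behind each consensus position).
#' @export
consensus_sequence <- function(aln) {
  keep <- integer(0)
  res <- character(0)
  for (j in seq_len(aln$ncol)) {
    col <- aln$mat[, j]
    col <- col[col != "-" & col != "."]
    if (!length(col)) next
    tab <- sort(table(col), decreasing = TRUE)
    best <- names(tab)[tab == tab[1]]
    keep <- c(keep, j)
    res <- c(res, sort(best)[1])
  }
  list(seq = paste(res, collapse = ""), columns = keep)
}

#' Per-column residue frequencies
#' @param aln A `motif_alignment`.
#' @return 20 x ncol matrix of residue frequencies among non-gap characters.
#' @export
column_frequencies <- function(aln) {
  f <- matrix(0, 20, aln$ncol, dimnames = list(AA_ALPHABET20, NULL))
  for (j in seq_len(aln$ncol)) {
    col <- aln$mat[, j]
    col <- col[col %in% AA_ALPHABET20]
    if (length(col)) f[, j] <- tabulate(match(col, AA_ALPHABET20), 20) / length(col)
  }
  f
}

# Extended 21-letter scoring matrix for profile columns: PAM250 plus a gap
# state scored -4 against residues and 0 against itself.
profile_score_matrix <- function(gap_score = -4) {
  S <- rbind(cbind(pam250_matrix(), "-" = gap_score),
             "-" = c(rep(gap_score, 20), 0))
  colnames(S)[21] <- "-"
  S
}

# Column frequency profile over the 21-letter alphabet (gaps counted).
profile_freq <- function(mat) {
  ab <- c(AA_ALPHABET20, "-")
  L <- ncol(mat)
  f <- matrix(0, 21, L, dimnames = list(ab, NULL))
  for (j in seq_len(L)) {
    idx <- match(mat[, j], ab)
    idx[is.na(idx)] <- 21L  # X and friends scored like gaps
    tab <- tabulate(idx, 21)
    f[, j] <- tab / nrow(mat)
  }
  f
}

# Global profile-profile alignment, linear gap penalty; returns merged
# character matrix. Deterministic: ties prefer diagonal, then up.
align_profiles <- function(m1, m2, gap = 8) {
  S <- profile_score_matrix()
  f1 <- profile_freq(m1); f2 <- profile_freq(m2)
  CS <- t(f1) %*% S %*% f2            # column-vs-column scores
  g1 <- as.numeric(t(f1) %*% S[, 21]) # column vs all-gap
  g2 <- as.numeric(S[21, ] %*% f2)
  L1 <- nrow(CS); L2 <- ncol(CS)
  M <- matrix(-Inf, L1 + 1, L2 + 1)
  TB <- matrix(0L, L1 + 1, L2 + 1)    # 1 diag, 2 up (gap in m2), 3 left
  M[1, 1] <- 0
  M[, 1] <- c(0, cumsum(g1 - gap)); TB[-1, 1] <- 2L
  M[1, ] <- c(0, cumsum(g2 - gap)); TB[1, -1] <- 3L
  for (i in seq_len(L1)) {
    for (j in seq_len(L2)) {
      sc <- c(M[i, j] + CS[i, j], M[i, j + 1] + g1[i] - gap,
              M[i + 1, j] + g2[j] - gap)
      k <- which.max(sc)
      M[i + 1, j + 1] <- sc[k]
      TB[i + 1, j + 1] <- k
    }
  }
  # traceback
  i <- L1; j <- L2
  path <- list()
  while (i > 0 || j > 0) {
    k <- if (i == 0) 3L else if (j == 0) 2L else TB[i + 1, j + 1]
    path[[length(path) + 1L]] <- k
    if (k == 1L) { i <- i - 1; j <- j - 1 }
    else if (k == 2L) i <- i - 1
    else j <- j - 1
  }
  path <- rev(unlist(path))
  out1 <- matrix("-", nrow(m1), length(path))
  out2 <- matrix("-", nrow(m2), length(path))
  i <- 0; j <- 0
  for (p in seq_along(path)) {
    k <- path[p]
    if (k != 3L) { i <- i + 1; out1[, p] <- m1[, i] }
    if (k != 2L) { j <- j + 1; out2[, p] <- m2[, j] }
  }
  rownames(out1) <- rownames(m1); rownames(out2) <- rownames(m2)
  rbind(out1, out2)
}

#' Progressive multiple alignment of peptides
#'
#' Simplified ClustalW-like strategy: pairwise global alignment identities
#' give a distance matrix, a neighbor-joining guide tree orders
#' profile-profile merges, and profiles are aligned by global dynamic
#' programming with sum-of-pairs PAM250 scoring and a linear gap penalty.
#' Deterministic for fixed input.
#'
#' @param peptides Named character vector of ungapped amino-acid sequences.
#' @param gap Linear gap penalty per column (default 8).
#' @return A [motif_alignment()].
#' @export
progressive_align <- function(peptides, gap = 8) {
  if (is.null(names(peptides)) || anyDuplicated(names(peptides)))
    stop("peptides must have unique names")
  peptides <- toupper(peptides)
  n <- length(peptides)
  if (n == 0) stop("no peptides to align")
  if (n == 1)
    return(motif_alignment(peptides))
  profs <- lapply(peptides, function(s) {
    m <- matrix(strsplit(s, "")[[1]], nrow = 1)
    m
  })
  for (i in seq_len(n)) rownames(profs[[i]]) <- names(peptides)[i]
  if (n == 2) {
    merged <- align_profiles(profs[[1]], profs[[2]], gap = gap)
    return(motif_alignment(merged))
  }
  d <- pairwise_identity_distance(peptides)
  guide <- neighbor_joining(d)
  order_ops <- merge_order(guide)
  # cluster index per tip; merge following guide-tree postorder
  cluster <- as.list(seq_len(n))
  names(cluster) <- guide$tip.label
  profs <- profs[guide$tip.label]
  for (op in order_ops) {
    a <- op[1]; b <- op[2]
    merged <- align_profiles(profs[[a]], profs[[b]], gap = gap)
    profs[[a]] <- merged
    profs[b] <- NULL
  }
  final <- profs[[1]]
  final <- final[names(peptides), , drop = FALSE]
  motif_alignment(final)
}

# Distances for the guide tree: 1 - fraction identity of the global
# pairwise alignment under PAM250.
pairwise_identity_distance <- function(peptides) {
  n <- length(peptides)
  d <- matrix(0, n, n, dimnames = list(names(peptides), names(peptides)))
  pam <- get_pam250_full()
  for (i in seq_len(n - 1)) {
    pij <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(unname(peptides[(i + 1):n])),
      Biostrings::AAString(peptides[[i]]), type = "global",
      substitutionMatrix = pam, gapOpening = 10, gapExtension = 1)
    d[i, (i + 1):n] <- d[(i + 1):n, i] <- 1 - Biostrings::pid(pij) / 100
  }
  d
}

# Postorder merge schedule from a guide tree: list of (target, source)
# cluster names, where clusters are named after their first tip.
merge_order <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  rep_name <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  ops <- list()
  for (node in unique(tree$edge[, 1])) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    reps <- rep_name[children]
    for (k in 2:length(reps))
      ops[[length(ops) + 1L]] <- c(reps[1], reps[k])
    rep_name[node] <- reps[1]
  }
  # ensure postorder: nodes must be processed children-first
  ops
}
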