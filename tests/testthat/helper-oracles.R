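# Independent oracles used by the tests: brute-force local alignment,
# exhaustive Fitch labelings, codon-table translation and spliced-CDS
# extraction. These deliberately avoid the package's own code paths.

# Exhaustive affine-gap local alignment score by recursive enumeration of
# alignment paths over all substring pairs (feasible for tiny peptides).
brute_local_align <- function(query, target, S, gap_open = 11, gap_extend = 1) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  best <- 0
  # state: positions consumed, current score, gap state (0 none, 1 in-q, 2 in-t)
  rec <- function(i, j, sc, gs) {
    best <<- max(best, sc)
    if (i > length(q) || j > length(t)) return()
    rec(i + 1, j + 1, sc + S[q[i], t[j]], 0)
    rec(i + 1, j, sc - (if (gs == 1) gap_extend else gap_open + gap_extend), 1)
    rec(i, j + 1, sc - (if (gs == 2) gap_extend else gap_open + gap_extend), 2)
  }
  for (i in seq_along(q)) for (j in seq_along(t)) rec(i, j, 0, 0)
  best
}

# Minimal-change count by enumerating all internal-node labelings.
brute_fitch <- function(tree, aln) {
  mat <- aln$mat
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  E <- tree$edge
  total <- 0L
  aa20 <- rownames(bhlhscan::pam250_matrix())
  for (col in seq_len(ncol(mat))) {
    states <- mat[tree$tip.label, col]
    known <- states %in% aa20
    obs <- unique(states[known])
    if (length(obs) <= 1) next
    combos <- expand.grid(rep(list(obs), nint), stringsAsFactors = FALSE)
    bestc <- Inf
    for (r in seq_len(nrow(combos))) {
      lab <- c(states, unlist(combos[r, ]))
      changes <- 0L
      for (k in seq_len(nrow(E))) {
        a <- lab[E[k, 1]]; b <- lab[E[k, 2]]
        child_tip <- E[k, 2] <= ntip
        if (child_tip && !known[E[k, 2]]) next  # missing data: free
        if (a != b) changes <- changes + 1L
      }
      bestc <- min(bestc, changes)
    }
    total <- total + bestc
  }
  total
}

# Codon-by-codon translation using the standard genetic code table.
brute_translate <- function(nt) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(nt) %/% 3
  out <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(nt, 3 * i - 2, 3 * i)
    out[i] <- if (grepl("N", codon)) "X" else unname(code[codon])
  }
  paste(out, collapse = "")
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Spliced CDS of a truth/gff record, in transcription order.
spliced_cds <- function(genome, contig, strand, starts, ends) {
  s <- as.integer(strsplit(starts, ";")[[1]])
  e <- as.integer(strsplit(ends, ";")[[1]])
  o <- order(s)
  pieces <- substring(genome[[contig]], s[o], e[o])
  if (strand == "+") paste(pieces, collapse = "")
  else revcomp(paste(rev(pieces), collapse = ""))
}

# Random ungapped peptide alignment with given dimensions.
random_alignment <- function(n, L, ids = sprintf("t%d", seq_len(n))) {
  aa <- rownames(bhlhscan::pam250_matrix())
  motif_alignment(stats::setNames(
    vapply(seq_len(n), function(i)
      paste(sample(aa, L, replace = TRUE), collapse = ""), ""), ids))
}

# Small simulation config used across tests.
tiny_sim <- function(seed = 7, ...)
  simulation_config(n_contigs = 3, contig_length = 9000, n_implants = 4,
                    decoy_count = 6, seed = seed, ...)
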