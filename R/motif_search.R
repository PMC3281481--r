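# Six-frame translated search for candidate bHLH coding regions,
# deduplication, exon chaining and the 19-conserved-site filter.

#' Search configuration
#'
#' The permissive-search-then-filter structure replaces an E-value
#' threshold by a raw local-alignment score threshold under PAM250 with
#' affine gap costs (a length-k gap costs `gap_open + k * gap_extend`).
#' Hits below `min_score` are dropped after exon chaining; individual
#' exon segments need only reach `min_segment_score` so that motifs split
#' by an intron can be recovered by chaining segments up to
#' `max_chain_gap` apart on the same contig and strand.
#'
#' @param min_score Raw-score threshold for a retained candidate
#'   (default 40).
#' @param min_segment_score Per-segment score floor during scanning.
#' @param gap_open,gap_extend Affine gap costs (default 11/1).
#' @param max_chain_gap Maximum genomic gap (bp) bridged when chaining
#'   exon segments (default 50000).
#' @param chain_gap_penalty Score penalty per bp of bridged gap in the
#'   chain search (default 0.01, i.e. 10 points per kb), so joining a
#'   distant segment must be supported by real alignment signal and a
#'   segment joins its nearby true partner rather than a distant
#'   paralog's segment.
#' @param max_candidates_per_contig Cap on recorded hits per query, frame
#'   and contig.
#' @param overlap_fraction Interval-overlap fraction (of the shorter hit)
#'   at which two same-contig, same-frame hits are considered duplicates.
#' @param min_conserved Minimum number of matched conserved sites for a
#'   candidate to be kept (default 10 of 19).
#' @return List of class `search_config`.
#' @export
search_config <- function(min_score = 40, min_segment_score = 25,
                          gap_open = 11, gap_extend = 1,
                          max_chain_gap = 50000, chain_gap_penalty = 0.01,
                          max_candidates_per_contig = 6,
                          overlap_fraction = 0.5, min_conserved = 10) {
  stopifnot(min_score >= 0, min_segment_score >= 0, gap_open >= 0,
            gap_extend >= 0, overlap_fraction > 0, overlap_fraction <= 1,
            chain_gap_penalty >= 0)
  structure(list(min_score = min_score,
                 min_segment_score = min_segment_score,
                 gap_open = gap_open, gap_extend = gap_extend,
                 max_chain_gap = max_chain_gap,
                 chain_gap_penalty = chain_gap_penalty,
                 max_candidates_per_contig = max_candidates_per_contig,
                 overlap_fraction = overlap_fraction,
                 min_conserved = min_conserved),
            class = "search_config")
}

#' Six-frame conceptual translation
#'
#' Translates a nucleotide sequence in all three reading frames of both
#' strands under the standard genetic code. `N` translates to `X`, stop
#' codons to `*`; reverse frames translate the reverse complement.
#'
#' @param contig_seq Nucleotide string over A, C, G, T, N (case
#'   insensitive).
#' @return Named character vector of six peptides, frames
#'   `+1, +2, +3, -1, -2, -3`.
#' @export
six_frame_translate <- function(contig_seq) {
  contig_seq <- toupper(contig_seq)
  if (nchar(contig_seq) == 0)
    return(stats::setNames(rep("", 6), c("+1", "+2", "+3", "-1", "-2", "-3")))
  if (grepl("[^ACGTN]", contig_seq))
    stop("sequence contains non-nucleotide characters")
  fwd <- Biostrings::DNAString(contig_seq)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3
    if (n < 3) return("")
    as.character(Biostrings::translate(Biostrings::subseq(s, off + 1, off + n),
                                       if.fuzzy.codon = "X"))
  }
  stats::setNames(c(one(fwd, 0), one(fwd, 1), one(fwd, 2),
                    one(rev, 0), one(rev, 1), one(rev, 2)),
                  c("+1", "+2", "+3", "-1", "-2", "-3"))
}

#' Local alignment of two peptides
#'
#' Smith-Waterman local alignment under PAM250 with affine gap costs.
#' If no positive-scoring segment exists the score is 0 with empty
#' intervals.
#'
#' @param query,target Peptide strings.
#' @param config A [search_config()].
#' @return List with `score`, `query_interval`, `target_interval`
#'   (1-based inclusive; integer(0) when score is 0).
#' @export
local_align <- function(query, target, config = search_config()) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = get_pam250_full(),
    gapOpening = config$gap_open, gapExtension = config$gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0)
    return(list(score = 0, query_interval = integer(0),
                target_interval = integer(0)))
  list(score = sc,
       query_interval = c(IRanges::start(Biostrings::pattern(pa)),
                          IRanges::end(Biostrings::pattern(pa))),
       target_interval = c(IRanges::start(Biostrings::subject(pa)),
                           IRanges::end(Biostrings::subject(pa))))
}

# Peptide-frame coordinates -> forward-strand nucleotide interval.
frame_to_genomic <- function(frame, aa_start, aa_end, contig_len) {
  off <- abs(frame) - 1L
  nt_start <- off + 3L * (aa_start - 1L) + 1L
  nt_end <- off + 3L * aa_end
  if (frame > 0) c(nt_start, nt_end)
  else c(contig_len - nt_end + 1L, contig_len - nt_start + 1L)
}

#' Scan a genome or proteome for candidate bHLH motifs
#'
#' Every reading frame of every contig (genome mode) or every protein
#' (proteome mode) is locally aligned against every reference motif;
#' non-overlapping hits above the per-segment score floor are recorded,
#' iteratively masking found regions so that multiple copies per frame
#' are detected.
#'
#' @param panel A `reference_panel`.
#' @param target Named character vector of sequences (or an
#'   `XStringSet`).
#' @param config A [search_config()].
#' @param mode `"genome"` (six-frame translation) or `"proteome"`.
#' @return Data frame of hits: `contig`, `frame` (0 in proteome mode),
#'   `strand`, `start`, `end` (1-based inclusive forward-strand
#'   coordinates; amino-acid positions in proteome mode), `score`,
#'   `query`, `q_start`, `q_end`, `peptide`, `n_exons`, `exons`.
#' @export
scan_target <- function(panel, target, config = search_config(),
                        mode = c("genome", "proteome")) {
  mode <- match.arg(mode)
  if (nrow(panel) == 0) stop("reference panel is empty")
  if (methods::is(target, "XStringSet")) {
    target <- stats::setNames(as.character(target), names(target))
  }
  if (is.null(names(target)) || anyDuplicated(names(target)))
    stop("target sequences must have unique names")
  hits <- list()
  for (ctg in names(target)) {
    seqs <- if (mode == "genome") six_frame_translate(target[[ctg]])
            else stats::setNames(toupper(target[[ctg]]), "0")
    for (fr_name in names(seqs)) {
      pep <- seqs[[fr_name]]
      if (nchar(pep) < 5) next
      frame <- if (mode == "genome") as.integer(fr_name) else 0L
      hits[[length(hits) + 1L]] <-
        scan_frame(panel, pep, ctg, frame, nchar(target[[ctg]]), config)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) out <- empty_hits()
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(contig = character(), frame = integer(), strand = character(),
             start = integer(), end = integer(), score = numeric(),
             query = character(), q_start = integer(), q_end = integer(),
             peptide = character(), n_exons = integer(), exons = character(),
             stringsAsFactors = FALSE)
}

scan_frame <- function(panel, pep, ctg, frame, contig_len, config) {
  pam <- get_pam250_full()
  queries <- Biostrings::AAStringSet(stats::setNames(panel$motif_seq, panel$id))
  # stage 1 -- locus discovery: every round aligns all queries against
  # the shared, progressively masked frame translation and masks the
  # union of the found regions, so multiple motif copies per frame are
  # discovered without per-query rescans
  masked <- pep
  loci <- matrix(0L, 0, 2)
  for (round in seq_len(config$max_candidates_per_contig)) {
    pa <- Biostrings::pairwiseAlignment(
      queries, Biostrings::AAString(masked), type = "local",
      substitutionMatrix = pam, gapOpening = config$gap_open,
      gapExtension = config$gap_extend)
    scores <- Biostrings::score(pa)
    found <- which(scores >= config$min_segment_score)
    if (!length(found)) break
    ts <- IRanges::start(Biostrings::subject(pa))
    te <- IRanges::end(Biostrings::subject(pa))
    loci <- rbind(loci, cbind(ts[found], te[found]))
    for (qi in found)
      substr(masked, ts[qi], te[qi]) <- strrep("X", te[qi] - ts[qi] + 1L)
  }
  if (nrow(loci) == 0) return(empty_hits())
  loci <- merge_intervals(loci, slop = 5L)
  # stage 2 -- per-locus refinement: realign every query against each
  # discovered locus (with small flanks) so each query gets its own
  # segment coordinates regardless of which query discovered the locus;
  # only the strongest queries per locus are recorded
  acc_q <- character(0)
  acc_ts <- acc_te <- acc_qs <- acc_qe <- integer(0)
  acc_sc <- numeric(0)
  acc_pep <- character(0)
  maxq <- max(nchar(panel$motif_seq))
  top_k <- 6L
  for (li in seq_len(nrow(loci))) {
    ls <- max(1L, loci[li, 1] - 10L)
    le <- min(nchar(pep), loci[li, 2] + 10L)
    if (le - ls + 1L > 3L * maxq) {  # runaway locus; keep it bounded
      le <- min(nchar(pep), ls + 3L * maxq)
    }
    sub <- substr(pep, ls, le)
    pa <- Biostrings::pairwiseAlignment(
      queries, Biostrings::AAString(sub), type = "local",
      substitutionMatrix = pam, gapOpening = config$gap_open,
      gapExtension = config$gap_extend)
    scores <- Biostrings::score(pa)
    sel <- which(scores >= config$min_segment_score)
    if (!length(sel)) next
    sel <- sel[order(-scores[sel])]
    sel <- sel[seq_len(min(top_k, length(sel)))]
    ts <- IRanges::start(Biostrings::subject(pa))[sel] + ls - 1L
    te <- IRanges::end(Biostrings::subject(pa))[sel] + ls - 1L
    acc_q <- c(acc_q, panel$id[sel])
    acc_sc <- c(acc_sc, scores[sel])
    acc_ts <- c(acc_ts, ts)
    acc_te <- c(acc_te, te)
    acc_qs <- c(acc_qs, IRanges::start(Biostrings::pattern(pa))[sel])
    acc_qe <- c(acc_qe, IRanges::end(Biostrings::pattern(pa))[sel])
    acc_pep <- c(acc_pep, substring(pep, ts, te))
  }
  if (!length(acc_q)) return(empty_hits())
  if (frame == 0L) {
    gs <- acc_ts; ge <- acc_te
  } else {
    off <- abs(frame) - 1L
    nt_s <- off + 3L * (acc_ts - 1L) + 1L
    nt_e <- off + 3L * acc_te
    if (frame > 0) { gs <- nt_s; ge <- nt_e }
    else { gs <- contig_len - nt_e + 1L; ge <- contig_len - nt_s + 1L }
  }
  data.frame(contig = ctg, frame = frame,
             strand = if (frame < 0) "-" else "+",
             start = gs, end = ge, score = acc_sc, query = acc_q,
             q_start = acc_qs, q_end = acc_qe, peptide = acc_pep,
             n_exons = 1L, exons = paste0(gs, "-", ge),
             stringsAsFactors = FALSE)
}

# Merge overlapping or near-adjacent intervals (two-column matrix).
merge_intervals <- function(iv, slop = 0L) {
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[i, 1] <= out[last, 2] + slop)
      out[last, 2] <- max(out[last, 2], iv[i, 2])
    else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

#' Chain exon segments of intron-split candidates
#'
#' Hits of the same query on the same contig and strand whose query
#' intervals are compatible (non-overlapping up to 2 residues, in
#' transcription order) and whose genomic gap is at most `max_chain_gap`
#' are merged into one multi-exon candidate: peptides are concatenated in
#' query order and the chain score is the sum of segment scores.
#'
#' @param hits Hit data frame from [scan_target()].
#' @param config A [search_config()].
#' @return Hit data frame with chained candidates replacing their
#'   segments.
#' @export
chain_hits <- function(hits, config = search_config()) {
  if (nrow(hits) == 0) return(hits)
  key <- paste(hits$contig, hits$strand, hits$query, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sub <- hits[key == k, , drop = FALSE]
    n <- nrow(sub)
    if (n == 1) { out[[length(out) + 1L]] <- sub; next }
    plus <- sub$strand[1] == "+"
    # transcription order
    sub <- sub[order(if (plus) sub$start else -sub$start), , drop = FALSE]
    v_start <- sub$start; v_end <- sub$end
    v_qs <- sub$q_start; v_qe <- sub$q_end; v_score <- sub$score
    # segment j may extend segment i when it continues both the query
    # and the genome within the allowed intron span; the returned gap is
    # -1 when the pair is not chainable
    follow_gap <- function(i, j) {
      gap <- if (plus) v_start[j] - v_end[i] - 1L
             else v_start[i] - v_end[j] - 1L
      if (gap >= 4 && gap <= config$max_chain_gap &&
          v_qs[j] >= v_qe[i] - 1L && v_qs[j] <= v_qe[i] + 15L) gap else -1L
    }
    used <- rep(FALSE, n)
    repeat {
      idx <- which(!used)
      if (!length(idx)) break
      # best chain among unused segments (weighted DAG path); long gaps
      # are penalized so that a segment joins its nearby true partner
      # rather than a distant paralog's segment
      best <- v_score[idx]
      parent <- rep(0L, length(idx))
      for (a in seq_along(idx)) {
        for (b in seq_len(a - 1L)) {
          gp <- follow_gap(idx[b], idx[a])
          if (gp >= 0) {
            cand_score <- best[b] + v_score[idx[a]] -
              config$chain_gap_penalty * gp
            if (cand_score > best[a]) {
              best[a] <- cand_score
              parent[a] <- b
            }
          }
        }
      }
      endpt <- which.max(best)
      path <- endpt
      while (parent[path[1]] > 0L) path <- c(parent[path[1]], path)
      members <- idx[path]
      used[members] <- TRUE
      seg <- sub[members, , drop = FALSE]
      merged <- seg[1, , drop = FALSE]
      merged$score <- sum(seg$score)
      merged$peptide <- paste(seg$peptide, collapse = "")
      merged$q_start <- seg$q_start[1]
      merged$q_end <- seg$q_end[nrow(seg)]
      merged$start <- min(seg$start)
      merged$end <- max(seg$end)
      merged$n_exons <- nrow(seg)
      merged$exons <- paste(seg$exons[order(seg$start)], collapse = ";")
      out[[length(out) + 1L]] <- merged
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Deduplicate overlapping hits
#'
#' Among hits sharing contig and frame whose coding intervals overlap by
#' at least `overlap_fraction` of the shorter interval, only the
#' highest-scoring hit survives; ties are broken by leftmost start, then
#' lexicographic query id. Idempotent.
#'
#' @param hits Hit data frame.
#' @param overlap_fraction Fraction in (0, 1].
#' @return Filtered hit data frame.
#' @export
dedupe_hits <- function(hits, overlap_fraction = 0.5) {
  stopifnot(overlap_fraction > 0, overlap_fraction <= 1)
  if (nrow(hits) <= 1) return(hits)
  # coding-region overlap compares exon intervals, so a multi-exon chain
  # does not swallow a distinct gene lying inside one of its introns
  exon_iv <- lapply(strsplit(hits$exons, ";"), function(x)
    do.call(rbind, lapply(strsplit(x, "-"), as.integer)))
  exon_len <- vapply(exon_iv, function(m) sum(m[, 2] - m[, 1] + 1L), 0L)
  groups <- split(seq_len(nrow(hits)), paste(hits$contig, hits$frame))
  keep_idx <- integer(0)
  for (g in groups) {
    ord <- order(-hits$score[g], hits$start[g], hits$query[g])
    g <- g[ord]
    kept <- integer(0)
    for (i in g) {
      dup <- FALSE
      for (j in kept) {
        ov <- overlap_len(exon_iv[[i]], exon_iv[[j]])
        if (ov / min(exon_len[i], exon_len[j]) >= overlap_fraction) {
          dup <- TRUE; break
        }
      }
      if (!dup) kept <- c(kept, i)
    }
    keep_idx <- c(keep_idx, kept)
  }
  out <- hits[sort(keep_idx), , drop = FALSE]
  out <- out[order(out$contig, out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse redundant candidates across frames at one locus
#'
#' An intron-split motif leaves partial single-frame hits alongside the
#' chained multi-exon candidate; this pass drops any hit whose span is
#' covered at least `fraction` by a higher-scoring hit on the same
#' contig and strand (any frame), mirroring the manual one-gene-per-locus
#' curation.
#'
#' @param hits Hit data frame.
#' @param fraction Coverage fraction of the lower-scoring hit (default
#'   0.7).
#' @return Filtered hit data frame.
#' @export
collapse_loci <- function(hits, fraction = 0.7) {
  if (nrow(hits) <= 1) return(hits)
  exon_iv <- lapply(strsplit(hits$exons, ";"), function(x) {
    m <- do.call(rbind, lapply(strsplit(x, "-"), as.integer))
    m
  })
  exon_len <- vapply(exon_iv, function(m) sum(m[, 2] - m[, 1] + 1L), 0L)
  keep <- logical(nrow(hits))
  for (g in split(seq_len(nrow(hits)), paste(hits$contig, hits$strand))) {
    # most complete candidate first: exonic coverage, then score
    ord <- g[order(-exon_len[g], -hits$score[g], hits$start[g], hits$query[g])]
    kept <- integer(0)
    for (i in ord) {
      dup <- FALSE
      for (j in kept) {
        if (hits$end[j] < hits$start[i] || hits$start[j] > hits$end[i]) next
        ov <- overlap_len(exon_iv[[i]], exon_iv[[j]])
        if (ov >= fraction * exon_len[i]) { dup <- TRUE; break }
      }
      if (!dup) kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$contig, out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count conserved-site matches of a candidate peptide
#'
#' The peptide is aligned to the majority consensus of the reference
#' alignment (ends-free alignment under PAM250); for each conserved site
#' the aligned residue is compared with the allowed residue set. A
#' candidate is kept when at least `min_conserved` (default 10) of the
#' sites match; a peptide covering less than half of the motif columns is
#' rejected as truncated.
#'
#' @param peptide Candidate amino-acid string.
#' @param ref_alignment Reference [motif_alignment()].
#' @param spec A `conserved_site_spec`.
#' @param config A [search_config()].
#' @param cons Optional precomputed [consensus_sequence()] of
#'   `ref_alignment` (avoids recomputing it per candidate).
#' @return List with `conserved_matches`, `keep`, `reason`.
#' @export
conserved_site_filter <- function(peptide, ref_alignment,
                                  spec = default_conserved_sites(),
                                  config = search_config(),
                                  cons = NULL) {
  if (is.null(cons)) cons <- consensus_sequence(ref_alignment)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(peptide)),
    Biostrings::AAString(cons$seq), type = "overlap",
    substitutionMatrix = get_pam250_full(),
    gapOpening = config$gap_open, gapExtension = config$gap_extend)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  # residue of the candidate opposite each consensus position; the
  # aligned strings exclude unaligned subject flanks, so start from the
  # subject offset
  cons_res <- rep(NA_character_, nchar(cons$seq))
  jpos <- IRanges::start(Biostrings::subject(pa)) - 1L
  for (i in seq_along(sub)) {
    if (sub[i] != "-") {
      jpos <- jpos + 1L
      if (pat[i] != "-") cons_res[jpos] <- pat[i]
    }
  }
  covered <- sum(!is.na(cons_res))
  if (covered < length(cons_res) / 2)
    return(list(conserved_matches = 0L, keep = FALSE, reason = "truncated"))
  site_pos <- match(spec$column, cons$columns)
  matches <- 0L
  for (s in seq_along(site_pos)) {
    p <- site_pos[s]
    if (is.na(p)) next
    r <- cons_res[p]
    if (!is.na(r) &&
        grepl(r, spec$residues[s], fixed = TRUE)) matches <- matches + 1L
  }
  list(conserved_matches = matches, keep = matches >= config$min_conserved,
       reason = if (matches >= config$min_conserved) ""
                else "below conserved-site threshold")
}
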