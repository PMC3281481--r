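# Mapping of introns inside the motif coding region to motif subregions
# and the intron summary statistics.

#' Map the introns of one motif coding region
#'
#' Given the ordered exon intervals covering a motif's coding sequence,
#' emits one record per inter-exon gap: its genomic length (donor GT
#' through acceptor AG inclusive), its phase (coding offset within the
#' interrupted codon) and the motif subregion of the interrupted codon
#' (for phase 0, the codon 5' of the junction -- the deterministic
#' boundary rule).
#'
#' @param exon_starts,exon_ends Integer vectors of forward-strand 1-based
#'   inclusive exon coordinates (ascending starts).
#' @param strand `"+"` or `"-"`; exons are walked in transcription order.
#' @param member_id Label attached to the records.
#' @param scheme A [subregion_scheme()]; its motif length must equal the
#'   total coding length / 3.
#' @return Data frame with columns `member_id`, `intron_index`,
#'   `genomic_length`, `donor_pos`, `phase`, `subregion`; zero rows for a
#'   single exon.
#' @export
map_introns <- function(exon_starts, exon_ends, strand = "+",
                        member_id = "member", scheme = subregion_scheme()) {
  stopifnot(length(exon_starts) == length(exon_ends),
            all(exon_ends >= exon_starts), strand %in% c("+", "-"))
  k <- length(exon_starts)
  ord <- order(exon_starts)
  if (any(ord != seq_len(k))) stop("exons out of order")
  if (k > 1 && any(exon_starts[-1] <= exon_ends[-k]))
    stop("exons out of order")
  if (k == 1) return(empty_introns())
  # transcription order
  idx <- if (strand == "+") seq_len(k) else rev(seq_len(k))
  s <- exon_starts[idx]; e <- exon_ends[idx]
  coding <- cumsum(e - s + 1L)
  out <- list()
  for (i in seq_len(k - 1)) {
    gap <- if (strand == "+") s[i + 1] - e[i] - 1L else s[i] - e[i + 1] - 1L
    if (gap < 4) stop("implausible intron of ", gap, " bp (< 4)")
    c_off <- coding[i]
    phase <- c_off %% 3L
    donor <- if (phase == 0L) c_off %/% 3L else c_off %/% 3L + 1L
    out[[i]] <- data.frame(member_id = member_id, intron_index = i,
                           genomic_length = gap, donor_pos = donor,
                           phase = phase,
                           subregion = subregion_of(scheme, donor),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

empty_introns <- function() {
  data.frame(member_id = character(), intron_index = integer(),
             genomic_length = integer(), donor_pos = integer(),
             phase = integer(), subregion = character(),
             stringsAsFactors = FALSE)
}

#' Summary statistics of motif introns
#'
#' @param records Intron data frame (rows from [map_introns()], possibly
#'   over many members).
#' @return List with `members_with_introns`, `total_introns`,
#'   `per_member_histogram` (introns-per-member -> member count),
#'   `per_subregion` (subregion -> intron count), `longest_bp` and
#'   `mean_bp` (arithmetic mean rounded to the nearest bp).
#' @export
summarize_introns <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    return(list(members_with_introns = 0L, total_introns = 0L,
                per_member_histogram = integer(0),
                per_subregion = integer(0),
                longest_bp = 0L, mean_bp = 0L))
  per_member <- table(records$member_id)
  hist <- table(as.integer(per_member))
  list(members_with_introns = length(per_member),
       total_introns = nrow(records),
       per_member_histogram = stats::setNames(as.integer(hist), names(hist)),
       per_subregion = stats::setNames(
         as.integer(table(records$subregion)),
         names(table(records$subregion))),
       longest_bp = max(records$genomic_length),
       mean_bp = as.integer(round(mean(records$genomic_length))))
}
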