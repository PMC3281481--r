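# Reference bHLH motif panels, the family -> higher-order-group map,
# conserved-site specifications, and motif subregion boundaries.

#' Load and validate a reference motif panel
#'
#' A panel is a FASTA of amino-acid motif sequences plus a tab-separated
#' metadata table with columns `id`, `species`, `family`, `group`. FASTA
#' ids must match metadata rows one-to-one; every family must map to
#' exactly one higher-order group (A-F); sequences may contain only the 20
#' standard residues.
#'
#' @param fasta_path Path to the motif FASTA.
#' @param metadata_path Path to the metadata TSV.
#' @return A data frame of class `reference_panel` with columns
#'   `id`, `species`, `family`, `group`, `motif_seq`.
#' @export
load_reference_panel <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) == 0) {
    warning("empty reference FASTA: ", fasta_path)
    return(empty_panel())
  }
  ids <- sub("\\s.*$", "", names(seqs))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  required <- c("id", "species", "family", "group")
  if (!all(required %in% names(meta)))
    stop("metadata must have columns: ", paste(required, collapse = ", "))
  missing_meta <- setdiff(ids, meta$id)
  if (length(missing_meta))
    stop("no metadata row for FASTA record(s): ",
         paste(missing_meta, collapse = ", "))
  meta <- meta[match(ids, meta$id), ]
  motif_seq <- toupper(as.character(seqs))
  bad <- grepl(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]"), motif_seq)
  if (any(bad))
    stop("non-standard amino-acid letters in record(s): ",
         paste(ids[bad], collapse = ", "))
  panel <- data.frame(id = ids, species = meta$species, family = meta$family,
                      group = meta$group, motif_seq = unname(motif_seq),
                      stringsAsFactors = FALSE)
  validate_panel(panel)
}

empty_panel <- function() {
  structure(data.frame(id = character(), species = character(),
                       family = character(), group = character(),
                       motif_seq = character(), stringsAsFactors = FALSE),
            class = c("reference_panel", "data.frame"))
}

validate_panel <- function(panel, group_map = NULL) {
  if (anyDuplicated(panel$id))
    stop("duplicated panel ids: ",
         paste(unique(panel$id[duplicated(panel$id)]), collapse = ", "))
  if (!all(panel$group %in% LETTERS[1:6]))
    stop("group must be one of A-F")
  fg <- unique(panel[, c("family", "group")])
  dup <- fg$family[duplicated(fg$family)]
  if (length(dup))
    stop("family mapped to more than one group: ", paste(dup, collapse = ", "))
  if (!is.null(group_map)) {
    unknown <- setdiff(panel$family, names(group_map))
    if (length(unknown))
      stop("unknown family: ", paste(unknown, collapse = ", "))
    mismatch <- panel$group != group_map[panel$family]
    if (any(mismatch))
      stop("family/group mismatch for: ",
           paste(panel$id[mismatch], collapse = ", "))
  }
  class(panel) <- c("reference_panel", "data.frame")
  panel
}

#' Write a reference panel to FASTA + metadata TSV
#' @param panel A `reference_panel`.
#' @param fasta_path,metadata_path Output paths.
#' @export
write_reference_panel <- function(panel, fasta_path, metadata_path) {
  seqs <- Biostrings::AAStringSet(stats::setNames(panel$motif_seq, panel$id))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 60)
  utils::write.table(panel[, c("id", "species", "family", "group")],
                     metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(panel)
}

#' Family to higher-order-group map
#'
#' The bundled map assigns each of the 45 animal bHLH families to its
#' higher-order group (A-F): 22 families in group A, 12 in B, 7 in C and
#' one each in D and F, with two (H/E(spl) and Hey) in group E.
#'
#' @param path Optional TSV with columns `family`, `group`; defaults to
#'   the bundled map.
#' @return Named character vector, family -> group letter.
#' @export
family_group_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "family_groups.tsv", package = "bhlhscan",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("family", "group") %in% names(tab)))
  if (anyDuplicated(tab$family)) stop("duplicate family in group map")
  stats::setNames(tab$group, tab$family)
}

#' Bundled synthetic reference panel
#'
#' A synthetic stand-in for the 59-motif *Drosophila melanogaster*
#' reference panel: 59 simulated bHLH motifs covering the 45 animal
#' families and all six higher-order groups, with 19 invariant
#' (conserved) columns including motif columns 24 and 51. Real panels can
#' be supplied by the user in the same FASTA + TSV format.
#'
#' @return A `reference_panel` data frame.
#' @export
default_reference_panel <- function() {
  load_reference_panel(
    system.file("extdata", "synthetic_panel.fasta", package = "bhlhscan",
                mustWork = TRUE),
    system.file("extdata", "synthetic_panel_meta.tsv", package = "bhlhscan",
                mustWork = TRUE))
}

#' Alignment of a reference panel
#'
#' Panels of equal-length motifs (the bundled panel) align trivially;
#' otherwise the progressive aligner is used.
#'
#' @param panel A `reference_panel`.
#' @return A [motif_alignment()].
#' @export
panel_alignment <- function(panel) {
  seqs <- stats::setNames(panel$motif_seq, panel$id)
  if (length(unique(nchar(seqs))) == 1) motif_alignment(seqs)
  else progressive_align(seqs)
}

#' Derive a conserved-site specification from an aligned panel
#'
#' A column is a conserved site when its modal residue frequency (among
#' non-gap characters) is at least `min_frequency`; the allowed residue
#' set of a site contains every residue whose frequency reaches
#' `secondary_floor`. Deterministic for fixed input.
#'
#' @param aln A [motif_alignment()] with >= 2 rows.
#' @param min_frequency Modal-frequency threshold, in (0.5, 1].
#' @param secondary_floor Frequency floor for membership in the allowed
#'   residue set (default 0.10).
#' @return A data frame of class `conserved_site_spec` with columns
#'   `column` (1-based alignment column) and `residues` (string of allowed
#'   residues).
#' @export
derive_conserved_sites <- function(aln, min_frequency,
                                   secondary_floor = 0.10) {
  if (length(aln$ids) < 2) stop("alignment must have >= 2 rows")
  if (!(min_frequency > 0.5 && min_frequency <= 1))
    stop("min_frequency must be in (0.5, 1]")
  f <- column_frequencies(aln)
  modal <- apply(f, 2, max)
  cols <- which(modal >= min_frequency - 1e-12)
  residues <- vapply(cols, function(j)
    paste(rownames(f)[f[, j] >= secondary_floor - 1e-12], collapse = ""), "")
  conserved_site_spec(cols, residues)
}

#' Construct a conserved-site specification
#' @param columns Strictly increasing 1-based alignment columns.
#' @param residues Character vector of allowed-residue strings.
#' @export
conserved_site_spec <- function(columns, residues) {
  stopifnot(length(columns) == length(residues),
            !is.unsorted(columns, strictly = TRUE),
            all(nchar(residues) > 0))
  structure(data.frame(column = as.integer(columns), residues = residues,
                       stringsAsFactors = FALSE),
            class = c("conserved_site_spec", "data.frame"))
}

#' Calibrate the conserved-site specification to a fixed site count
#'
#' Chooses the modal-frequency threshold at which exactly `n_sites`
#' columns qualify (the classical 19 diagnostic bHLH sites by default) and
#' checks that the required anchor columns are among them.
#'
#' @param aln A [motif_alignment()].
#' @param n_sites Number of sites to select (default 19).
#' @param required Columns that must be present (default 24 and 51, the
#'   two most conserved motif sites).
#' @param secondary_floor Passed to [derive_conserved_sites()].
#' @return A `conserved_site_spec` with attribute `"min_frequency"`.
#' @export
calibrate_conserved_sites <- function(aln, n_sites = 19,
                                      required = c(24L, 51L),
                                      secondary_floor = 0.10) {
  f <- column_frequencies(aln)
  modal <- apply(f, 2, max)
  ord <- order(modal, seq_along(modal), decreasing = c(TRUE, FALSE),
               method = "radix")
  if (length(modal) < n_sites) stop("alignment has fewer columns than n_sites")
  thr <- modal[ord[n_sites]]
  if (sum(modal >= thr) != n_sites)
    stop("cannot select exactly ", n_sites,
         " sites: ties at the threshold frequency")
  if (thr <= 0.5) stop("calibrated threshold not above 0.5; panel too diverse")
  spec <- derive_conserved_sites(aln, thr, secondary_floor)
  miss <- setdiff(required, spec$column)
  if (length(miss))
    stop("required conserved columns absent: ", paste(miss, collapse = ", "))
  attr(spec, "min_frequency") <- thr
  spec
}

#' Default conserved-site specification
#'
#' Derived from the bundled synthetic panel so that exactly 19 sites
#' result, anchored at motif columns 24 and 51; cached after first use.
#' A user-supplied TSV (columns `column`, `residues`) overrides it.
#'
#' @param path Optional TSV path overriding the derived default.
#' @return A `conserved_site_spec`.
#' @export
default_conserved_sites <- function(path = NULL) {
  if (!is.null(path)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    return(conserved_site_spec(tab$column, tab$residues))
  }
  if (is.null(.bhlh_cache$conserved_default)) {
    aln <- panel_alignment(default_reference_panel())
    .bhlh_cache$conserved_default <- calibrate_conserved_sites(aln)
  }
  .bhlh_cache$conserved_default
}

#' Motif subregion scheme
#'
#' Partition of the motif columns into the basic region, helix 1, loop and
#' helix 2. The default boundaries (1-based, half-open) are
#' basic = \[1,16), helix 1 = \[16,31), loop = \[31,46),
#' helix 2 = \[46, length\]; they are contiguous and cover the whole
#' motif.
#'
#' @param starts Named integer vector with the start column of each
#'   subregion, in order basic, helix1, loop, helix2.
#' @param motif_length Total number of motif columns.
#' @return List of class `subregion_scheme`.
#' @export
subregion_scheme <- function(starts = c(basic = 1L, helix1 = 16L,
                                        loop = 31L, helix2 = 46L),
                             motif_length = 60L) {
  nm <- c("basic", "helix1", "loop", "helix2")
  stopifnot(identical(names(starts), nm), starts[1] == 1L,
            !is.unsorted(starts, strictly = TRUE),
            starts[4] <= motif_length)
  ends <- c(starts[-1] - 1L, motif_length)
  structure(list(starts = as.integer(starts), ends = as.integer(ends),
                 names = nm, motif_length = as.integer(motif_length)),
            class = "subregion_scheme")
}

#' Subregion of a motif column
#' @param scheme A [subregion_scheme()].
#' @param column Motif column (1-based); values beyond the motif length
#'   are clamped into the last subregion.
#' @return Character vector of subregion names.
#' @export
subregion_of <- function(scheme, column) {
  column <- pmin(pmax(as.integer(column), 1L), scheme$motif_length)
  idx <- findInterval(column, scheme$starts)
  scheme$names[idx]
}
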