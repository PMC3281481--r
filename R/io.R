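# Readers and writers for the external formats the pipeline touches:
# FASTA (Biostrings), GFF3 (rtracklayer for parsing), newick (ape), TSV
# and JSON manifests.

#' Read a nucleotide FASTA into a named character vector
#' @param path FASTA path.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a peptide FASTA into a named character vector
#' @param path FASTA path.
#' @export
read_peptide_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA (wrapped at 60 columns)
#' @param seqs Named character vector.
#' @param path Output path.
#' @param type `"DNA"` or `"AA"`.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read an alignment from aligned FASTA
#' @param path Aligned FASTA path.
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  motif_alignment(stats::setNames(as.character(x), sub("\\s.*$", "", names(x))))
}

#' Write an alignment to aligned FASTA
#' @param aln A [motif_alignment()].
#' @param path Output path.
#' @export
write_alignment_fasta <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(alignment_strings(aln)),
                              path, width = 60)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' @param gff Data frame with the nine GFF3 columns (`seqid`, `source`,
#'   `type`, `start`, `end`, `score`, `strand`, `phase`, `attributes`),
#'   1-based inclusive coordinates.
#' @param path Output path.
#' @export
write_gff3 <- function(gff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses with rtracklayer and returns one row per mRNA with its ordered
#' CDS intervals.
#'
#' @param path GFF3 path.
#' @return Data frame with `model_id`, `contig`, `strand`,
#'   `exon_starts`, `exon_ends` (ascending, `;`-joined), `span_start`,
#'   `span_end`.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  cds <- g[g$type == "CDS"]
  if (length(cds) == 0)
    return(data.frame(model_id = character(), contig = character(),
                      strand = character(), exon_starts = character(),
                      exon_ends = character(), span_start = integer(),
                      span_end = integer(), stringsAsFactors = FALSE))
  parents <- vapply(as.list(S4Vectors::mcols(cds)$Parent),
                    function(p) if (length(p)) p[[1]] else NA_character_, "")
  rows <- lapply(split(seq_along(cds), parents), function(ii) {
    sub <- cds[ii]
    o <- order(GenomicRanges::start(sub))
    data.frame(
      model_id = parents[ii[1]],
      contig = as.character(GenomicRanges::seqnames(sub))[1],
      strand = as.character(GenomicRanges::strand(sub))[1],
      exon_starts = paste(GenomicRanges::start(sub)[o], collapse = ";"),
      exon_ends = paste(GenomicRanges::end(sub)[o], collapse = ";"),
      span_start = min(GenomicRanges::start(sub)),
      span_end = max(GenomicRanges::end(sub)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a tree (with support labels) to newick
#' @param tree A `phylo`.
#' @param path Output path.
#' @export
write_tree_file <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree (support values become node labels)
#' @param path Newick path.
#' @export
read_tree_file <- function(path) ape::read.tree(path)

#' Write a TSV with documented headers
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a run manifest (effective parameters and seeds) as JSON
#' @param manifest Named list.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
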