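# End-to-end pipeline: scan -> chain -> dedupe -> conserved-site filter
# -> in-group classification (-> cross-species fallback) -> intron
# annotation -> report.

#' Run the whole identification and classification pipeline
#'
#' @param genome Named character vector of contigs (or a FASTA path).
#' @param panel A `reference_panel` (or NULL for the bundled panel).
#' @param gene_models Optional gene-model data frame
#'   ([read_gene_models()]) or GFF3 path; enables intron annotation.
#' @param fallback_panels List of `reference_panel`s for the
#'   cross-species fallback.
#' @param search_cfg,phylo_cfg,cls_cfg Configurations.
#' @param conserved_spec Optional `conserved_site_spec`; by default
#'   calibrated from the panel alignment (19 sites).
#' @param species_prefix Prefix of assigned gene names.
#' @param outdir Optional output directory for TSV/FASTA/newick/manifest
#'   artifacts.
#' @param seed Integer seed for all stochastic steps.
#' @return List with `hits` (retained candidates), `calls` (data frame),
#'   `call_objects`, `introns`, `summary`, `manifest`.
#' @export
run_pipeline <- function(genome, panel = NULL, gene_models = NULL,
                         fallback_panels = list(),
                         search_cfg = search_config(),
                         phylo_cfg = phylo_config(),
                         cls_cfg = classify_config(),
                         conserved_spec = NULL,
                         species_prefix = "Sp", outdir = NULL, seed = 1) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_genome_fasta(genome)
  if (is.null(panel)) panel <- default_reference_panel()
  if (is.character(gene_models)) gene_models <- read_gene_models(gene_models)
  phylo_cfg$seed <- seed
  ref_aln <- panel_alignment(panel)
  if (is.null(conserved_spec))
    conserved_spec <- tryCatch(calibrate_conserved_sites(ref_aln),
                               error = function(e) default_conserved_sites())

  raw <- scan_target(panel, genome, search_cfg, mode = "genome")
  chained <- chain_hits(raw, search_cfg)
  chained <- chained[chained$score >= search_cfg$min_score, , drop = FALSE]
  hits <- collapse_loci(dedupe_hits(chained, search_cfg$overlap_fraction))

  if (nrow(hits)) {
    cons <- consensus_sequence(ref_aln)
    fres <- lapply(hits$peptide, conserved_site_filter,
                   ref_alignment = ref_aln, spec = conserved_spec,
                   config = search_cfg, cons = cons)
    hits$conserved_matches <- vapply(fres, `[[`, 0L, "conserved_matches")
    hits$keep <- vapply(fres, `[[`, logical(1), "keep")
    hits <- hits[hits$keep, , drop = FALSE]
    hits$keep <- NULL
  }
  if (nrow(hits))
    hits$candidate_id <- sprintf("cand%03d", seq_len(nrow(hits)))

  cl_res <- classify_hits(hits, panel, fallback_panels, phylo_cfg, cls_cfg,
                          species_prefix, seed)
  calls <- cl_res$call_objects
  calls_df <- cl_res$calls

  introns <- annotate_introns(calls_df, gene_models)

  summary <- list(groups = summarize_groups(calls_df),
                  introns = summarize_introns(introns))
  manifest <- list(tool = "bhlhscan", step = "pipeline", seed = seed,
                   n_contigs = length(genome),
                   search = unclass(search_cfg), phylo = unclass(phylo_cfg),
                   classify = unclass(cls_cfg),
                   species_prefix = species_prefix)
  out <- list(hits = hits, calls = calls_df, call_objects = calls,
              introns = introns, summary = summary, manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

#' Classify every retained hit by in-group phylogenetic analysis
#'
#' @param hits Filtered hit data frame with `candidate_id` and `peptide`.
#' @param panel Primary `reference_panel`.
#' @param fallback_panels List of fallback panels.
#' @param phylo_cfg,cls_cfg Configurations.
#' @param species_prefix Name prefix.
#' @param seed Integer seed; each candidate derives its own child seed.
#' @return List with `call_objects` and `calls` (data frame).
#' @export
classify_hits <- function(hits, panel, fallback_panels = list(),
                          phylo_cfg = phylo_config(),
                          cls_cfg = classify_config(),
                          species_prefix = "Sp", seed = 1) {
  calls <- list()
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      pc <- phylo_cfg
      pc$seed <- seed + 13L * i
      cl <- tryCatch({
        sel <- choose_ingroup(hits$peptide[i], panel, cls_cfg)
        ingroup_classify(hits$peptide[i], hits$candidate_id[i],
                         sel$ingroup, sel$outgroup, pc, cls_cfg)
      }, error = function(e)
        structure(list(candidate_id = hits$candidate_id[i],
                       family = NA_character_, group = NA_character_,
                       ortholog_ref = NA_character_, per_method = NULL,
                       tier = "unassigned", reason = conditionMessage(e),
                       trees = NULL), class = "orthology_call"))
      if (cl$tier == "unassigned")
        cl <- cross_species_fallback(hits$peptide[i], hits$candidate_id[i],
                                     fallback_panels, vote_panel = panel,
                                     phylo_cfg = pc, cls_cfg = cls_cfg,
                                     prior_call = cl)
      calls[[i]] <- cl
    }
    calls <- assign_names(calls, species_prefix)
  }
  list(call_objects = calls, calls = calls_to_df(calls, hits))
}

#' Map introns of classified candidates from gene models
#'
#' @param calls_df Calls data frame ([classify_hits()]).
#' @param gene_models Gene-model data frame ([read_gene_models()]) or
#'   NULL.
#' @return Intron record data frame.
#' @export
annotate_introns <- function(calls_df, gene_models) {
  introns <- empty_introns()
  if (is.null(gene_models) || !nrow(calls_df)) return(introns)
  for (i in seq_len(nrow(calls_df))) {
    gm <- match_gene_model(calls_df[i, ], gene_models)
    if (is.null(gm)) next
    s <- as.integer(strsplit(gm$exon_starts, ";")[[1]])
    e <- as.integer(strsplit(gm$exon_ends, ";")[[1]])
    mlen <- sum(e - s + 1L) %/% 3L
    rec <- map_introns(s, e, gm$strand, calls_df$candidate_id[i],
                       subregion_scheme(motif_length = mlen))
    introns <- rbind(introns, rec)
  }
  introns
}

calls_to_df <- function(calls, hits) {
  if (!length(calls))
    return(data.frame(candidate_id = character(), name = character(),
                      family = character(), group = character(),
                      ortholog = character(), tier = character(),
                      nj_support = numeric(), mp_support = numeric(),
                      ml_support = numeric(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), exon_starts = character(),
                      exon_ends = character(), score = numeric(),
                      conserved_matches = integer(), peptide = character(),
                      stringsAsFactors = FALSE))
  sup <- function(cl, m) {
    if (is.null(cl$per_method)) return(NA_real_)
    v <- cl$per_method$support[cl$per_method$method == m]
    if (length(v)) v else NA_real_
  }
  df <- data.frame(
    candidate_id = vapply(calls, `[[`, "", "candidate_id"),
    name = vapply(calls, function(x)
      if (is.null(x$assigned_name)) NA_character_ else x$assigned_name, ""),
    family = vapply(calls, function(x) as.character(x$family)[1], ""),
    group = vapply(calls, function(x) as.character(x$group)[1], ""),
    ortholog = vapply(calls, function(x) as.character(x$ortholog_ref)[1], ""),
    tier = vapply(calls, `[[`, "", "tier"),
    nj_support = vapply(calls, sup, 0, "NJ"),
    mp_support = vapply(calls, sup, 0, "MP"),
    ml_support = vapply(calls, sup, 0, "ML"),
    stringsAsFactors = FALSE)
  hit_cols <- hits[match(df$candidate_id, hits$candidate_id),
                   c("contig", "strand", "start", "end", "exons",
                     "score", "conserved_matches", "peptide")]
  df$exon_starts <- vapply(strsplit(hit_cols$exons, ";"), function(x)
    paste(vapply(strsplit(x, "-"), `[`, "", 1), collapse = ";"), "")
  df$exon_ends <- vapply(strsplit(hit_cols$exons, ";"), function(x)
    paste(vapply(strsplit(x, "-"), `[`, "", 2), collapse = ";"), "")
  cbind(df, hit_cols[, c("contig", "strand", "start", "end", "score",
                         "conserved_matches", "peptide")])
}

match_gene_model <- function(call_row, models) {
  cand <- models[models$contig == call_row$contig &
                   models$strand == call_row$strand, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  ov <- pmin(cand$span_end, call_row$end) -
    pmax(cand$span_start, call_row$start) + 1
  frac <- ov / (cand$span_end - cand$span_start + 1)
  best <- which.max(frac)
  if (frac[best] <= 0) return(NULL)
  cand[best, ]
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(out$hits, file.path(outdir, "hits.tsv"))
  write_tsv(out$calls, file.path(outdir, "calls.tsv"))
  write_tsv(out$introns, file.path(outdir, "introns.tsv"))
  if (nrow(out$calls))
    write_fasta(stats::setNames(out$calls$peptide, out$calls$name),
                file.path(outdir, "candidates.fasta"), type = "AA")
  treedir <- file.path(outdir, "trees")
  dir.create(treedir, showWarnings = FALSE)
  for (cl in out$call_objects) {
    if (is.null(cl$trees)) next
    for (m in names(cl$trees))
      write_tree_file(cl$trees[[m]],
                      file.path(treedir, sprintf("%s_%s.nwk",
                                                 cl$candidate_id, m)))
  }
  jsonlite::write_json(
    list(groups = out$summary$groups, introns = out$summary$introns),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  write_manifest(out$manifest, file.path(outdir, "manifest.json"))
  invisible(outdir)
}
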