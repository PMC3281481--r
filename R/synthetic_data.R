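# Synthetic study-condition generator: reference panels with designated
# conserved columns, target genomes with implanted (possibly
# intron-split) bHLH motifs plus shuffled decoys, and scoring of
# pipeline output against the recorded truth.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a genome-wide bHLH survey:
#' 10 families of 60-residue motifs, two reference members per family
#' (mirroring the sparse per-family representation of real panels),
#' within-family divergence of 0.10 substitutions per site with the 19
#' conserved columns protected, 50 implants and 100 composition-matched
#' decoys on 10 contigs, and intron presence in about half of the
#' implants (a second intron in ~30% of introned implants) with log-normal
#' lengths whose median is ~1 kb with a heavy right tail.
#'
#' @param n_families Number of motif families (>= 2).
#' @param members_per_family Reference members generated per family.
#' @param motif_length Motif length in residues (default 60).
#' @param within_family_divergence Per-site substitution probability
#'   between a family ancestor and its members (and implants).
#' @param between_family_divergence Per-site substitution probability
#'   between the shared domain ancestor and each family ancestor
#'   (default 0.35, giving ~45% inter-family identity, the relatedness
#'   regime of real bHLH motif panels; all motifs remain recognizably
#'   homologous).
#' @param conserved_site_protection Keep the 19 designated conserved
#'   columns invariant (default `TRUE`).
#' @param n_contigs,contig_length Genome dimensions.
#' @param n_implants Number of true motif implants.
#' @param decoy_count Number of shuffled decoy implants.
#' @param intron_probability Probability that an implant is split by at
#'   least one GT..AG intron.
#' @param second_intron_probability Probability of a second intron given
#'   the first.
#' @param intron_meanlog,intron_sdlog Log-normal intron length
#'   parameters (bp).
#' @param seed Integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_families = 10, members_per_family = 2,
                              motif_length = 60,
                              within_family_divergence = 0.10,
                              between_family_divergence = 0.35,
                              conserved_site_protection = TRUE,
                              n_contigs = 10, contig_length = 30000,
                              n_implants = 50, decoy_count = 100,
                              intron_probability = 0.5,
                              second_intron_probability = 0.3,
                              intron_meanlog = log(1000),
                              intron_sdlog = 1.0, seed = 1) {
  stopifnot(n_families >= 2, members_per_family >= 1, motif_length >= 55,
            within_family_divergence >= 0, within_family_divergence <= 1,
            intron_probability >= 0, intron_probability <= 1,
            n_contigs >= 1, contig_length > 3 * motif_length)
  structure(as.list(environment()), class = "simulation_config")
}

#' The 19 designated conserved motif columns of the simulator
#'
#' Spread over the whole motif and anchored at columns 24 and 51, the two
#' most conserved sites of the real domain.
#'
#' @return Integer vector of length 19.
#' @export
default_conserved_columns <- function() {
  c(2L, 5L, 9L, 13L, 16L, 20L, 23L, 24L, 28L, 32L, 35L, 39L, 42L, 45L,
    49L, 51L, 54L, 57L, 60L)
}

sample_residues <- function(n) {
  sample(AA_ALPHABET20, n, replace = TRUE, prob = .JTT_FREQ)
}

mutate_peptide <- function(res, p, protect = integer(0)) {
  hit <- which(stats::runif(length(res)) < p)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    repeat {
      r <- sample_residues(1)
      if (r != res[i]) break
    }
    res[i] <- r
  }
  res
}

#' Generate a synthetic reference panel
#'
#' A single domain ancestor is drawn (residues sampled from the JTT
#' stationary frequencies); each family's ancestor diverges from it at
#' `between_family_divergence` per site, and members diverge from their
#' family ancestor at `within_family_divergence`, so all motifs are
#' recognizably homologous as in real panels. When conserved-site
#' protection is on, the 19 designated columns carry the same residues
#' in every family and are never mutated. Families are assigned to
#' groups A-F round-robin unless a family -> group map is supplied.
#'
#' @param config A [simulation_config()].
#' @param family_names Optional family names (default `Fam01`...).
#' @param group_map Optional named vector family -> group letter.
#' @return List with `panel` (a `reference_panel`), `alignment`
#'   (the ungapped panel alignment), `conserved_columns` and
#'   `conserved_residues`.
#' @export
generate_panel <- function(config = simulation_config(),
                           family_names = NULL, group_map = NULL) {
  set.seed(config$seed)
  L <- config$motif_length
  nf <- config$n_families
  if (is.null(family_names))
    family_names <- sprintf("Fam%02d", seq_len(nf))
  stopifnot(length(family_names) == nf)
  if (is.null(group_map))
    group_map <- stats::setNames(rep(LETTERS[1:6], length.out = nf),
                                 family_names)
  cc <- default_conserved_columns()
  cc <- cc[cc <= L]
  cres <- sample_residues(length(cc))
  # one shared domain ancestor: all families are homologous copies of it
  domain_anc <- sample_residues(L)
  if (config$conserved_site_protection) domain_anc[cc] <- cres
  rows <- list()
  for (f in seq_len(nf)) {
    protect_anc <- if (config$conserved_site_protection) cc else integer(0)
    anc <- mutate_peptide(domain_anc, config$between_family_divergence,
                          protect_anc)
    if (config$conserved_site_protection) anc[cc] <- cres
    for (m in seq_len(config$members_per_family)) {
      protect <- if (config$conserved_site_protection) cc else integer(0)
      res <- mutate_peptide(anc, config$within_family_divergence, protect)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s-%d", family_names[f], m), species = "synthetic",
        family = family_names[f], group = unname(group_map[family_names[f]]),
        motif_seq = paste(res, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  panel <- validate_panel(do.call(rbind, rows))
  list(panel = panel,
       alignment = motif_alignment(stats::setNames(panel$motif_seq, panel$id)),
       conserved_columns = cc, conserved_residues = cres)
}

# Uniform synonymous back-translation of a peptide.
back_translate <- function(peptide) {
  code <- Biostrings::GENETIC_CODE
  res <- strsplit(peptide, "")[[1]]
  vapply(res, function(a) {
    cands <- names(code)[code == a]
    cands[sample.int(length(cands), 1)]
  }, "", USE.NAMES = FALSE) |> paste(collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Implant motifs and decoys into a random genome
#'
#' Background contigs are uniform random nucleotides. Each implant takes
#' a random panel member, mutates it at `within_family_divergence`
#' (conserved columns protected when protection is on), back-translates
#' it with uniform synonymous codons and places it on a random contig and
#' strand without overlapping prior implants. With probability
#' `intron_probability` the coding region is split by one (or, with
#' probability `second_intron_probability`, two) GT..AG introns with
#' log-normal lengths. Decoys are composition-preserving shuffles of
#' panel motifs, implanted without introns; they are expected to fail the
#' conserved-site filter. All coordinates are recorded as truth.
#'
#' @param panel_obj Result of [generate_panel()].
#' @param config The same [simulation_config()].
#' @return List with `genome` (named character vector), `truth`
#'   (data frame, one row per implant/decoy), `gff` (GFF3-style gene
#'   model data frame for the true implants) and `manifest`.
#' @export
implant_genome <- function(panel_obj, config = simulation_config()) {
  set.seed(config$seed + 1000L)
  panel <- panel_obj$panel
  L <- config$motif_length
  contigs <- stats::setNames(
    vapply(seq_len(config$n_contigs), function(i) random_dna(config$contig_length), ""),
    sprintf("contig%02d", seq_len(config$n_contigs)))
  occupied <- lapply(contigs, function(x) matrix(0L, 0, 2))
  truth <- list()
  place <- function(total_len) {
    for (try in seq_len(200)) {
      ci <- sample.int(length(contigs), 1)
      maxs <- nchar(contigs[[ci]]) - total_len - 1L
      if (maxs < 2) next
      s <- sample.int(maxs, 1) + 1L
      e <- s + total_len - 1L
      occ <- occupied[[ci]]
      if (nrow(occ) == 0 ||
          all(e + 10L < occ[, 1] | s - 10L > occ[, 2])) {
        occupied[[ci]] <<- rbind(occ, c(s, e))
        return(list(contig = ci, start = s, end = e))
      }
    }
    stop("could not place implant without overlap; use larger contigs")
  }
  make_implant <- function(idx, decoy = FALSE) {
    src <- sample.int(nrow(panel), 1)
    res <- strsplit(panel$motif_seq[src], "")[[1]]
    if (decoy) {
      res <- sample(res)  # composition-preserving shuffle
    } else {
      protect <- if (config$conserved_site_protection)
        panel_obj$conserved_columns else integer(0)
      res <- mutate_peptide(res, config$within_family_divergence, protect)
    }
    pep <- paste(res, collapse = "")
    cds <- back_translate(pep)
    n_introns <- 0L
    if (!decoy && stats::runif(1) < config$intron_probability) {
      n_introns <- 1L +
        (stats::runif(1) < config$second_intron_probability)
    }
    # intron insertion points as coding offsets (nt completed before the
    # intron), kept >= 3 codons from either motif end
    offs <- sort(sample(9:(3L * L - 9L), n_introns))
    if (n_introns == 2L && diff(offs) < 9L) offs[2] <- offs[1] + 9L
    ilens <- integer(0)
    gene <- ""
    prev <- 0L
    exon_coding <- integer(0)
    for (k in seq_len(n_introns)) {
      ilen <- max(50L, round(stats::rlnorm(1, config$intron_meanlog,
                                           config$intron_sdlog)))
      # keep the whole gene placeable on one contig
      ilen <- min(ilen, 20000L,
                  (config$contig_length - 3L * L - 200L) %/% 2L)
      ilens <- c(ilens, ilen)
      gene <- paste0(gene, substr(cds, prev + 1L, offs[k]),
                     paste0("GT", random_dna(ilen - 4L), "AG"))
      exon_coding <- c(exon_coding, offs[k] - prev)
      prev <- offs[k]
    }
    gene <- paste0(gene, substr(cds, prev + 1L, nchar(cds)))
    exon_coding <- c(exon_coding, nchar(cds) - prev)
    strand <- sample(c("+", "-"), 1)
    oriented <- if (strand == "+") gene
                else as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(gene)))
    loc <- place(nchar(gene))
    ci <- loc$contig
    substr(contigs[[ci]], loc$start, loc$end) <<- oriented
    # exon intervals in gene-local coordinates, transcription order
    starts <- integer(0); ends <- integer(0); pos <- 0L
    for (k in seq_along(exon_coding)) {
      starts <- c(starts, pos + 1L)
      ends <- c(ends, pos + exon_coding[k])
      pos <- pos + exon_coding[k] + if (k <= length(ilens)) ilens[k] else 0L
    }
    glen <- nchar(gene)
    if (strand == "+") {
      ex_s <- loc$start + starts - 1L
      ex_e <- loc$start + ends - 1L
    } else {
      ex_s <- loc$end - ends + 1L
      ex_e <- loc$end - starts + 1L
    }
    phases <- offs %% 3L
    donor_cols <- ifelse(phases == 0L, offs %/% 3L, offs %/% 3L + 1L)
    scheme <- subregion_scheme(motif_length = L)
    data.frame(
      implant_id = sprintf("%s%03d", if (decoy) "decoy" else "implant", idx),
      type = if (decoy) "decoy" else "implant",
      contig = names(contigs)[ci], strand = strand,
      start = loc$start, end = loc$end,
      family = if (decoy) NA_character_ else panel$family[src],
      source_reference_id = panel$id[src],
      peptide = pep,
      exon_starts = paste(ex_s, collapse = ";"),
      exon_ends = paste(ex_e, collapse = ";"),
      n_introns = n_introns,
      intron_lengths = paste(ilens, collapse = ";"),
      intron_subregions = paste(subregion_of(scheme, donor_cols),
                                collapse = ";"),
      intron_donor_columns = paste(donor_cols, collapse = ";"),
      intron_phases = paste(phases, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(config$n_implants))
    truth[[length(truth) + 1L]] <- make_implant(i, decoy = FALSE)
  for (i in seq_len(config$decoy_count))
    truth[[length(truth) + 1L]] <- make_implant(i, decoy = TRUE)
  truth <- do.call(rbind, truth)
  gff <- truth_to_gff(truth[truth$type == "implant", , drop = FALSE])
  manifest <- list(tool = "bhlhscan", step = "simulate",
                   config = unclass(config), n_truth = nrow(truth))
  list(genome = contigs, truth = truth, gff = gff, manifest = manifest)
}

# gene/mRNA/CDS rows (1-based inclusive) for the true implants.
truth_to_gff <- function(truth) {
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    gid <- tr$implant_id
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = tr$contig, source = "bhlhscan_sim",
      type = c("gene", "mRNA"), start = tr$start, end = tr$end,
      score = ".", strand = tr$strand, phase = ".",
      attributes = c(sprintf("ID=%s", gid),
                     sprintf("ID=%s.t1;Parent=%s", gid, gid)),
      stringsAsFactors = FALSE)
    s <- as.integer(strsplit(tr$exon_starts, ";")[[1]])
    e <- as.integer(strsplit(tr$exon_ends, ";")[[1]])
    ord <- order(s)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = tr$contig, source = "bhlhscan_sim", type = "CDS",
      start = s[ord], end = e[ord], score = ".", strand = tr$strand,
      phase = ".", attributes = sprintf("ID=%s.cds;Parent=%s.t1", gid, gid),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

interval_list <- function(starts, ends) {
  cbind(as.integer(strsplit(starts, ";")[[1]]),
        as.integer(strsplit(ends, ";")[[1]]))
}

overlap_len <- function(a, b) {
  # total overlap of two interval sets (matrices with cols start, end)
  tot <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    tot <- tot + max(0L, min(a[i, 2], b[j, 2]) - max(a[i, 1], b[j, 1]) + 1L)
  tot
}

#' Score pipeline output against the simulation truth
#'
#' A hit matches a truth record when their coding intervals overlap
#' reciprocally by at least 50% on the same contig and strand. Recall and
#' precision are computed over the true (non-decoy) implants;
#' `family_accuracy` is the fraction of matched classification calls with
#' the correct family; `decoy_rejection` is the fraction of decoys absent
#' from the final calls; `intron_recovery` is the fraction of implanted
#' introns reported with the correct subregion and exact length.
#'
#' @param calls Classification data frame with columns `contig`,
#'   `strand`, `exon_starts`, `exon_ends`, `family` (one row per final
#'   candidate).
#' @param truth Truth data frame from [implant_genome()].
#' @param introns Optional intron data frame (columns `member_id`,
#'   `genomic_length`, `subregion`) keyed by the call's candidate id
#'   column `candidate_id`.
#' @return List with `precision`, `recall`, `family_accuracy`,
#'   `decoy_rejection`, `intron_recovery` and the per-call matching.
#' @export
score_against_truth <- function(calls, truth, introns = NULL) {
  stopifnot(nrow(truth) > 0)
  true_truth <- truth[truth$type == "implant", , drop = FALSE]
  decoys <- truth[truth$type == "decoy", , drop = FALSE]
  n_calls <- nrow(calls)
  match_of <- rep(NA_character_, n_calls)
  matched_family_ok <- logical(0)
  decoy_hit <- rep(FALSE, nrow(decoys))
  if (n_calls > 0) {
    call_iv <- lapply(seq_len(n_calls), function(i)
      interval_list(calls$exon_starts[i], calls$exon_ends[i]))
    for (i in seq_len(n_calls)) {
      civ <- call_iv[[i]]
      clen <- sum(civ[, 2] - civ[, 1] + 1L)
      for (j in seq_len(nrow(true_truth))) {
        if (calls$contig[i] != true_truth$contig[j] ||
            calls$strand[i] != true_truth$strand[j]) next
        tiv <- interval_list(true_truth$exon_starts[j], true_truth$exon_ends[j])
        tlen <- sum(tiv[, 2] - tiv[, 1] + 1L)
        ov <- overlap_len(civ, tiv)
        if (ov >= 0.5 * clen && ov >= 0.5 * tlen) {
          match_of[i] <- true_truth$implant_id[j]
          break
        }
      }
      if (is.na(match_of[i]) && nrow(decoys)) {
        for (j in seq_len(nrow(decoys))) {
          if (calls$contig[i] != decoys$contig[j]) next
          tiv <- interval_list(decoys$exon_starts[j], decoys$exon_ends[j])
          tlen <- sum(tiv[, 2] - tiv[, 1] + 1L)
          ov <- overlap_len(civ, tiv)
          if (ov >= 0.5 * min(clen, tlen)) decoy_hit[j] <- TRUE
        }
      }
    }
    mi <- which(!is.na(match_of))
    matched_family_ok <- vapply(mi, function(i)
      isTRUE(calls$family[i] ==
               true_truth$family[match(match_of[i], true_truth$implant_id)]),
      logical(1))
  }
  matched_ids <- unique(match_of[!is.na(match_of)])
  recall <- length(matched_ids) / nrow(true_truth)
  precision <- if (n_calls == 0) {
    warning("no calls; precision reported as 1.0 by convention")
    1.0
  } else sum(!is.na(match_of)) / n_calls
  family_accuracy <- if (length(matched_family_ok))
    mean(matched_family_ok) else NA_real_
  decoy_rejection <- if (nrow(decoys)) 1 - mean(decoy_hit) else NA_real_
  intron_recovery <- NA_real_
  if (!is.null(introns)) {
    tot <- 0L; rec <- 0L
    for (j in seq_len(nrow(true_truth))) {
      tr <- true_truth[j, ]
      if (tr$n_introns == 0) next
      il <- as.integer(strsplit(tr$intron_lengths, ";")[[1]])
      isub <- strsplit(tr$intron_subregions, ";")[[1]]
      tot <- tot + length(il)
      cand <- calls$candidate_id[which(match_of == tr$implant_id)]
      if (!length(cand)) next
      rep_i <- introns[introns$member_id %in% cand, , drop = FALSE]
      for (k in seq_along(il)) {
        hit <- which(rep_i$genomic_length == il[k] &
                       rep_i$subregion == isub[k])
        if (length(hit)) {
          rec <- rec + 1L
          rep_i <- rep_i[-hit[1], , drop = FALSE]
        }
      }
    }
    intron_recovery <- if (tot > 0) rec / tot else NA_real_
  }
  list(precision = precision, recall = recall,
       family_accuracy = family_accuracy,
       decoy_rejection = decoy_rejection,
       intron_recovery = intron_recovery,
       match_of = match_of)
}
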