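# In-group phylogenetic classification: build NJ, MP and ML trees of one
# candidate with the reference members of its higher-order group, test
# two-leaf monophyly with each reference, and assign family, ortholog,
# confidence tier and name.

#' Classification configuration
#'
#' @param support_threshold Bootstrap percentage that must be exceeded
#'   (strictly) for a clade to count (default 50).
#' @param max_ingroup In-group size cap; the best-scoring group members
#'   are kept (default 8).
#' @param top_k_vote Number of top alignment hits used for the
#'   family-level majority vote of last resort.
#' @return List of class `classify_config`.
#' @export
classify_config <- function(support_threshold = 50, max_ingroup = 8,
                            top_k_vote = 5) {
  stopifnot(support_threshold >= 0, support_threshold <= 100,
            max_ingroup >= 2)
  structure(list(support_threshold = support_threshold,
                 max_ingroup = max_ingroup, top_k_vote = top_k_vote),
            class = "classify_config")
}

TIER_LEVELS <- c("full", "nj_mp", "single_method", "cross_species",
                 "family_only", "unassigned")

# Alignment score of a candidate against every panel member.
panel_scores <- function(peptide, panel, config = search_config()) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(stats::setNames(panel$motif_seq, panel$id)),
    Biostrings::AAString(toupper(peptide)), type = "local",
    substitutionMatrix = get_pam250_full(),
    gapOpening = config$gap_open, gapExtension = config$gap_extend)
  stats::setNames(Biostrings::score(pa), panel$id)
}

#' Choose the in-group and outgroup for one candidate
#'
#' The in-group consists of the panel members of the best-hitting
#' reference's higher-order group (capped at `max_ingroup` by descending
#' alignment score); the outgroup is the best-scoring panel member of a
#' different group.
#'
#' @param peptide Candidate amino-acid sequence.
#' @param panel A `reference_panel`.
#' @param config A [classify_config()].
#' @return List with `ingroup` (panel subset), `outgroup` (one panel
#'   row), `best_query`, `group` and `scores`.
#' @export
choose_ingroup <- function(peptide, panel, config = classify_config()) {
  if (nrow(panel) == 0) stop("unclassifiable: empty panel")
  scores <- panel_scores(peptide, panel)
  if (all(scores <= 0)) stop("unclassifiable: no alignment to any panel member")
  best <- names(scores)[order(-scores, names(scores))][1]
  grp <- panel$group[panel$id == best]
  members <- panel[panel$group == grp, , drop = FALSE]
  if (nrow(members) < 2)
    stop("group ", grp, " has fewer than 2 panel members")
  members <- members[order(-scores[members$id], members$id), , drop = FALSE]
  members <- members[seq_len(min(nrow(members), config$max_ingroup)), ,
                     drop = FALSE]
  others <- panel[panel$group != grp, , drop = FALSE]
  if (nrow(others) == 0) stop("no panel member outside group ", grp,
                              " to serve as outgroup")
  og <- others[order(-scores[others$id], others$id), , drop = FALSE][1, ]
  list(ingroup = members, outgroup = og, best_query = best, group = grp,
       scores = scores)
}

# One method's point tree + support, focused on the candidate.
method_support <- function(aln, method, pc, seed, focus) {
  builders <- switch(method,
    NJ = list(point = function(a) neighbor_joining(step_distance(a)),
              rep = function(a) neighbor_joining(step_distance(a)),
              reps = pc$nj_reps),
    MP = list(point = function(a) mp_search(a, pc, "full"),
              rep = function(a) mp_search(a, pc, "quick"),
              reps = pc$mp_reps),
    ML = list(point = function(a) ml_search(a, pc, "full"),
              rep = function(a) ml_search(a, pc, "quick"),
              reps = pc$ml_reps))
  bootstrap_support(aln, builders$point, reps = builders$reps, seed = seed,
                    focus = focus, rep_builder = builders$rep)
}

#' Classify one candidate by in-group phylogenetic analysis
#'
#' Aligns the candidate with its in-group and outgroup, builds NJ, MP and
#' ML trees with bootstrap support, and applies the decision rule: a
#' reference that forms a two-leaf monophyletic clade with the candidate
#' (rooted at the outgroup) in all three trees with every bootstrap value
#' exceeding the threshold is a full-confidence ortholog; agreement of NJ
#' and MP alone gives tier `nj_mp`; a single supported method gives
#' `single_method`; otherwise the candidate is `unassigned` at this
#' stage.
#'
#' @param peptide Candidate sequence.
#' @param candidate_id Label of the candidate.
#' @param ingroup Panel subset (>= 2 rows).
#' @param outgroup Single panel row from a different group.
#' @param phylo_cfg A [phylo_config()].
#' @param cls_cfg A [classify_config()].
#' @return List of class `orthology_call`: `candidate_id`, `family`,
#'   `group`, `ortholog_ref`, `per_method` (data frame with method,
#'   monophyletic, ortholog, support), `tier`, `trees` (named list of
#'   support-labelled `phylo`).
#' @export
ingroup_classify <- function(peptide, candidate_id, ingroup, outgroup,
                             phylo_cfg = phylo_config(),
                             cls_cfg = classify_config()) {
  stopifnot(nrow(ingroup) >= 2, nrow(outgroup) == 1)
  peps <- c(stats::setNames(toupper(peptide), candidate_id),
            stats::setNames(ingroup$motif_seq, ingroup$id),
            stats::setNames(outgroup$motif_seq, outgroup$id))
  call_fail <- function(reason) {
    structure(list(candidate_id = candidate_id, family = NA_character_,
                   group = NA_character_, ortholog_ref = NA_character_,
                   per_method = NULL, tier = "unassigned", reason = reason,
                   trees = NULL), class = "orthology_call")
  }
  aln <- tryCatch(progressive_align(peps), error = function(e) NULL)
  if (is.null(aln)) return(call_fail("alignment failure"))
  methods <- c("NJ", "MP", "ML")
  res <- list()
  for (i in seq_along(methods)) {
    res[[methods[i]]] <- method_support(aln, methods[i], phylo_cfg,
                                        seed = phylo_cfg$seed + i - 1L,
                                        focus = candidate_id)
  }
  thr <- cls_cfg$support_threshold
  per <- do.call(rbind, lapply(methods, function(m) {
    pt <- res[[m]]$tree
    sis <- sister_leaf(pt, candidate_id)
    ok_sis <- !is.na(sis) && sis != outgroup$id
    supp <- if (ok_sis) unname(res[[m]]$pair_support[sis]) else NA_real_
    data.frame(method = m, monophyletic = ok_sis,
               ortholog = if (ok_sis) sis else NA_character_,
               support = supp, stringsAsFactors = FALSE)
  }))
  ok <- per$monophyletic & !is.na(per$support) & per$support > thr
  tier <- "unassigned"
  ortholog <- NA_character_
  if (all(ok) && length(unique(per$ortholog)) == 1) {
    tier <- "full"; ortholog <- per$ortholog[1]
  } else if (ok[1] && ok[2] && per$ortholog[1] == per$ortholog[2]) {
    tier <- "nj_mp"; ortholog <- per$ortholog[1]
  } else if (any(ok)) {
    cand <- per[ok, , drop = FALSE]
    cand <- cand[order(-cand$support, match(cand$method, methods)), ,
                 drop = FALSE]
    tier <- "single_method"; ortholog <- cand$ortholog[1]
  }
  fam <- grp <- NA_character_
  if (!is.na(ortholog)) {
    fam <- ingroup$family[ingroup$id == ortholog]
    grp <- ingroup$group[ingroup$id == ortholog]
  }
  structure(list(candidate_id = candidate_id, family = fam, group = grp,
                 ortholog_ref = ortholog, per_method = per, tier = tier,
                 reason = "",
                 trees = lapply(res, `[[`, "tree")),
            class = "orthology_call")
}

#' @export
print.orthology_call <- function(x, ...) {
  cat("orthology call for", x$candidate_id, "- tier:", x$tier, "\n")
  if (!is.na(x$ortholog_ref))
    cat("  ortholog:", x$ortholog_ref, " family:", x$family,
        " group:", x$group, "\n")
  if (!is.null(x$per_method)) print(x$per_method)
  invisible(x)
}

#' Cross-species fallback classification
#'
#' Candidates without a supported ortholog in the primary panel are
#' re-analysed against each fallback species panel in order; the first
#' panel yielding at least a single supported method defines the
#' ortholog, with tier `cross_species`. If no panel succeeds, the family
#' is assigned by majority vote among the top-k alignment hits (tier
#' `family_only`); with no vote possible the candidate stays
#' `unassigned`.
#'
#' @param peptide,candidate_id Candidate sequence and label.
#' @param fallback_panels List of `reference_panel` objects (may be
#'   empty).
#' @param vote_panel Panel used for the family vote (typically the
#'   primary panel).
#' @param phylo_cfg,cls_cfg Configurations.
#' @param prior_call The failed primary-panel call (returned unchanged
#'   when everything fails and no vote is possible).
#' @return An `orthology_call`.
#' @export
cross_species_fallback <- function(peptide, candidate_id, fallback_panels,
                                   vote_panel,
                                   phylo_cfg = phylo_config(),
                                   cls_cfg = classify_config(),
                                   prior_call = NULL) {
  for (pnl in fallback_panels) {
    sel <- tryCatch(choose_ingroup(peptide, pnl, cls_cfg),
                    error = function(e) NULL)
    if (is.null(sel)) next
    call <- ingroup_classify(peptide, candidate_id, sel$ingroup,
                             sel$outgroup, phylo_cfg, cls_cfg)
    if (call$tier %in% c("full", "nj_mp", "single_method")) {
      call$tier <- "cross_species"
      call$fallback_species <- pnl$species[1]
      return(call)
    }
  }
  scores <- panel_scores(peptide, vote_panel)
  top <- names(scores)[order(-scores, names(scores))]
  top <- top[seq_len(min(cls_cfg$top_k_vote, length(top)))]
  top <- top[scores[top] > 0]
  if (length(top)) {
    fams <- vote_panel$family[match(top, vote_panel$id)]
    # score-weighted family vote (plain counts tie too easily)
    tab <- sort(tapply(scores[top], fams, sum), decreasing = TRUE)
    fam <- names(tab)[1]
    grp <- vote_panel$group[match(fam, vote_panel$family)]
    return(structure(list(candidate_id = candidate_id, family = fam,
                          group = grp, ortholog_ref = NA_character_,
                          per_method = NULL, tier = "family_only",
                          reason = "majority family vote", trees = NULL),
                     class = "orthology_call"))
  }
  if (!is.null(prior_call)) prior_call
  else structure(list(candidate_id = candidate_id, family = NA_character_,
                      group = NA_character_, ortholog_ref = NA_character_,
                      per_method = NULL, tier = "unassigned",
                      reason = "no fallback evidence", trees = NULL),
                 class = "orthology_call")
}

# Family stems whose punctuation collapses to an established short form.
FAMILY_STEMS <- c("H/E(spl)" = "HES")

name_stem <- function(call) {
  stem <- if (!is.na(call$ortholog_ref)) {
    sub("-\\d+$", "", call$ortholog_ref)  # drop panel member suffix
  } else call$family
  if (is.na(stem)) return(NA_character_)
  if (stem %in% names(FAMILY_STEMS)) return(unname(FAMILY_STEMS[stem]))
  gsub("[^A-Za-z0-9()]", "", stem)
}

#' Assign a unique gene name to one call
#'
#' The name is the species prefix plus the ortholog (or family) stem;
#' when the stem is already in use, the next free suffix is appended:
#' numbers for alphabetic stems, letters for stems that already end in a
#' digit (so a second `Stich1` becomes `Stich1b`).
#'
#' @param species_prefix E.g. `"Ap"`.
#' @param call An `orthology_call` (or a stem string).
#' @param existing_names Character set of names already taken.
#' @param style `"auto"` (default), `"numeric"` or `"letters"`.
#' @return A name not in `existing_names`.
#' @export
assign_name <- function(species_prefix, call, existing_names = character(0),
                        style = c("auto", "numeric", "letters")) {
  style <- match.arg(style)
  stem <- if (is.character(call)) call else name_stem(call)
  if (is.na(stem)) stop("call has neither ortholog nor family")
  base <- paste0(species_prefix, stem)
  suffixed <- style == "letters" ||
    (style == "auto" && grepl("[0-9]$", stem))
  suffixes <- if (suffixed) letters else as.character(1:99)
  taken <- function(x) x %in% existing_names
  has_suffixed_sibling <- any(taken(paste0(base, suffixes)))
  if (!taken(base) && !has_suffixed_sibling) return(base)
  for (s in suffixes) {
    cand <- paste0(base, s)
    if (!taken(cand)) return(cand)
  }
  stop("no free name for stem ", stem)
}

#' Assign names to a whole run of calls
#'
#' Stems claimed by a single candidate get the bare name; stems shared by
#' several candidates are numbered (or lettered for stems ending in a
#' digit) in input order, so two Mist orthologs become `<prefix>Mist1`
#' and `<prefix>Mist2`.
#'
#' @param calls List of `orthology_call`s.
#' @param species_prefix Name prefix.
#' @return The calls with `$assigned_name` set (injective over the run).
#' @export
assign_names <- function(calls, species_prefix) {
  stems <- vapply(calls, function(cl)
    if (is.na(name_stem(cl))) "unassigned" else name_stem(cl), "")
  counts <- table(stems)
  existing <- character(0)
  for (i in seq_along(calls)) {
    st <- stems[i]
    if (st == "unassigned") {
      nm <- assign_name(species_prefix, "bHLHu", existing, style = "numeric")
    } else if (counts[st] == 1) {
      nm <- assign_name(species_prefix, st, existing)
    } else {
      # shared stem: always suffixed
      style <- if (grepl("[0-9]$", st)) "letters" else "numeric"
      nm <- assign_name(species_prefix, st, c(existing, paste0(species_prefix, st)),
                        style = style)
    }
    calls[[i]]$assigned_name <- nm
    existing <- c(existing, nm)
  }
  calls
}

#' Group and family counts of a set of calls
#'
#' @param calls List of `orthology_call`s (or a data frame with `group`,
#'   `family`, `tier` columns).
#' @return List with `per_group` (named counts over A-F), `n_families`,
#'   `n_assigned`, `n_unassigned`.
#' @export
summarize_groups <- function(calls) {
  if (is.data.frame(calls)) df <- calls
  else df <- data.frame(
    group = vapply(calls, function(x) as.character(x$group)[1], ""),
    family = vapply(calls, function(x) as.character(x$family)[1], ""),
    tier = vapply(calls, `[[`, "", "tier"), stringsAsFactors = FALSE)
  assigned <- df[df$tier != "unassigned" & !is.na(df$group), , drop = FALSE]
  per_group <- stats::setNames(integer(6), LETTERS[1:6])
  tab <- table(assigned$group)
  per_group[names(tab)] <- as.integer(tab)
  list(per_group = per_group,
       n_families = length(unique(assigned$family)),
       n_assigned = nrow(assigned),
       n_unassigned = nrow(df) - nrow(assigned))
}
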