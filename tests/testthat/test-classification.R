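# Small bootstrap replicate numbers keep these unit tests fast; the
# protocol-scale replicate numbers are exercised by the end-to-end
# acceptance checks.
fast_pc <- function(seed = 1) phylo_config(nj_reps = 100, mp_reps = 40,
                                           ml_reps = 40, seed = seed)

test_that("in-group selection stays within the best hit's group", {
  panel <- default_reference_panel()
  cand <- panel$motif_seq[panel$id == "Da"]
  sel <- choose_ingroup(cand, panel, classify_config(max_ingroup = 6))
  expect_equal(sel$best_query, "Da")
  expect_equal(sel$group, "A")
  expect_true(all(sel$ingroup$group == "A"))
  expect_lte(nrow(sel$ingroup), 6)
  expect_false(sel$outgroup$group == "A")
  expect_error(choose_ingroup(cand, panel[0, ]), "unclassifiable")
})

test_that("an identity clone is a full-tier ortholog with support 100", {
  cfg <- simulation_config(n_families = 8, members_per_family = 2, seed = 3)
  pnl <- generate_panel(cfg)
  cand <- pnl$panel$motif_seq[1]
  sel <- choose_ingroup(cand, pnl$panel)
  call <- ingroup_classify(cand, "cand", sel$ingroup, sel$outgroup,
                           fast_pc(2))
  expect_equal(call$tier, "full")
  expect_equal(call$ortholog_ref, pnl$panel$id[1])
  expect_equal(call$family, pnl$panel$family[1])
  expect_true(all(call$per_method$support == 100))
})

test_that("a lightly mutated planted candidate recovers its reference", {
  cfg <- simulation_config(n_families = 8, members_per_family = 2, seed = 3)
  pnl <- generate_panel(cfg)
  set.seed(31)
  src <- 5
  res <- strsplit(pnl$panel$motif_seq[src], "")[[1]]
  res <- bhlhscan:::mutate_peptide(res, 0.05, protect = pnl$conserved_columns)
  cand <- paste(res, collapse = "")
  sel <- choose_ingroup(cand, pnl$panel)
  call <- ingroup_classify(cand, "cand", sel$ingroup, sel$outgroup,
                           fast_pc(4))
  expect_true(call$tier %in% c("full", "nj_mp"))
  expect_equal(call$family, pnl$panel$family[src])
  expect_true(all(call$per_method$support[call$per_method$monophyletic] > 50))
})

test_that("an equidistant consensus candidate does not reach full tier", {
  cfg <- simulation_config(n_families = 6, members_per_family = 2,
                           within_family_divergence = 0.25,
                           conserved_site_protection = FALSE, seed = 9)
  pnl <- generate_panel(cfg)
  fam <- pnl$panel[pnl$panel$family == pnl$panel$family[1], ]
  a <- strsplit(fam$motif_seq[1], "")[[1]]
  b <- strsplit(fam$motif_seq[2], "")[[1]]
  # alternate residues from the two members: equidistant by construction
  cons <- ifelse(seq_along(a) %% 2 == 0, a, b)
  cand <- paste(cons, collapse = "")
  sel <- choose_ingroup(cand, pnl$panel)
  call <- ingroup_classify(cand, "cand", sel$ingroup, sel$outgroup,
                           fast_pc(6))
  # sister to one member is possible, but never with uniform full support
  expect_false(call$tier == "full" &&
                 all(call$per_method$support >= 95))
})

test_that("tier never improves when the support threshold rises", {
  cfg <- simulation_config(n_families = 6, members_per_family = 2, seed = 12)
  pnl <- generate_panel(cfg)
  set.seed(41)
  res <- strsplit(pnl$panel$motif_seq[3], "")[[1]]
  cand <- paste(bhlhscan:::mutate_peptide(res, 0.12,
                                          protect = pnl$conserved_columns),
                collapse = "")
  sel <- choose_ingroup(cand, pnl$panel)
  tiers <- vapply(c(50, 80, 99), function(thr) {
    ingroup_classify(cand, "cand", sel$ingroup, sel$outgroup, fast_pc(7),
                     classify_config(support_threshold = thr))$tier
  }, "")
  ranks <- match(tiers, bhlhscan:::TIER_LEVELS)
  expect_true(all(diff(ranks) >= 0))
})

test_that("cross-species fallback finds orthologs in secondary panels", {
  cfg <- simulation_config(n_families = 6, members_per_family = 2, seed = 21)
  primary <- generate_panel(cfg)
  cfg2 <- simulation_config(n_families = 6, members_per_family = 2, seed = 22)
  fallback <- generate_panel(cfg2)
  fallback$panel$species <- "fallback_sp"
  # candidate drawn from a family present only in the fallback panel
  cand <- fallback$panel$motif_seq[3]
  call <- cross_species_fallback(cand, "cand", list(fallback$panel),
                                 vote_panel = primary$panel,
                                 phylo_cfg = fast_pc(8))
  expect_equal(call$tier, "cross_species")
  expect_equal(call$ortholog_ref, fallback$panel$id[3])

  # no fallback panels: the family vote produces a family-only call
  vote <- cross_species_fallback(primary$panel$motif_seq[1], "cand", list(),
                                 vote_panel = primary$panel,
                                 phylo_cfg = fast_pc(9))
  expect_equal(vote$tier, "family_only")
  expect_equal(vote$family, primary$panel$family[1])
  expect_true(is.na(vote$ortholog_ref))
})

test_that("naming follows the shared-stem suffix rules", {
  mk <- function(ortholog, family = "Fam") structure(
    list(candidate_id = "x", family = family, group = "A",
         ortholog_ref = ortholog, per_method = NULL, tier = "full",
         trees = NULL), class = "orthology_call")
  # single ortholog: bare name
  one <- assign_names(list(mk("Da")), "Ap")
  expect_equal(one[[1]]$assigned_name, "ApDa")
  # two candidates sharing a stem get numbered
  two <- assign_names(list(mk("Mist"), mk("Mist")), "Ap")
  expect_equal(vapply(two, `[[`, "", "assigned_name"),
               c("ApMist1", "ApMist2"))
  # stems ending in a digit switch to letter suffixes
  st <- assign_names(list(mk("Stich1"), mk("Stich1")), "Ap")
  expect_equal(vapply(st, `[[`, "", "assigned_name"),
               c("ApStich1a", "ApStich1b"))
  # family-only H/E(spl) calls continue the HES series
  expect_equal(assign_name("Ap", mk(NA_character_, "H/E(spl)"),
                           c("ApHES1", "ApHES2")), "ApHES3")
  # injectivity over a run
  run <- assign_names(list(mk("Da"), mk("Mist"), mk("Mist"), mk("Da"),
                           mk(NA_character_, "H/E(spl)")), "Ap")
  nms <- vapply(run, `[[`, "", "assigned_name")
  expect_equal(anyDuplicated(nms), 0L)
})

test_that("group summaries count assigned calls", {
  empty <- summarize_groups(list())
  expect_true(all(empty$per_group == 0))
  df <- data.frame(
    group = c("A", "A", "B", "C", NA),
    family = c("f1", "f2", "f3", "f4", NA),
    tier = c("full", "nj_mp", "single_method", "family_only", "unassigned"),
    stringsAsFactors = FALSE)
  s <- summarize_groups(df)
  expect_equal(unname(s$per_group[c("A", "B", "C")]), c(2L, 1L, 1L))
  expect_equal(s$n_families, 4)
  expect_equal(s$n_assigned, 4)
  expect_equal(s$n_unassigned, 1)
  expect_equal(sum(s$per_group), s$n_assigned)
})
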