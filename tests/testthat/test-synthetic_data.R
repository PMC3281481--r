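test_that("panel generation honours divergence and protection", {
  cfg0 <- simulation_config(within_family_divergence = 0, seed = 5)
  p0 <- generate_panel(cfg0)
  for (f in unique(p0$panel$family)) {
    seqs <- p0$panel$motif_seq[p0$panel$family == f]
    expect_equal(length(unique(seqs)), 1)
  }

  cfg <- simulation_config(seed = 6)
  p <- generate_panel(cfg)
  cc <- p$conserved_columns
  mat <- do.call(rbind, strsplit(p$panel$motif_seq, ""))
  for (j in seq_along(cc))
    expect_equal(length(unique(mat[, cc[j]])), 1)

  # observed within-family differences near the binomial expectation
  diffs <- integer(0)
  n_free <- cfg$motif_length - length(cc)
  for (f in unique(p$panel$family)) {
    seqs <- strsplit(p$panel$motif_seq[p$panel$family == f], "")
    diffs <- c(diffs, sum(seqs[[1]] != seqs[[2]]))
  }
  # two members each mutated independently at rate 0.10 on free sites
  p_diff <- 1 - ((1 - 0.1)^2 + 0.1^2 / 19)
  expmean <- n_free * p_diff
  sd3 <- 3 * sqrt(length(diffs) * n_free * p_diff * (1 - p_diff)) /
    length(diffs)
  expect_lt(abs(mean(diffs) - expmean), sd3 + 1)
})

test_that("genome implanting is reproducible and round-trips via GFF3", {
  cfg <- tiny_sim(seed = 19)
  pnl <- generate_panel(cfg)
  sim1 <- implant_genome(pnl, cfg)
  sim2 <- implant_genome(pnl, cfg)
  expect_identical(sim1$genome, sim2$genome)
  expect_identical(sim1$truth, sim2$truth)

  # every implanted peptide is reproduced by translating its spliced CDS
  tr <- sim1$truth[sim1$truth$type == "implant", ]
  for (j in seq_len(nrow(tr))) {
    cds <- spliced_cds(sim1$genome, tr$contig[j], tr$strand[j],
                       tr$exon_starts[j], tr$exon_ends[j])
    expect_equal(brute_translate(cds), tr$peptide[j], info = tr$implant_id[j])
  }

  # the emitted GFF3 carries the same exon structure
  gff_path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim1$gff, gff_path)
  models <- read_gene_models(gff_path)
  expect_equal(nrow(models), nrow(tr))
  m <- models[match(paste0(tr$implant_id, ".t1"), models$model_id), ]
  expect_equal(m$exon_starts, tr$exon_starts)
  expect_equal(m$exon_ends, tr$exon_ends)
})

test_that("intron-free configurations yield single-exon truth", {
  cfg <- tiny_sim(seed = 20, intron_probability = 0)
  pnl <- generate_panel(cfg)
  sim <- implant_genome(pnl, cfg)
  tr <- sim$truth[sim$truth$type == "implant", ]
  expect_true(all(tr$n_introns == 0))
  expect_false(any(grepl(";", tr$exon_starts)))
})

test_that("truth scoring computes the documented quantities", {
  cfg <- tiny_sim(seed = 24, intron_probability = 0)
  pnl <- generate_panel(cfg)
  sim <- implant_genome(pnl, cfg)
  tr <- sim$truth[sim$truth$type == "implant", ]
  perfect <- data.frame(candidate_id = tr$implant_id, contig = tr$contig,
                        strand = tr$strand, exon_starts = tr$exon_starts,
                        exon_ends = tr$exon_ends, family = tr$family,
                        stringsAsFactors = FALSE)
  s <- score_against_truth(perfect, sim$truth)
  expect_equal(s$recall, 1)
  expect_equal(s$precision, 1)
  expect_equal(s$family_accuracy, 1)
  expect_equal(s$decoy_rejection, 1)

  expect_warning(s0 <- score_against_truth(perfect[0, ], sim$truth),
                 "precision")
  expect_equal(s0$recall, 0)
  expect_equal(s0$precision, 1)

  wrong <- perfect
  wrong$family[1] <- "NoSuchFamily"
  sw <- score_against_truth(wrong, sim$truth)
  expect_equal(sw$family_accuracy, (nrow(perfect) - 1) / nrow(perfect))
})

test_that("shuffled decoys fail the conserved-site filter", {
  cfg <- simulation_config(seed = 25)
  pnl <- generate_panel(cfg)
  spec <- calibrate_conserved_sites(pnl$alignment)
  set.seed(26)
  rejected <- 0L
  n <- 100L
  for (i in seq_len(n)) {
    src <- sample(nrow(pnl$panel), 1)
    decoy <- paste(sample(strsplit(pnl$panel$motif_seq[src], "")[[1]]),
                   collapse = "")
    f <- conserved_site_filter(decoy, pnl$alignment, spec)
    if (!f$keep) rejected <- rejected + 1L
  }
  expect_gte(rejected / n, 0.95)
})
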