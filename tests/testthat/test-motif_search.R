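test_that("six-frame translation matches the codon table", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(unname(fr["+1"]), "MK")
  expect_equal(unname(six_frame_translate("TTTCAT")["-1"]), "MK")
  expect_equal(unname(six_frame_translate("")), rep("", 6))
  expect_error(six_frame_translate("ATGU"), "non-nucleotide")

  set.seed(11)
  nt <- paste(sample(c("A", "C", "G", "T", "N"), 300, replace = TRUE,
                     prob = c(.24, .24, .24, .24, .04)), collapse = "")
  fr <- six_frame_translate(nt)
  rc <- revcomp(nt)
  for (k in 1:3) {
    expect_equal(unname(fr[paste0("+", k)]),
                 brute_translate(substr(nt, k, nchar(nt))))
    expect_equal(unname(fr[paste0("-", k)]),
                 brute_translate(substr(rc, k, nchar(rc))))
  }
})

test_that("local alignment equals brute-force enumeration on tiny peptides", {
  la <- local_align("WWW", "PPP")
  expect_equal(la$score, 0)
  pep <- "ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVW"
  self <- local_align(pep, pep)
  S <- pam250_matrix()
  expect_equal(self$score,
               sum(S[cbind(strsplit(pep, "")[[1]], strsplit(pep, "")[[1]])]))
  expect_equal(self$query_interval, c(1, nchar(pep)))

  set.seed(3)
  aa <- rownames(S)
  for (i in 1:20) {
    q <- paste(sample(aa, sample(2:5, 1), replace = TRUE), collapse = "")
    t <- paste(sample(aa, sample(2:6, 1), replace = TRUE), collapse = "")
    expect_equal(local_align(q, t)$score, brute_local_align(q, t, S),
                 info = paste(q, t))
  }
})

test_that("local alignment score is symmetric for symmetric matrices", {
  set.seed(4)
  aa <- rownames(pam250_matrix())
  for (i in 1:10) {
    q <- paste(sample(aa, 12, replace = TRUE), collapse = "")
    t <- paste(sample(aa, 20, replace = TRUE), collapse = "")
    expect_equal(local_align(q, t)$score, local_align(t, q)$score)
  }
})

test_that("scan finds implanted motifs on both strands", {
  panel <- default_reference_panel()[1:5, ]
  motif_nt <- vapply(strsplit(panel$motif_seq[1], "")[[1]], function(a) {
    code <- Biostrings::GENETIC_CODE
    names(code)[code == a][1]
  }, "")
  motif_nt <- paste(motif_nt, collapse = "")
  set.seed(9)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  genome <- c(ctgA = paste0(bg(300), motif_nt, bg(300)),
              ctgB = paste0(bg(200), revcomp(motif_nt), bg(250)))
  hits <- scan_target(panel, genome, search_config())
  hits <- dedupe_hits(hits[hits$score >= 40, ], 0.5)
  hA <- hits[hits$contig == "ctgA", ]
  hB <- hits[hits$contig == "ctgB", ]
  expect_gte(nrow(hA), 1)
  expect_gte(nrow(hB), 1)
  expect_equal(hA$peptide[which.max(hA$score)], panel$motif_seq[1])
  expect_true(all(hA$frame > 0) && all(hB$frame < 0))
  expect_equal(hA$start[which.max(hA$score)], 301)
  expect_error(scan_target(panel, c(x = "ATGQQQ")), "non-nucleotide")
})

test_that("dedupe keeps the dominant hit and is idempotent", {
  h <- data.frame(contig = "c1", frame = 1L, strand = "+",
                  start = c(100L, 100L), end = c(280L, 280L),
                  score = c(80, 75), query = c("q1", "q2"),
                  q_start = 1L, q_end = 60L, peptide = "X", n_exons = 1L,
                  exons = "100-280", stringsAsFactors = FALSE)
  out <- dedupe_hits(h, 0.5)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 80)

  h2 <- h; h2$contig <- c("c1", "c2")
  expect_equal(nrow(dedupe_hits(h2, 0.5)), 2)

  set.seed(21)
  rand <- data.frame(
    contig = sample(c("c1", "c2"), 60, TRUE), frame = sample(c(1L, -2L), 60, TRUE),
    strand = "+", start = sample(1:500, 60, TRUE), score = runif(60, 10, 90),
    query = sample(sprintf("q%d", 1:5), 60, TRUE), q_start = 1L, q_end = 60L,
    peptide = "X", n_exons = 1L, exons = "1-1", stringsAsFactors = FALSE)
  rand$end <- rand$start + sample(50:150, 60, TRUE)
  rand$exons <- paste0(rand$start, "-", rand$end)
  out <- dedupe_hits(rand, 0.5)
  expect_equal(dedupe_hits(out, 0.5), out)
  # no two kept hits on the same contig+frame overlap above the threshold
  for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out))) {
    if (i >= j) next
    if (out$contig[i] != out$contig[j] || out$frame[i] != out$frame[j]) next
    ov <- min(out$end[i], out$end[j]) - max(out$start[i], out$start[j]) + 1
    shorter <- min(out$end[i] - out$start[i], out$end[j] - out$start[j]) + 1
    expect_lt(ov / shorter, 0.5)
  }
  # every dropped hit overlaps a kept, not-lower-scoring hit
  dropped <- rand[!paste(rand$start, rand$score) %in%
                    paste(out$start, out$score), ]
  for (i in seq_len(nrow(dropped))) {
    cand <- out[out$contig == dropped$contig[i] &
                  out$frame == dropped$frame[i], ]
    ov <- pmin(cand$end, dropped$end[i]) - pmax(cand$start, dropped$start[i]) + 1
    shorter <- pmin(cand$end - cand$start, dropped$end[i] - dropped$start[i]) + 1
    expect_true(any(ov / shorter >= 0.5 & cand$score >= dropped$score[i]))
  }
})

test_that("chaining reassembles intron-split segments", {
  seg <- data.frame(
    contig = "c1", frame = c(1L, 2L), strand = "+",
    start = c(1000L, 1601L), end = c(1089L, 1690L),
    score = c(120, 110), query = "q1", q_start = c(1L, 31L),
    q_end = c(30L, 60L), peptide = c(strrep("A", 30), strrep("C", 30)),
    n_exons = 1L, exons = c("1000-1089", "1601-1690"),
    stringsAsFactors = FALSE)
  out <- chain_hits(seg, search_config())
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 230)
  expect_equal(out$n_exons, 2L)
  expect_equal(out$exons, "1000-1089;1601-1690")
  expect_equal(out$peptide, paste0(strrep("A", 30), strrep("C", 30)))

  # an interleaved off-query segment does not break the chain
  noise <- seg[1, ]
  noise$start <- 1200L; noise$end <- 1250L
  noise$q_start <- 10L; noise$q_end <- 26L; noise$score <- 30
  out2 <- chain_hits(rbind(seg, noise), search_config())
  expect_true(any(out2$score == 230 & out2$n_exons == 2))

  # beyond the maximum chain gap the segments stay separate
  far <- seg
  far$start[2] <- 60000L; far$end[2] <- 60089L
  far$exons[2] <- "60000-60089"
  expect_equal(nrow(chain_hits(far, search_config())), 2)
})

test_that("conserved-site filter keeps >= 10 of 19 matches", {
  # identity panel: consensus equals the sequence, 19 single-residue sites
  base <- default_reference_panel()$motif_seq[1]
  aln <- motif_alignment(stats::setNames(rep(base, 3), c("a", "b", "c")))
  spec <- conserved_site_spec(default_conserved_columns(),
                              strsplit(base, "")[[1]][default_conserved_columns()])
  res <- conserved_site_filter(base, aln, spec)
  expect_equal(res$conserved_matches, 19L)
  expect_true(res$keep)

  mutate_sites <- function(seq, sites) {
    r <- strsplit(seq, "")[[1]]
    for (s in sites) r[s] <- if (r[s] == "A") "W" else "A"
    paste(r, collapse = "")
  }
  cols <- default_conserved_columns()
  # exactly 9 matches (10 sites broken ... 19 - 10 = 9) -> discarded
  nine <- conserved_site_filter(mutate_sites(base, cols[1:10]), aln, spec)
  expect_equal(nine$conserved_matches, 9L)
  expect_false(nine$keep)
  # exactly 10 matches -> kept (boundary of the discard rule)
  ten <- conserved_site_filter(mutate_sites(base, cols[1:9]), aln, spec)
  expect_equal(ten$conserved_matches, 10L)
  expect_true(ten$keep)
  # a short fragment is rejected as truncated
  frag <- conserved_site_filter(substr(base, 1, 20), aln, spec)
  expect_false(frag$keep)
  expect_equal(frag$reason, "truncated")
})

test_that("proteome mode scans amino-acid targets directly", {
  panel <- default_reference_panel()[1:4, ]
  set.seed(33)
  aa <- rownames(pam250_matrix())
  bg <- function(n) paste(sample(aa, n, TRUE), collapse = "")
  prot <- c(p1 = paste0(bg(40), panel$motif_seq[2], bg(30)), p2 = bg(80))
  hits <- scan_target(panel, prot, search_config(), mode = "proteome")
  hits <- hits[hits$score >= 40, ]
  best <- hits[which.max(hits$score), ]
  expect_equal(best$contig, "p1")
  expect_equal(best$frame, 0L)
  expect_equal(best$start, 41)
  expect_equal(best$peptide, panel$motif_seq[2])
})
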