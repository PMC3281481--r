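test_that("progressive alignment handles identity and single indels", {
  two <- progressive_align(c(a = "ACDEFG", b = "ACDEFG"))
  expect_equal(unname(alignment_strings(two)), c("ACDEFG", "ACDEFG"))

  gap <- progressive_align(c(a = "ACDEFG", b = "ACEFG"))
  s <- alignment_strings(gap)
  expect_equal(nchar(s[["a"]]), 6)
  expect_equal(s[["a"]], "ACDEFG")
  expect_equal(s[["b"]], "AC-EFG")

  set.seed(2)
  aa <- rownames(pam250_matrix())
  peps <- stats::setNames(
    vapply(1:5, function(i)
      paste(sample(aa, sample(20:30, 1), TRUE), collapse = ""), ""),
    sprintf("p%d", 1:5))
  aln <- progressive_align(peps)
  expect_gte(aln$ncol, max(nchar(peps)))
  expect_equal(aln$ids, names(peps))
  # deterministic
  expect_equal(alignment_strings(progressive_align(peps)),
               alignment_strings(aln))
})

test_that("step distances follow the PAM250 cost conversion", {
  aln <- motif_alignment(c(x = "AA", y = "AR"))
  d <- step_distance(aln)
  # cost(A,R) = (S(A,A)+S(R,R))/2 - S(A,R) = (2+6)/2 + 2 = 6; mean over 2 cols
  expect_equal(d["x", "y"], 3)
  expect_equal(diag(d), c(x = 0, y = 0))

  set.seed(6)
  aln2 <- random_alignment(5, 40)
  d2 <- step_distance(aln2)
  expect_true(isSymmetric(d2))
  expect_true(all(diag(d2) == 0))
  expect_true(all(d2 >= 0))

  gappy <- motif_alignment(c(a = "A-", b = "-R"))
  expect_error(step_distance(gappy), "no shared non-gap columns")
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2,
                                       dimnames = list(c("a", "b"), c("a", "b")))))
  dd <- d; dd[1, 2] <- 5
  expect_error(neighbor_joining(dd), "symmetric")
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(8)
  for (n in c(4, 5, 6, 8)) {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 1.5)
    d <- ape::cophenetic.phylo(tr)
    rec <- neighbor_joining(d[tr$tip.label, tr$tip.label])
    expect_equal(ape::dist.topo(ape::unroot(tr), rec), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    expect_equal(max(abs(ape::cophenetic.phylo(rec)[tr$tip.label, tr$tip.label] - d)),
                 0, tolerance = 1e-8)
  }
})

test_that("fitch score matches hand cases and exhaustive labelings", {
  same <- motif_alignment(c(t1 = "AAA", t2 = "AAA", t3 = "AAA", t4 = "AAA"))
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  expect_equal(fitch_score(tr, same), 0L)

  col <- motif_alignment(c(t1 = "A", t2 = "A", t3 = "C", t4 = "C"))
  expect_equal(fitch_score(ape::read.tree(text = "((t1,t2),(t3,t4));"), col), 1L)
  expect_equal(fitch_score(ape::read.tree(text = "((t1,t3),(t2,t4));"), col), 2L)

  expect_error(fitch_score(tr, motif_alignment(c(x = "A", y = "C", z = "G", w = "T"))),
               "do not match")

  set.seed(12)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    aln <- random_alignment(n, sample(4:8, 1))
    # occasional gaps exercise missing-data handling
    aln$mat[sample(length(aln$mat), 3)] <- "-"
    topo <- ape::rtree(n, rooted = FALSE, tip.label = aln$ids)
    expect_equal(fitch_score(topo, aln), brute_fitch(topo, aln), info = i)
  }
})

test_that("fitch score is monotone when columns are added", {
  set.seed(13)
  aln <- random_alignment(5, 10)
  topo <- ape::rtree(5, rooted = FALSE, tip.label = aln$ids)
  sub <- motif_alignment(aln$mat[, 1:6])
  expect_lte(fitch_score(topo, sub), fitch_score(topo, aln))
})

test_that("parsimony search recovers a homoplasy-free topology", {
  # columns are clade indicators of the generating tree: it is the unique
  # most-parsimonious topology with one change per column
  gen <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  cols <- list(c(a = "A", b = "A", c = "C", d = "C", e = "C", f = "C"),
               c(a = "C", b = "C", c = "A", d = "A", e = "C", f = "C"),
               c(a = "C", b = "C", c = "C", d = "C", e = "A", f = "A"))
  cols <- rep(cols, 4)
  rows <- vapply(c("a", "b", "c", "d", "e", "f"), function(t)
    paste(vapply(cols, `[[`, "", t), collapse = ""), "")
  aln <- motif_alignment(rows)
  mp <- mp_search(aln, phylo_config(seed = 1))
  expect_equal(attr(mp, "score"), length(cols) / 4 * 4)
  expect_equal(ape::dist.topo(gen, mp), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  # exhaustiveness: no enumerated topology scores lower
  scores <- vapply(enumerate_topologies(aln$ids), fitch_score, 0L, aln = aln)
  expect_equal(attr(mp, "score"), min(scores))
  # row permutation leaves the score unchanged
  perm <- motif_alignment(rows[sample(names(rows))])
  expect_equal(attr(mp_search(perm, phylo_config(seed = 1)), "score"),
               attr(mp, "score"))
})

test_that("JTT likelihood matches direct matrix exponentiation", {
  m <- jtt_rate_matrix()
  expect_equal(sum(m$pi * -diag(m$Q)), 1, tolerance = 1e-12)
  expect_equal(rowSums(m$Q), rep(0, 20), tolerance = 1e-12,
               ignore_attr = TRUE)

  # zero-branch limit: two identical one-site sequences
  tr0 <- ape::read.tree(text = "(x:0,y:0);")
  expect_equal(jtt_likelihood(tr0, motif_alignment(c(x = "A", y = "A"))),
               log(m$pi[["A"]]), tolerance = 1e-10)

  set.seed(14)
  aa <- rownames(pam250_matrix())
  for (i in 1:10) {
    t <- stats::runif(1, 0.01, 3)
    a <- sample(aa, 1); b <- sample(aa, 1)
    tr <- ape::read.tree(text = sprintf("(x:%.12f,y:%.12f);", t / 2, t / 2))
    P <- as.matrix(Matrix::expm(m$Q * (t / 2)))
    direct <- log(sum(m$pi * P[, a] * P[, b]))
    mine <- jtt_likelihood(tr, motif_alignment(c(x = a, y = b)))
    expect_equal(mine, direct, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to re-rooting", {
  set.seed(15)
  aln <- random_alignment(5, 25)
  tr <- ape::rtree(5, rooted = FALSE, tip.label = aln$ids)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.8)
  ll <- jtt_likelihood(tr, aln)
  for (og in aln$ids[1:3]) {
    rr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(jtt_likelihood(rr, aln), ll, tolerance = 1e-8)
  }
})

test_that("likelihood agrees with an independent pruning implementation", {
  skip_if_not_installed("phangorn")
  set.seed(16)
  aln <- random_alignment(4, 30)
  tr <- ape::rtree(4, rooted = FALSE, tip.label = aln$ids)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.6)
  dat <- phangorn::phyDat(aln$mat, type = "AA")
  fit <- phangorn::pml(tr, dat, model = "JTT",
                       bf = jtt_rate_matrix()$pi)
  expect_equal(jtt_likelihood(tr, aln), as.numeric(fit$logLik),
               tolerance = 1e-6)
})

test_that("ML search improves on its start and recovers a simulated tree", {
  set.seed(17)
  gen <- ape::read.tree(text = "((a:0.15,b:0.15):0.2,(c:0.15,d:0.15):0.2,(e:0.15,f:0.15):0.2);")
  aa <- rownames(pam250_matrix())
  # simulate one site at a time down the tree under JTT
  sim_sites <- function(tree, L) {
    tree <- stats::reorder(tree, "postorder")
    ntip <- length(tree$tip.label)
    root <- tree$edge[nrow(tree$edge), 1]
    states <- matrix(NA_integer_, ntip + tree$Nnode, L)
    pi <- jtt_rate_matrix()$pi
    states[root, ] <- sample.int(20, L, replace = TRUE, prob = pi)
    for (k in rev(seq_len(nrow(tree$edge)))) {
      P <- jtt_prob(tree$edge.length[k])
      par <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      states[ch, ] <- vapply(states[par, ], function(s)
        sample.int(20, 1, prob = P[s, ]), 0L)
    }
    rows <- apply(states[seq_len(ntip), , drop = FALSE], 1, function(r)
      paste(aa[r], collapse = ""))
    stats::setNames(rows, tree$tip.label)
  }
  aln <- motif_alignment(sim_sites(gen, 500))
  ml <- ml_search(aln, phylo_config(seed = 2))
  expect_equal(ape::dist.topo(gen, ml), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  nj <- ape::unroot(neighbor_joining(step_distance(aln)))
  expect_gte(attr(ml, "loglik"), jtt_likelihood(nj, aln) - 1e-6)
  # local optimum: perturbing any optimized branch length does not help
  ll <- attr(ml, "loglik")
  for (k in seq_len(nrow(ml$edge))) {
    for (f in c(0.9, 1.1)) {
      pert <- ml
      pert$edge.length[k] <- ml$edge.length[k] * f
      expect_lte(jtt_likelihood(pert, aln), ll + 1e-6)
    }
  }
})

test_that("monophyly test agrees with ape on random trees", {
  t1 <- ape::read.tree(text = "((a,b),(c,o));")
  expect_true(is_monophyletic_pair(t1, "a", "b", "o"))
  t2 <- ape::read.tree(text = "((a,c),(b,o));")
  expect_false(is_monophyletic_pair(t2, "a", "b", "o"))
  expect_error(is_monophyletic_pair(t1, "a", "zz", "o"), "zz")

  set.seed(18)
  for (i in 1:20) {
    tr <- ape::rtree(10, rooted = FALSE)
    tips <- sample(tr$tip.label, 3)
    mine <- is_monophyletic_pair(tr, tips[1], tips[2], tips[3])
    rt <- ape::root(tr, outgroup = tips[3], resolve.root = TRUE)
    expect_equal(mine, ape::is.monophyletic(rt, tips[1:2]), info = i)
  }
})

test_that("bootstrap support is exact on unambiguous data and reproducible", {
  # every informative column supports ((a,b),(c,d))
  rows <- c(a = strrep("A", 30), b = strrep("A", 30),
            c = strrep("C", 30), d = strrep("C", 30))
  # add distinguishing noise so tips are not identical
  substr(rows[["a"]], 1, 2) <- "RN"
  substr(rows[["c"]], 1, 2) <- "KV"
  aln <- motif_alignment(rows)
  njb <- function(a) neighbor_joining(step_distance(a))
  bs <- bootstrap_support(aln, njb, reps = 200, seed = 5, focus = "a")
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  key <- names(bs$support)
  expect_equal(unname(bs$support[key]), 100)
  expect_equal(unname(bs$pair_support[["b"]]), 100)
  bs2 <- bootstrap_support(aln, njb, reps = 200, seed = 5, focus = "a")
  expect_identical(bs$support, bs2$support)
})
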