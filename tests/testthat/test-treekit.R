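test_that("NJ recovers an additive 4-taxon metric exactly", {
  true <- ape::read.tree(text = "((A:0.1,B:0.1):0.2,(C:0.1,D:0.1):0.2);")
  d <- ape::cophenetic.phylo(true)
  est <- nj_tree(stats::as.dist(d))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), est)), 0)
  expect_equal(as.matrix(ape::cophenetic.phylo(est))[rownames(d), colnames(d)],
               d, tolerance = 1e-10)
})

test_that("NJ reproduces random tree metrics exactly (consistency property)", {
  set.seed(20)
  for (i in 1:8) {
    n <- sample(5:16, 1)
    true <- ape::rtree(n)
    est <- nj_tree(stats::as.dist(ape::cophenetic.phylo(true)))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), est)), 0)
  }
})

test_that("NJ fails informatively on 2 taxa and on an all-missing pair", {
  g <- geno_matrix(rbind(a = c(0L, 1L), b = c(1L, 2L)))
  expect_error(nj_tree(g), "at least 3")
  G <- rbind(a = c(0L, NA), b = c(NA, 2L), c = c(1L, 1L))
  expect_error(nj_tree(geno_matrix(G)), "a.*b|no shared")
})

test_that("negative NJ branch lengths are clamped with length transferred", {
  # near-degenerate distances provoke negative estimates; output must be
  # nonnegative with pairwise path lengths preserved where possible
  set.seed(30)
  d <- matrix(runif(36, 0.99, 1.01), 6)
  d <- (d + t(d)) / 2; diag(d) <- 0
  rownames(d) <- colnames(d) <- letters[1:6]
  tr <- nj_tree(stats::as.dist(d))
  expect_true(all(tr$edge.length >= 0))
})

test_that("monophyly semantics match the caterpillar worked example", {
  cat <- ape::read.tree(text = "(((a1,a2),b1),b2);")
  expect_false(is_monophyletic(cat, c("b1", "b2"), rooted = TRUE))
  # unrooted, the 4-taxon caterpillar collapses to the quartet a1a2|b1b2,
  # so the b-pair IS a bipartition; a 5-taxon caterpillar is not
  expect_true(is_monophyletic(cat, c("b1", "b2"), rooted = FALSE))
  cat5 <- ape::read.tree(text = "((((a1,a2),b1),b2),c1);")
  expect_false(is_monophyletic(cat5, c("b1", "b2"), rooted = TRUE))
  expect_false(is_monophyletic(cat5, c("b1", "b2"), rooted = FALSE))
  expect_true(is_monophyletic(cat, c("a1", "a2")))
  expect_true(is_monophyletic(cat, cat$tip.label))       # full set
  expect_true(is_monophyletic(cat, "a1"))                # singleton
  bal <- ape::read.tree(text = "((a1,a2),(b1,b2));")
  expect_true(is_monophyletic(bal, c("b1", "b2"), rooted = FALSE))
  expect_error(is_monophyletic(cat, "zz"), "unknown")
})

test_that("gCF: identical gene trees give 100 everywhere; worked 2-of-3 example", {
  sp <- ape::read.tree(text = "((A,B),(C,D));")
  gt_same <- rep(c(sp), 5)
  gc <- gene_concordance(sp, gt_same)
  expect_true(all(gc$gcf == 100))
  gts <- c(ape::read.tree(text = "((A,B),(C,D));"),
           ape::read.tree(text = "((A,C),(B,D));"),
           ape::read.tree(text = "((A,B),(C,D));"))
  gc2 <- gene_concordance(sp, gts)
  expect_equal(gc2$gcf, 100 * 2 / 3, tolerance = 1e-10)
  expect_equal(gc2$n_decisive, 3)
})

test_that("gene trees missing a taxon are excluded from the denominator", {
  sp <- ape::read.tree(text = "((A,B),(C,D));")
  gts <- c(ape::read.tree(text = "((A,B),(C,D));"),
           ape::read.tree(text = "((A,B),C);"))   # no D: not decisive
  gc <- gene_concordance(sp, gts)
  expect_equal(gc$n_decisive, 1)
  expect_equal(gc$gcf, 100)
})

test_that("sCF: diagnostic alignment gives 100, symmetric alignment ~33.3", {
  sp <- ape::read.tree(text = "((A,B),(C,D));")
  diag_aln <- aln_from_haps("L1", list(
    A = c("AAAAAAAAGG", "AAAAAAAAGG"), B = c("AAAAAAAAGG", "AAAAAAAAGG"),
    C = c("TTTTTTTTGG", "TTTTTTTTGG"), D = c("TTTTTTTTGG", "TTTTTTTTGG")))
  sc <- site_concordance(sp, diag_aln, n_quartets = 10, seed = 1)
  expect_true(all(sc$scf == 100))
  # 10 sites supporting each of the three pairings
  blk <- function(p) paste(rep(p, 10), collapse = "")
  sym <- aln_from_haps("L1", list(
    A = rep(paste0(blk("A"), blk("A"), blk("A")), 2),
    B = rep(paste0(blk("A"), blk("T"), blk("T")), 2),
    C = rep(paste0(blk("T"), blk("A"), blk("T")), 2),
    D = rep(paste0(blk("T"), blk("T"), blk("A")), 2)))
  sc_sym <- site_concordance(sp, sym, n_quartets = 10, seed = 2)
  expect_equal(sc_sym$scf, 100 / 3, tolerance = 1e-10)
  # no decisive sites at all -> flagged undefined
  inv <- aln_from_haps("L1", list(A = c("AAAA", "AAAA"), B = c("AAAA", "AAAA"),
                                  C = c("AAAA", "AAAA"), D = c("AAAA", "AAAA")))
  sc_inv <- site_concordance(sp, inv, n_quartets = 5, seed = 3)
  expect_true(all(sc_inv$undefined))
})

test_that("sCF is deterministic under a fixed seed", {
  sp <- ape::read.tree(text = "(((A,B),(C,D)),(E,F));")
  set.seed(40)
  haps <- lapply(setNames(sp$tip.label, sp$tip.label), function(x) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    c(s, s)
  })
  aln <- aln_from_haps("L1", haps)
  s1 <- site_concordance(sp, aln, n_quartets = 20, seed = 7)
  s2 <- site_concordance(sp, aln, n_quartets = 20, seed = 7)
  expect_identical(s1, s2)
})

test_that("terminal gCF duplicates across a cherry and is 100 for a universal branch", {
  sp <- ape::read.tree(text = "(((A,B),C),(D,E));")
  gts <- rep(c(sp), 4)
  tg <- terminal_gcf(sp, gts)
  expect_equal(tg$gcf[tg$specimen == "A"], tg$gcf[tg$specimen == "B"])
  expect_equal(tg$gcf[tg$specimen == "A"], 100)
  expect_equal(tg$branch[tg$specimen == "D"], tg$branch[tg$specimen == "E"])
})

test_that("gCF is invariant to gene-tree input order", {
  sp <- ape::read.tree(text = "((A,B),(C,D));")
  gts <- c(ape::read.tree(text = "((A,B),(C,D));"),
           ape::read.tree(text = "((A,C),(B,D));"),
           ape::read.tree(text = "((A,D),(B,C));"),
           ape::read.tree(text = "((A,B),(C,D));"))
  expect_equal(gene_concordance(sp, gts)$gcf,
               gene_concordance(sp, rev(gts))$gcf)
})

test_that("concordance-annotated Newick round-trips through node labels", {
  sp <- ape::read.tree(text = "(((A,B),C),(D,E));")
  gc <- gene_concordance(sp, rep(c(sp), 3))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_concordance_tree(sp, gcf = gc, path = path)
  back <- ape::read.tree(path)
  expect_true(any(grepl("/100.00/", back$node.label)))
})
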