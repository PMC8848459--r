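test_that("Balding-Nichols frequencies match their moment identities", {
  m <- population_model(pops = c("p1", "p2"), F = c(p1 = 0.2, p2 = 1e-4))
  fr <- simulate_allele_frequencies(m, 1e5, seed = 1,
                                    ancestral = function(n) rep(0.5, n))
  # Var = F p (1 - p) = 0.05 at F = 0.2, p = 0.5, within 5%
  expect_lt(abs(var(fr$freq["p1", ]) - 0.05) / 0.05, 0.05)
  # F -> 0 limit collapses onto the ancestral frequency
  expect_lt(var(fr$freq["p2", ]), 1e-4)
  # degenerate ancestral p = 0 stays 0 in every population
  fr0 <- simulate_allele_frequencies(m, 100, seed = 2,
                                     ancestral = function(n) rep(0, n))
  expect_true(all(fr0$freq == 0))
  expect_error(population_model(pops = "x", F = c(x = 0)), "strictly inside")
})

test_that("genotype simulation follows the binomial mixture", {
  P <- rbind(A = c(1, 1, 0), B = c(0, 1, 1))
  Q1 <- matrix(c(1, 0), 1)
  rownames(Q1) <- "i1"
  g1 <- simulate_genotypes(P, Q1, seed = 3)
  expect_equal(unname(g1$G[1, ]), c(2L, 2L, 0L))
  # 50/50 individual at a diagnostic site: mean genotype 1.0 +/- 0.02
  Qh <- matrix(0.5, 1e4, 2)
  rownames(Qh) <- paste0("i", seq_len(1e4))
  gh <- simulate_genotypes(rbind(A = 1, B = 0), Qh, seed = 4)
  expect_equal(mean(gh$G), 1, tolerance = 0.02)
  expect_error(simulate_genotypes(P, matrix(1, 1, 3)), "populations")
  expect_error(simulate_genotypes(P, matrix(c(0.7, 0.6), 1)), "sum to 1")
})

test_that("single-population pairwise coalescence time has mean 1", {
  m <- population_model(tree = ape::read.tree(text = "(x:1,y:1);"))
  s <- tibble::tibble(specimen = "x_i1", population = "x")
  gt <- simulate_gene_trees(m, s, 2000, seed = 5)
  tmrca <- vapply(gt, function(t) max(ape::node.depth.edgelength(t)), numeric(1))
  expect_equal(mean(tmrca), 1, tolerance = 0.05)
})

test_that("deep splits give reciprocal monophyly in > 99% of loci", {
  m <- population_model(tree = ape::read.tree(text = "(x:10,y:10);"))
  s <- tibble::tibble(specimen = c("x_i1", "x_i2", "y_i1", "y_i2"),
                      population = rep(c("x", "y"), each = 2))
  gt <- simulate_gene_trees(m, s, 400, seed = 6)
  mono <- vapply(gt, function(t) {
    is_monophyletic(t, grep("^x", t$tip.label, value = TRUE), rooted = TRUE)
  }, logical(1))
  expect_gt(mean(mono), 0.99)
})

test_that("pulse admixture reroutes lineages at the stated rate", {
  tr <- ape::read.tree(text = "((d:8,r:8):2,o:10);")
  m <- population_model(tree = tr, pops = tr$tip.label,
                        pulses = tibble::tibble(donor = "d", recipient = "r",
                                                time = 1, prop = 0.3))
  s <- tibble::tibble(specimen = c("d_i1", "r_i1", "o_i1"),
                      population = c("d", "r", "o"))
  gt <- simulate_gene_trees(m, s, 2000, seed = 7)
  crossed <- vapply(gt, function(t) {
    cop <- ape::cophenetic.phylo(t)
    cop["r_i1|1", "d_i1|1"] < 2 * 8   # coalesced more recently than the split
  }, logical(1))
  expect_lt(abs(mean(crossed) - 0.3), 0.03)
})

test_that("pulse events must fall inside both branches' existence intervals", {
  tr <- ape::read.tree(text = "((d:2,r:2):2,o:4);")
  expect_error(population_model(tree = tr, pops = tr$tip.label,
                                pulses = tibble::tibble(donor = "d", recipient = "r",
                                                        time = 3, prop = 0.2)),
               "existence interval")
  expect_error(population_model(pops = "x", pulses = tibble::tibble(
    donor = "x", recipient = "x", time = 0, prop = 1.2)), "\\[0, 1\\]")
})

test_that("sequence evolution matches the Jukes-Cantor closed form", {
  tr <- ape::read.tree(text = "(a|1:0.05,b|1:0.05);")
  aln <- evolve_sequences(tr, 2e4, rate = 1, seed = 8)
  p_obs <- mean(aln$seqs[1, ] != aln$seqs[2, ])
  d <- 0.1
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 2e4)
  expect_lt(abs(p_obs - p_exp), 2 * se + 0.002)
  # rate 0: identical sequences
  aln0 <- evolve_sequences(tr, 100, rate = 0, seed = 9)
  expect_true(all(aln0$seqs[1, ] == aln0$seqs[2, ]))
  # saturation: identity -> 25%
  tr_far <- ape::read.tree(text = "(a|1:50,b|1:50);")
  aln_far <- evolve_sequences(tr_far, 1e4, rate = 1, seed = 10)
  expect_equal(mean(aln_far$seqs[1, ] == aln_far$seqs[2, ]), 0.25,
               tolerance = 0.02)
  expect_error(evolve_sequences(tr, 0, 1), "zero-length")
})

test_that("a fixed seed reproduces the dataset byte-for-byte", {
  mod <- population_model(tree = ape::read.tree(text = "((a:2,b:2):2,c:4);"))
  cfg <- sim_config(n_loci = 4, locus_length = 150, n_per_pop = 2,
                    site_missing = 0.02, ambig_rate = 0.01, seed = 11)
  d1 <- simulate_dataset(mod, cfg)
  d2 <- simulate_dataset(mod, cfg)
  expect_identical(lapply(d1$alignments, `[[`, "seqs"),
                   lapply(d2$alignments, `[[`, "seqs"))
  expect_identical(d1$genotypes$G, d2$genotypes$G)
  expect_identical(ape::write.tree(d1$gene_trees), ape::write.tree(d2$gene_trees))
})

test_that("the emitted genotype matrix is recomputable from the alignments", {
  mod <- population_model(tree = ape::read.tree(text = "((a:2,b:2):2,c:4);"))
  cfg <- sim_config(n_loci = 3, locus_length = 200, n_per_pop = 3,
                    site_missing = 0.05, seed = 12)
  ds <- simulate_dataset(mod, cfg)
  re <- genotypes_from_alignments(ds$alignments)
  expect_identical(ds$genotypes$G, re$G)
  expect_true(all(abs(rowSums(ds$Q_true) - 1) < 1e-12))
})

test_that("mitochondrial capture moves carriers into the donor clade", {
  mod <- population_model(tree = ape::read.tree(text = "((x:6,d:6):2,o:8);"))
  cfg <- sim_config(n_loci = 2, locus_length = 800, n_per_pop = 4, seed = 13)
  ds <- simulate_dataset(mod, cfg)
  # no carriers: unchanged
  expect_identical(make_mito_capture_locus(ds, character(), "d"), ds)
  expect_error(make_mito_capture_locus(ds, "nobody", "d"), "not in dataset")
  carriers <- paste0("x_i0", 1:4)
  cap <- make_mito_capture_locus(ds, carriers, "d", seed = 14)
  mito <- cap$alignments[[1]]
  tr <- nj_tree(mito, tips = "specimen")
  tr_rooted <- ape::root(tr, outgroup = "o_i01", resolve.root = TRUE)
  # all of x captured: x monophyletic and nested inside the donor clade
  expect_true(is_monophyletic(tr_rooted, carriers, rooted = TRUE))
  donor_clade <- ape::extract.clade(
    tr_rooted, ape::getMRCA(tr_rooted, c(carriers, paste0("d_i0", 1:4))))
  expect_setequal(donor_clade$tip.label, c(carriers, paste0("d_i0", 1:4)))
  # partial capture splits x across the mito tree
  cap2 <- make_mito_capture_locus(ds, carriers[1:2], "d", seed = 15)
  tr2 <- ape::root(nj_tree(cap2$alignments[[1]], tips = "specimen"),
                   outgroup = "o_i01", resolve.root = TRUE)
  expect_false(is_monophyletic(tr2, carriers, rooted = TRUE))
  # nuclear loci untouched
  expect_identical(cap$alignments[[2]]$seqs, ds$alignments[[2]]$seqs)
})

test_that("dataset files round-trip through the standard formats", {
  mod <- population_model(tree = ape::read.tree(text = "((a:2,b:2):2,c:4);"))
  ds <- simulate_dataset(mod, sim_config(n_loci = 2, locus_length = 150,
                                         n_per_pop = 2, seed = 16))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  gm <- read_genotypes_vcf(file.path(dir, "genotypes.vcf"))
  expect_identical(unname(gm$G[ds$genotypes$specimens, ]),
                   unname(ds$genotypes$G))
  alns <- read_alignments(list.files(file.path(dir, "loci"), full.names = TRUE))
  expect_identical(alns[[1]]$seqs, ds$alignments[[1]]$seqs)
  gt <- ape::read.tree(file.path(dir, "gene_trees.nwk"))
  expect_equal(length(gt), 2)
  prov <- yaml::read_yaml(file.path(dir, "provenance.yaml"))
  expect_equal(prov$seed, 16)
})
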