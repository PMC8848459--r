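test_that("Patterson's D matches hand summation on the 3:1 ABBA:BABA table", {
  ft <- hand_d_table()
  d <- patterson_d(ft, c("P1", "P2", "P3"))
  expect_equal(d$d, 0.5)
  expect_equal(d$abba, 3)
  expect_equal(d$baba, 1)
  expect_false(d$swapped)
})

test_that("swapping P1 and P2 negates D exactly before orientation", {
  ft <- hand_d_table()
  d12 <- patterson_d(ft, c("P1", "P2", "P3"), orient = FALSE)
  d21 <- patterson_d(ft, c("P2", "P1", "P3"), orient = FALSE)
  expect_equal(d12$d, -d21$d)
  # orientation convention flips to nonnegative and records the swap
  d_or <- patterson_d(ft, c("P2", "P1", "P3"))
  expect_true(d_or$swapped)
  expect_equal(d_or$d, 0.5)
})

test_that("D is zero by symmetry when P2's frequencies equal P1's", {
  G <- rbind(P1 = c(1L, 1L, 1L, 1L), P2 = c(1L, 1L, 1L, 1L),
             P3 = c(2L, 2L, 0L, 2L), OG = c(0L, 0L, 0L, 0L))
  gm <- geno_matrix(G, sites = tibble::tibble(site = paste0("s", 1:4),
                                              locus = paste0("L", 1:4), pos = 1:4))
  ft <- allele_freqs(gm, tibble::tibble(specimen = rownames(G),
                                        population = rownames(G)), "OG")
  expect_equal(patterson_d(ft, c("P1", "P2", "P3"), orient = FALSE)$d, 0)
})

test_that("a trio with no ABBA or BABA weight is flagged undefined", {
  G <- rbind(P1 = c(0L, 2L), P2 = c(0L, 2L), P3 = c(2L, 2L), OG = c(0L, 0L))
  gm <- geno_matrix(G, sites = tibble::tibble(site = c("s1", "s2"),
                                              locus = c("L1", "L2"), pos = 1:2))
  ft <- allele_freqs(gm, tibble::tibble(specimen = rownames(G),
                                        population = rownames(G)), "OG")
  d <- patterson_d(ft, c("P1", "P2", "P3"))
  expect_true(d$undefined)
  expect_true(is.na(d$d))
})

test_that("D is invariant to site order and block relabeling", {
  set.seed(5)
  m <- population_model(pops = c("A", "B", "C", "O"),
                        F = c(A = 0.2, B = 0.2, C = 0.3, O = 0.05))
  fr <- simulate_allele_frequencies(m, 400, seed = 2)
  Q <- diag(4)[rep(1:4, each = 5), ]
  rownames(Q) <- paste0(rep(c("A", "B", "C", "O"), each = 5), 1:5)
  gm <- simulate_genotypes(fr, Q, n_loci = 8, seed = 3)
  pm <- tibble::tibble(specimen = rownames(Q),
                       population = rep(c("A", "B", "C", "O"), each = 5))
  ft <- allele_freqs(gm, pm, "O")
  d0 <- patterson_d(ft, c("A", "B", "C"))
  perm <- sample(ncol(gm$G))
  gm_p <- geno_matrix(gm$G[, perm], gm$sites[perm, ], gm$specimens)
  ft_p <- allele_freqs(gm_p, pm, "O")
  d_p <- patterson_d(ft_p, c("A", "B", "C"))
  expect_equal(d_p$d, d0$d, tolerance = 1e-12)
  expect_equal(d_p$se, d0$se, tolerance = 1e-12)
})

test_that("jackknife closed form and degenerate case", {
  jk <- jackknife_se(c(0.1, 0.2, 0.3))
  expect_equal(jk$se, sqrt((2 / 3) * 0.02), tolerance = 1e-10)
  deg <- jackknife_se(c(0.2, 0.2, 0.2), estimate = 0.2)
  expect_equal(deg$se, 0)
  expect_true(deg$degenerate)
  expect_error(jackknife_se(0.5), "at least 2")
})

test_that("allele_freqs polarizes by the outgroup and drops unusable sites", {
  # site 1: outgroup fixed derived -> polarity flipped; site 2 monomorphic;
  # site 3 usable as-is
  G <- rbind(P1 = c(0L, 1L, 2L), P2 = c(1L, 1L, 1L), OG = c(2L, 1L, 0L))
  gm <- geno_matrix(G, sites = tibble::tibble(site = paste0("s", 1:3),
                                              locus = c("L1", "L1", "L2"), pos = 1:3))
  ft <- allele_freqs(gm, tibble::tibble(specimen = rownames(G),
                                        population = rownames(G)), "OG",
                     max_outgroup_maf = 0.1)
  expect_equal(ncol(ft$d), 2)          # monomorphic site 2 dropped
  # site 1 flipped: P1 was 0/2 copies -> derived count 2 of 2
  expect_equal(unname(ft$d[1, 1]), 2L)
  expect_equal(unname(ft$d[3, 1]), 0L) # outgroup ancestral after flip
})

test_that("f4-ratio hits its closed-form anchors", {
  set.seed(8)
  m <- population_model(pops = c("A", "B", "C", "O"),
                        F = c(A = 0.1, B = 0.1, C = 0.1, O = 0.01))
  fr <- simulate_allele_frequencies(m, 20000, seed = 21)
  # B a complete copy of C: f = 1
  fr$freq["B", ] <- fr$freq["C", ]
  Q <- diag(4)[rep(1:4, each = 8), ]
  rownames(Q) <- paste0(rep(c("A", "B", "C", "O"), each = 8), 1:8)
  pm <- tibble::tibble(specimen = rownames(Q),
                       population = rep(c("A", "B", "C", "O"), each = 8))
  gm <- simulate_genotypes(fr, Q, n_loci = 40, seed = 22)
  ft <- allele_freqs(gm, pm, "O")
  expect_equal(f4_ratio(ft, "A", "B", "C")$f4_ratio, 1, tolerance = 0.05)
  # B identical to A (no introgression): f ~ 0
  fr2 <- simulate_allele_frequencies(m, 20000, seed = 23)
  fr2$freq["B", ] <- fr2$freq["A", ]
  gm2 <- simulate_genotypes(fr2, Q, n_loci = 40, seed = 24)
  ft2 <- allele_freqs(gm2, pm, "O")
  expect_lt(abs(f4_ratio(ft2, "A", "B", "C")$f4_ratio_raw), 0.02)
})

test_that("f_branch masks donors inside the recipient clade structurally", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  set.seed(3)
  m <- population_model(tree = ape::read.tree(text = "((((A:1,B:1):1,C:2):1,D:3):1,O:4);"),
                        pops = c("A", "B", "C", "D", "O"))
  fr <- simulate_frequencies_tree(m, 3000, seed = 4)
  Q <- diag(5)[rep(1:5, each = 4), ]
  rownames(Q) <- paste0(rep(c("A", "B", "C", "D", "O"), each = 4), 1:4)
  pm <- tibble::tibble(specimen = rownames(Q),
                       population = rep(c("A", "B", "C", "D", "O"), each = 4))
  gm <- simulate_genotypes(fr, Q, n_loci = 20, seed = 5)
  ft <- allele_freqs(gm, pm, "O")
  fb <- f_branch(tr, ft, seed = 1)
  cells <- tidy(fb)
  inside <- cells[cells$branch == "A+B" & cells$donor %in% c("A", "B"), ]
  expect_true(all(is.na(inside$f_b_raw)))
  ab <- cells[!is.na(cells$f_b), ]
  expect_true(all(ab$f_b >= 0))
})

test_that("mean f4-ratio increases monotonically with the simulated pulse size", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):2,O:4);")
  levels <- c(0.1, 0.2, 0.3, 0.4)
  means <- vapply(levels, function(a) {
    est <- vapply(1:4, function(r) {
      m <- population_model(tree = tr, pops = tr$tip.label,
                            pulses = tibble::tibble(donor = "C", recipient = "B",
                                                    time = 0.05, prop = a))
      fr <- simulate_frequencies_tree(m, 8000, seed = 1000 * a + r)
      Q <- diag(4)[rep(1:4, each = 6), ]
      rownames(Q) <- paste0(rep(tr$tip.label, each = 6), 1:6)
      gm <- simulate_genotypes(fr, Q, n_loci = 20, seed = 2000 * a + r)
      pm <- tibble::tibble(specimen = rownames(Q),
                           population = rep(tr$tip.label, each = 6))
      f4_ratio(allele_freqs(gm, pm, "O"), "A", "B", "C")$f4_ratio
    }, numeric(1))
    mean(est)
  }, numeric(1))
  expect_equal(cor(means, levels, method = "spearman"), 1)
})

test_that("tree-consistent trio ordering puts the sister pair first", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  expect_equal(tree_consistent_trio(tr, c("C", "A", "B"))[3], "C")
  expect_setequal(tree_consistent_trio(tr, c("C", "A", "B"))[1:2], c("A", "B"))
  expect_equal(tree_consistent_trio(tr, c("D", "C", "A"))[3], "D")
})
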