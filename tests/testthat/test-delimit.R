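test_that("the rubric reproduces the expected candidate table exactly", {
  sc <- rubric_scenario()
  tab <- delimit(sc$tree, sc$assignments, sc$hybrid_calls)
  expect_equal(tab$candidate, c("F", "M", "V1", "V2", "X/Y"))
  expect_equal(tab$status, c("kept", "hybrid-flagged", "split", "split", "lumped"))
  expect_equal(tab$lineage[tab$candidate == "F"], "F1c,F2c")
  expect_equal(tab$lineage[tab$candidate != "F"], rep("-", 4))
  expect_equal(tab$n_members, c(6L, 3L, 2L, 2L, 4L))
  # specimens conserved across candidates
  expect_setequal(unlist(tab$members), sc$assignments$specimen)
  expect_equal(sum(tab$n_members), nrow(sc$assignments))
})

test_that("delimit is deterministic and invariant to input row order", {
  sc <- rubric_scenario()
  tab1 <- delimit(sc$tree, sc$assignments, sc$hybrid_calls)
  set.seed(50)
  perm <- sample(nrow(sc$assignments))
  tab2 <- delimit(sc$tree, sc$assignments[perm, ], sc$hybrid_calls)
  expect_identical(tab1, tab2)
})

test_that("two reciprocally monophyletic clusters give two clean candidates", {
  tree <- ape::read.tree(text = "(((a1,a2),a3),((b1,b2),b3));")
  asg <- tibble::tibble(specimen = tree$tip.label,
                        cluster = rep(c("A", "B"), each = 3))
  tab <- delimit(tree, asg)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$lineage == "-"))
  expect_true(all(grepl("monophyletic", tab$evidence[tab$status == "kept"])))
})

test_that("a cluster spanning disjoint monophyletic priors without admixture is unresolved", {
  tree <- ape::read.tree(text = "(((p1,p2),(r1,r2)),(q1,q2));")
  asg <- tibble::tibble(specimen = tree$tip.label,
                        cluster = c("PQ", "PQ", "R", "R", "PQ", "PQ"),
                        prior = c("P", "P", "R", "R", "Q", "Q"))
  tab <- delimit(tree, asg)
  expect_true("unresolved" %in% tab$status)
  expect_equal(tab$status[tab$candidate == "P/Q"], "unresolved")
})

test_that("regression fragment matches the closed-form least squares", {
  # build 4 candidate subtrees with known imbalance on one tree
  tree <- ape::read.tree(text = paste0(
    "((((a1,a2),(a3,a4)),(((b1,b2),b3),b4)),",
    "((((c1,c2),c3),c4),(((d1,d2),d3),d4)));"))
  asg <- tibble::tibble(specimen = tree$tip.label,
                        candidate = rep(c("A", "B", "C", "D"), each = 4))
  qmax <- c(rep(1, 4), rep(c(1, 1, 0.8, 0.6), 3))
  Q <- cbind(qmax, 1 - qmax)
  rownames(Q) <- tree$tip.label
  summ <- clade_admixture_summary(Q, asg)
  res <- imbalance_vs_admixture(tree, summ, asg)
  ref <- lm(i_pda ~ sd_qmax, data = res$table[!is.na(res$table$i_pda), ])
  expect_equal(res$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(res$r2, summary(ref)$r.squared, tolerance = 1e-10)
  expect_equal(res$p, summary(ref)$coefficients[2, 4], tolerance = 1e-10)
})

test_that("regression is flagged undefined when SD(q_max) never varies", {
  tree <- ape::read.tree(text = "(((a1,a2),a3),((b1,b2),b3));")
  asg <- tibble::tibble(specimen = tree$tip.label,
                        candidate = rep(c("A", "B"), each = 3))
  Q <- cbind(rep(1, 6), 0)
  rownames(Q) <- tree$tip.label
  summ <- clade_admixture_summary(Q, asg)
  res <- imbalance_vs_admixture(tree, summ, asg)
  expect_true(res$undefined)
})

test_that("single-specimen candidates are excluded from the regression", {
  Q <- cbind(c(1, 1, 1, 0.6), c(0, 0, 0, 0.4))
  rownames(Q) <- c("a1", "a2", "a3", "solo")
  asg <- tibble::tibble(specimen = rownames(Q),
                        candidate = c("A", "A", "A", "SOLO"))
  summ <- clade_admixture_summary(Q, asg)
  expect_true(summ$excluded[summ$candidate == "SOLO"])
  expect_equal(summ$sd_qmax[summ$candidate == "SOLO"], 0)
})

test_that("gcf_vs_ancestry degenerates gracefully when everyone is pure", {
  sp <- ape::read.tree(text = "(((A,B),C),(D,E));")
  gts <- rep(c(sp), 3)
  Q <- cbind(rep(1, 5), 0)
  rownames(Q) <- sp$tip.label
  res <- gcf_vs_ancestry(sp, gts, Q)
  expect_true(res$envelope$skipped)
  expect_true(is.na(res$pearson$r))
})

test_that("rootward shift: earliest-diverging lone hybrid attains the minimal rank-sum p", {
  # caterpillar candidate, hybrid is the earliest-diverging member
  tree <- ape::read.tree(text = "((((p1:1,p2:1):1,p3:1):1,h1:3):1,out:4);")
  members <- c("h1", "p1", "p2", "p3")
  res <- rootward_shift(tree, members, "h1")
  expect_false(res$skipped)
  # the earliest-diverging labeling attains the minimal one-sided rank-sum p
  # over all single-hybrid labelings of this candidate
  p_all <- vapply(members, function(h) rootward_shift(tree, members, h)$p_rank,
                  numeric(1))
  expect_equal(res$p_rank, min(p_all))
  expect_lt(res$p_rank, 0.26)
  # skip rules
  expect_true(rootward_shift(tree, members, character())$skipped)
  expect_true(rootward_shift(tree, c("p1", "p2", "p3"), "p1")$skipped)
})

test_that("rootward ranks are calibrated under random hybrid labels", {
  set.seed(60)
  tree <- ape::rtree(12)
  members <- tree$tip.label
  ranks <- divergence_ranks(tree, members)$rank
  obs <- replicate(400, {
    hyb <- sample(members, 3)
    suppressWarnings(wilcox.test(ranks[members %in% hyb],
                                 ranks[!members %in% hyb],
                                 alternative = "less")$p.value)
  })
  # permutation-null p-values should not pile up near 0
  expect_lt(mean(obs < 0.05), 0.15)
  expect_gt(mean(obs), 0.35)
})
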