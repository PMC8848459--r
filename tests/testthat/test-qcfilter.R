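test_that("allele trimming applies the strict >80% missing / >5% ambiguity rules", {
  seqs <- c(
    a = paste(c(rep("-", 81), rep("A", 19)), collapse = ""),   # 81% gaps
    b = paste(c(rep("-", 80), rep("A", 20)), collapse = ""),   # exactly 80%
    c = paste(c(rep("R", 6), rep("A", 94)), collapse = ""),    # 6% ambiguity
    d = paste(c(rep("R", 5), rep("A", 95)), collapse = ""),    # exactly 5%
    e = paste(rep("A", 100), collapse = "")
  )
  names(seqs) <- paste0(c("a", "b", "c", "d", "e"), "|1")
  res <- trim_alleles(locus_alignment("L1", seqs))
  expect_setequal(rownames(res$alignment$seqs), c("b|1", "d|1", "e|1"))
  expect_equal(sum(res$report$dropped), 2)
  expect_equal(res$report$retained[res$report$rule == "allele_ambiguity"], 3)
})

test_that("toy locus of 5 haplotypes keeps the 3 hand-counted survivors", {
  # missing fractions .9,.5,.1,0,0; ambiguity 0,.06,0,0,0
  base <- function(miss, amb) {
    paste(c(rep("-", miss), rep("R", amb), rep("A", 100 - miss - amb)),
          collapse = "")
  }
  seqs <- setNames(c(base(90, 0), base(50, 6), base(10, 0), base(0, 0), base(0, 0)),
                   paste0("h", 1:5, "|1"))
  res <- trim_alleles(locus_alignment("L1", seqs))
  expect_equal(nrow(res$alignment$seqs), 3)
  expect_setequal(rownames(res$alignment$seqs), c("h3|1", "h4|1", "h5|1"))
})

test_that("individual dropping is strict at 50% and errors when nobody survives", {
  G <- rbind(w = c(NA, NA, NA, 0L, 0L),   # 60%
             x = c(NA, NA, 0L, 0L, 0L),   # 40%
             y = c(NA, 0L, 0L, 0L, 0L),   # 20%
             z = c(0L, 0L, 0L, 0L, 0L))   # 0%
  # 4-site version for exact 50% boundary
  G2 <- rbind(p = c(NA, NA, 0L, 0L), q = c(NA, NA, NA, 0L))
  res <- drop_individuals(geno_matrix(G))
  expect_setequal(res$genotypes$specimens, c("x", "y", "z"))
  res2 <- drop_individuals(geno_matrix(G2))
  expect_equal(res2$genotypes$specimens, "p")   # exactly 50% retained
  expect_error(drop_individuals(geno_matrix(G2[2, , drop = FALSE])),
               "all individuals")
})

test_that("SNP extraction keeps exactly the hand-counted clean sites", {
  # 6 diploid specimens, 8 sites: 2 invariant, 2 singletons, 1 high-missing,
  # 3 clean biallelic
  site <- function(...) unlist(list(...))
  haps <- lapply(1:6, function(i) {
    h <- character(2)
    for (k in 1:2) {
      s1 <- "A"; s2 <- "C"                       # invariant
      s3 <- if (i == 1 && k == 1) "T" else "A"   # haplotype singleton
      s4 <- if (i == 6 && k == 2) "G" else "C"   # haplotype singleton
      s5 <- if (i <= 2) "N" else if (i <= 4) "A" else "T"  # 2/6 missing = 33%
      s6 <- if (i <= 3) "A" else "G"
      s7 <- if (i %% 2 == 0) "C" else "T"
      s8 <- if (i <= 2) "G" else "T"
      h[k] <- paste(c(s1, s2, s3, s4, s5, s6, s7, s8), collapse = "")
    }
    h
  })
  names(haps) <- paste0("sp", 1:6)
  aln <- aln_from_haps("L1", haps)
  res <- extract_snps(list(aln), paste0("sp", 1:6))
  expect_equal(ncol(res$genotypes$G), 3)
  expect_setequal(res$genotypes$sites$pos, c(6, 7, 8))
  rep <- res$report
  expect_equal(rep$dropped[rep$rule == "site_invariant"], 2)
  expect_equal(rep$dropped[rep$rule == "site_singleton"], 2)
  expect_equal(rep$dropped[rep$rule == "site_high_missing"], 1)
})

test_that("filters are idempotent and permutation-invariant", {
  set.seed(42)
  gm <- two_pop_geno(n_per = 5, n_sites = 60)
  gm$G[sample(length(gm$G), 80)] <- NA_integer_
  once <- drop_individuals(gm, max_missing = 0.25)$genotypes
  twice <- drop_individuals(once, max_missing = 0.25)$genotypes
  expect_identical(once$G, twice$G)
  perm <- sample(nrow(gm$G))
  gm_p <- geno_matrix(gm$G[perm, ], gm$sites, gm$specimens[perm])
  res_p <- drop_individuals(gm_p, max_missing = 0.25)$genotypes
  expect_setequal(res_p$specimens, once$specimens)
  expect_identical(res_p$G[order(res_p$specimens), ],
                   once$G[order(once$specimens), ])
})

test_that("filter reports reconcile with matrix dimensions", {
  gm <- two_pop_geno(n_per = 4, n_sites = 40, seed = 3)
  gm$G[1, 1:30] <- NA_integer_
  res <- drop_individuals(gm, max_missing = 0.5)
  expect_equal(res$report$dropped + res$report$retained, nrow(gm$G))
  expect_equal(nrow(res$genotypes$G), res$report$retained)
})

test_that("PCA separates fixed populations and duplicates give identical scores", {
  gm <- two_pop_geno(n_per = 8, n_sites = 200, seed = 7)
  p <- pca_genotypes(gm, n_axes = 2)
  pc1 <- p$scores$PC1
  grp_a <- pc1[1:8]; grp_b <- pc1[9:16]
  expect_true(max(grp_a) < min(grp_b) || min(grp_a) > max(grp_b))
  # duplicated specimen rows -> identical scores
  G2 <- rbind(gm$G, dup = gm$G[1, ])
  gm2 <- geno_matrix(G2, gm$sites, c(gm$specimens, "dup"))
  p2 <- pca_genotypes(gm2, n_axes = 2)
  expect_equal(p2$scores$PC1[17], p2$scores$PC1[1], tolerance = 1e-10)
})

test_that("single-population PCA shows no dominant axis beyond the permutation null", {
  set.seed(11)
  P <- matrix(runif(300, 0.2, 0.8), 1)
  Q <- matrix(1, 24, 1)
  rownames(Q) <- paste0("i", 1:24)
  gm <- simulate_genotypes(P, Q, seed = 12)
  top_share <- pca_genotypes(gm, n_axes = 1)$var_explained[1]
  null_share <- replicate(30, {
    Gp <- apply(gm$G, 2, sample)
    pca_genotypes(geno_matrix(Gp, gm$sites, gm$specimens), 1)$var_explained[1]
  })
  expect_lt(top_share, mean(null_share) + 3 * sd(null_share))
})
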