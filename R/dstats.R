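#' Population allele-frequency table polarized by an outgroup
#'
#' Collapses a genotype matrix to per-population derived-allele counts and
#' frequencies at biallelic sites, polarized so that the outgroup's major
#' allele is the ancestral state. Sites where the outgroup is polymorphic
#' above `max_outgroup_maf` are dropped (polarity unreliable), as are sites
#' monomorphic across all populations. Sites keep their locus of origin as a
#' jackknife block.
#'
#' @param gm a [geno_matrix()].
#' @param population_map tibble with columns `specimen`, `population`.
#' @param outgroup name of the outgroup population (must be in the map).
#' @param max_outgroup_maf sites with outgroup minor-allele frequency above
#'   this are dropped; default 0.1.
#' @return An `allele_freq_table`: list with matrices `d` (derived counts) and
#'   `n` (called haplotype counts), both populations x sites, a `block`
#'   integer per site, `block_labels`, `pops`, and `outgroup`.
#' @export
allele_freqs <- function(gm, population_map, outgroup, max_outgroup_maf = 0.1) {
  stopifnot(inherits(gm, "geno_matrix"))
  population_map <- as_tibble(population_map)
  if (!outgroup %in% population_map$population) {
    abort(sprintf("outgroup population '%s' not in population map", outgroup))
  }
  pm <- population_map %>% filter(.data$specimen %in% gm$specimens)
  pops <- unique(pm$population)
  d <- matrix(0L, length(pops), ncol(gm$G), dimnames = list(pops, NULL))
  nh <- d
  for (i in seq_along(pops)) {
    rows <- gm$G[pm$specimen[pm$population == pops[i]], , drop = FALSE]
    d[i, ] <- colSums(rows, na.rm = TRUE)
    nh[i, ] <- 2L * colSums(!is.na(rows))
  }
  called <- nh > 0
  if (any(rowSums(called) == 0)) {
    abort(sprintf("population(s) with zero called haplotypes at every site: %s",
                  paste(pops[rowSums(called) == 0], collapse = ", ")))
  }
  og <- match(outgroup, pops)
  p_og <- ifelse(nh[og, ] > 0, d[og, ] / nh[og, ], NA_real_)
  # polarize: outgroup major allele is ancestral
  flip <- !is.na(p_og) & p_og > 0.5
  d[, flip] <- nh[, flip] - d[, flip]
  p_og <- ifelse(nh[og, ] > 0, d[og, ] / nh[og, ], NA_real_)
  tot_d <- colSums(d); tot_n <- colSums(nh)
  keep <- !is.na(p_og) & p_og <= max_outgroup_maf &
    tot_d > 0L & tot_d < tot_n
  block_f <- factor(gm$sites$locus, levels = unique(gm$sites$locus))
  structure(list(
    d = d[, keep, drop = FALSE], n = nh[, keep, drop = FALSE],
    block = as.integer(block_f)[keep],
    block_labels = levels(block_f),
    pops = pops, outgroup = outgroup
  ), class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("<allele_freq_table> %d populations x %d sites, %d blocks, outgroup '%s'\n",
              length(x$pops), ncol(x$d), length(unique(x$block)), x$outgroup))
  invisible(x)
}

freq_of <- function(ft, pop) {
  i <- match(pop, ft$pops)
  if (is.na(i)) abort(sprintf("population '%s' not in frequency table", pop))
  ifelse(ft$n[i, ] > 0, ft$d[i, ] / ft$n[i, ], NA_real_)
}

#' Block-jackknife standard error from delete-one estimates
#'
#' Delete-one block jackknife: given the statistic recomputed with each block
#' left out, `SE = sqrt((m-1)/m * sum((theta_j - mean)^2))`, with a two-sided
#' normal p-value for `estimate / SE`.
#'
#' @param deleted numeric vector of delete-one-block estimates.
#' @param estimate the full-data estimate (defaults to the mean of `deleted`).
#' @return One-row tibble: `estimate`, `se`, `z`, `p`, `n_blocks`,
#'   `degenerate` (TRUE when every delete-one estimate is identical, SE = 0).
#' @export
jackknife_se <- function(deleted, estimate = mean(deleted)) {
  m <- length(deleted)
  if (m < 2) abort("jackknife requires at least 2 blocks")
  se <- sqrt((m - 1) / m * sum((deleted - mean(deleted))^2))
  degenerate <- se == 0
  z <- if (degenerate) NA_real_ else estimate / se
  tibble(estimate = estimate, se = se, z = z,
         p = if (degenerate) NA_real_ else 2 * pnorm(-abs(z)),
         n_blocks = m, degenerate = degenerate)
}

# per-site ABBA and BABA weights from four frequency vectors
abba_baba <- function(p1, p2, p3, p4) {
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4))
}

#' Order a trio consistently with the species tree
#'
#' Arranges three populations so that (P1, P2) is the pair with the most
#' recent common ancestor and P3 the trio's tree-outgroup — the arrangement
#' Patterson's D assumes. Testing tree-inconsistent trios confounds topology
#' with gene flow.
#'
#' @param tree rooted `phylo` containing the three populations as tips.
#' @param trio character vector of three tip labels.
#' @return The trio reordered as `c(P1, P2, P3)`.
#' @export
tree_consistent_trio <- function(tree, trio) {
  stopifnot(length(trio) == 3, all(trio %in% tree$tip.label))
  depth <- ape::node.depth.edgelength(tree)
  pairs <- combn(trio, 2, simplify = FALSE)
  md <- vapply(pairs, function(p) depth[ape::getMRCA(tree, p)], numeric(1))
  sisters <- pairs[[which.max(md)]]
  c(sisters, setdiff(trio, sisters))
}

#' Patterson's D (ABBA-BABA) with block-jackknife significance
#'
#' Computes the frequency-based site-pattern asymmetry statistic
#' `D = (ABBA - BABA) / (ABBA + BABA)` for a trio (P1, P2, P3) against the
#' table's outgroup, with `ABBA = sum (1-p1) p2 p3 (1-p4)` over polarized
#' sites. Significance is by delete-one block jackknife over loci. By the
#' usual convention P1 and P2 are oriented so that D >= 0; set
#' `orient = FALSE` to keep the input orientation.
#'
#' @param freqs an [allele_freqs()] table.
#' @param trio character vector `c(P1, P2, P3)`.
#' @param orient orient P1/P2 so D >= 0 (default TRUE); the original order is
#'   reported in `swapped`.
#' @return One-row tibble: `p1`, `p2`, `p3`, `outgroup`, `abba`, `baba`, `d`,
#'   `se`, `z`, `p`, `n_blocks`, `n_sites`, `swapped`, `undefined`.
#' @export
patterson_d <- function(freqs, trio, orient = TRUE) {
  stopifnot(inherits(freqs, "allele_freq_table"), length(trio) == 3)
  f1 <- freq_of(freqs, trio[1]); f2 <- freq_of(freqs, trio[2])
  f3 <- freq_of(freqs, trio[3]); f4 <- freq_of(freqs, freqs$outgroup)
  ok <- complete.cases(cbind(f1, f2, f3, f4))
  w <- abba_baba(f1[ok], f2[ok], f3[ok], f4[ok])
  blk <- freqs$block[ok]
  A <- sum(w$abba); B <- sum(w$baba)
  swapped <- FALSE
  if (orient && (A - B) < 0) {
    tmp <- trio[1]; trio[1] <- trio[2]; trio[2] <- tmp
    w <- list(abba = w$baba, baba = w$abba)
    A <- sum(w$abba); B <- sum(w$baba)
    swapped <- TRUE
  }
  if (A + B == 0) {
    return(tibble(p1 = trio[1], p2 = trio[2], p3 = trio[3],
                  outgroup = freqs$outgroup, abba = A, baba = B,
                  d = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                  n_blocks = length(unique(blk)), n_sites = sum(ok),
                  swapped = swapped, undefined = TRUE))
  }
  d_full <- (A - B) / (A + B)
  a_b <- rowsum(w$abba, blk); b_b <- rowsum(w$baba, blk)
  m <- nrow(a_b)
  if (m < 2) abort("patterson_d requires at least 2 jackknife blocks")
  a_del <- A - a_b[, 1]; b_del <- B - b_b[, 1]
  d_del <- ifelse(a_del + b_del == 0, 0, (a_del - b_del) / (a_del + b_del))
  jk <- jackknife_se(d_del, d_full)
  tibble(p1 = trio[1], p2 = trio[2], p3 = trio[3], outgroup = freqs$outgroup,
         abba = A, baba = B, d = d_full, se = jk$se, z = jk$z, p = jk$p,
         n_blocks = m, n_sites = sum(ok), swapped = swapped, undefined = FALSE)
}

# Per-site numerator/denominator block sums for the f4-ratio, with C's
# haplotypes randomly half-split per site (removes the p3^2 bias of reusing
# one sample as both the test and reference copy of the donor).
f4_blocks <- function(freqs, A, B, C, O, seed = 1L) {
  pA <- freq_of(freqs, A); pB <- freq_of(freqs, B); pO <- freq_of(freqs, O)
  ci <- match(C, freqs$pops)
  if (is.na(ci)) abort(sprintf("population '%s' not in frequency table", C))
  dC <- freqs$d[ci, ]; nC <- freqs$n[ci, ]
  ok <- !is.na(pA) & !is.na(pB) & !is.na(pO) & nC >= 2
  dC <- dC[ok]; nC <- nC[ok]
  half <- nC %/% 2L
  # derived alleles landing in the first half: hypergeometric draw
  d_a <- withr_seed(seed, stats::rhyper(length(dC), dC, nC - dC, half))
  p_ca <- d_a / half
  p_cb <- (dC - d_a) / (nC - half)
  w <- (1 - pO[ok]) * p_ca
  num <- w * (pB[ok] - pA[ok])
  den <- w * (p_cb - pA[ok])
  blk <- freqs$block[ok]
  list(num = rowsum(num, blk)[, 1], den = rowsum(den, blk)[, 1],
       n_sites = sum(ok))
}

#' f4-ratio admixture-fraction estimate
#'
#' Estimates the admixture proportion contributed by donor lineage C to the
#' admixed population B (with A the unadmixed sister of B and O the outgroup)
#' as `f = S(A,B,Ca,O) / S(A,Cb,Ca,O)`, where S is the summed ABBA-BABA
#' difference and C's haplotypes are split per site into two random halves
#' Ca/Cb. The estimate is clamped to `[0, 1]`; the raw value and a
#' block-jackknife SE are reported alongside.
#'
#' @param freqs an [allele_freqs()] table.
#' @param A,B,C population names: A = sister of recipient, B = recipient,
#'   C = donor.
#' @param seed integer seed for the per-site haplotype split.
#' @return One-row tibble: `a`, `b`, `c`, `outgroup`, `f4_ratio` (clamped),
#'   `f4_ratio_raw`, `se`, `z`, `p`, `n_blocks`, `n_sites`, `undefined`.
#' @export
f4_ratio <- function(freqs, A, B, C, seed = 1L) {
  fb <- f4_blocks(freqs, A, B, C, freqs$outgroup, seed)
  S <- sum(fb$num); T_ <- sum(fb$den)
  if (T_ <= 0) {
    return(tibble(a = A, b = B, c = C, outgroup = freqs$outgroup,
                  f4_ratio = NA_real_, f4_ratio_raw = NA_real_,
                  se = NA_real_, z = NA_real_, p = NA_real_,
                  n_blocks = length(fb$num), n_sites = fb$n_sites,
                  undefined = TRUE))
  }
  f_raw <- S / T_
  den_del <- T_ - fb$den
  f_del <- ifelse(den_del <= 0, f_raw, (S - fb$num) / den_del)
  jk <- jackknife_se(f_del, f_raw)
  tibble(a = A, b = B, c = C, outgroup = freqs$outgroup,
         f4_ratio = min(max(f_raw, 0), 1), f4_ratio_raw = f_raw,
         se = jk$se, z = jk$z, p = jk$p,
         n_blocks = length(fb$num), n_sites = fb$n_sites, undefined = FALSE)
}
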