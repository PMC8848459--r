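# shared fixture builders; everything is generated in code at test time

# haplotype alignment from per-specimen genotype strings: a list like
# list(sp1 = c("ACGT", "ACGT")) -> locus_alignment with |1/|2 rows
aln_from_haps <- function(locus, haps) {
  seqs <- unlist(lapply(names(haps), function(sp) {
    setNames(haps[[sp]], paste0(sp, "|", seq_along(haps[[sp]])))
  }))
  locus_alignment(locus, seqs)
}

# the classic 4-site ABBA/BABA hand table: 3 ABBA sites, 1 BABA site,
# one locus per site so every site is its own jackknife block
hand_d_table <- function() {
  G <- rbind(P1 = c(0L, 0L, 0L, 2L), P2 = c(2L, 2L, 2L, 0L),
             P3 = c(2L, 2L, 2L, 2L), OG = c(0L, 0L, 0L, 0L))
  gm <- geno_matrix(G, sites = tibble::tibble(
    site = paste0("s", 1:4), locus = paste0("L", 1:4), pos = 1:4))
  allele_freqs(gm, tibble::tibble(specimen = rownames(G),
                                  population = rownames(G)), "OG")
}

# two fixed, fully diverged populations plus optional F1 hybrids
two_pop_geno <- function(n_per = 10, n_sites = 500, n_f1 = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per + n_f1
  p <- cbind(rep(1, n_sites), rep(0, n_sites))  # sites x pops? build pops x sites
  P <- rbind(A = rep(1, n_sites), B = rep(0, n_sites))
  Q <- rbind(matrix(rep(c(1, 0), each = n_per), ncol = 2),
             matrix(rep(c(0, 1), each = n_per), ncol = 2, byrow = FALSE))
  Q <- rbind(cbind(rep(1, n_per), 0), cbind(rep(0, n_per), 1))
  if (n_f1 > 0) Q <- rbind(Q, matrix(0.5, n_f1, 2))
  rownames(Q) <- c(paste0("a", seq_len(n_per)), paste0("b", seq_len(n_per)),
                   if (n_f1) paste0("h", seq_len(n_f1)))
  simulate_genotypes(P, Q, n_loci = 5, seed = seed)
}

# brute-force Colless oracle: plain recursion from the definition
colless_oracle <- function(tree) {
  n <- length(tree$tip.label)
  count_tips <- function(v) {
    if (v <= n) return(1L)
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    sum(vapply(kids, count_tips, integer(1)))
  }
  total <- 0L
  for (v in (n + 1):(n + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    total <- total + abs(count_tips(kids[1]) - count_tips(kids[2]))
  }
  total
}

# the scripted synthetic rubric scenario: one lump, one split, one
# lineage and one hybrid-cluster case on a single specimen tree
rubric_scenario <- function() {
  tree <- ape::read.tree(text = paste0(
    "((((x1,y1),(x2,y2)),((v1,v2),(v3,v4))),",
    "(((f1,f4),(f2,(f5,(f3,f6)))),(m1,(m2,m3))));"))
  assignments <- tibble::tibble(
    specimen = c("x1", "x2", "y1", "y2",
                 "v1", "v2", "v3", "v4",
                 "f1", "f2", "f3", "f4", "f5", "f6",
                 "m1", "m2", "m3"),
    cluster = c(rep("clXY", 4),
                rep(c("V1", "V2"), each = 2),
                rep(c("F1c", "F2c"), each = 3),
                rep("M", 3)),
    prior = c("X", "X", "Y", "Y",
              rep("V", 4), rep("F", 6), rep("M", 3)),
    geo_distinct = TRUE)
  assignments$cluster[assignments$specimen %in% c("f1", "f2", "f3")] <- "F1c"
  assignments$cluster[assignments$specimen %in% c("f4", "f5", "f6")] <- "F2c"
  hybrid_calls <- tibble::tibble(
    specimen = assignments$specimen,
    class = ifelse(assignments$specimen %in% c("f3", "f5"), "hybrid", "pure"),
    q_max = ifelse(assignments$specimen %in% paste0("m", 1:3), 0.4,
                   ifelse(assignments$specimen %in% c("f3", "f5"), 0.65, 0.97)))
  list(tree = tree, assignments = assignments, hybrid_calls = hybrid_calls)
}
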