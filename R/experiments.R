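#' Simulated admixture-distortion experiment
#'
#' Generates one replicate of the end-to-end experiment linking within-clade
#' admixture to phylogenetic distortion. Each candidate species is a clade of
#' six phylogeographically structured subpopulations (one diploid each), so
#' that every pure specimen's terminal branch reflects a genuine split with
#' gene-tree support; every other candidate is seeded with hybrid members
#' (one F1 and one clinal individual, partnered with the cherry-neighbour
#' candidate). Gene trees are simulated under the multispecies coalescent,
#' sequences under Jukes-Cantor, the concatenated tree by neighbor joining,
#' and per-specimen terminal gCF against the true gene trees pruned to one
#' random haplotype per specimen per locus (so hybrid mosaicism is visible).
#'
#' @param seed integer seed for the replicate.
#' @param n_candidates number of candidate species (multiple of 4).
#' @param n_hybrids hybrid members seeded per odd-numbered candidate
#'   (default 2 of 6 members, emulating clades with roughly a third of
#'   specimens admixed).
#' @param n_loci,locus_length,rate sequence-simulation knobs.
#' @return List with `regression` ([imbalance_vs_admixture()] result),
#'   `gcf` ([gcf_vs_ancestry()] result), `rootward` (per hybrid-candidate
#'   [rootward_shift()] rows), `gcf_by_class` (median terminal gCF of hybrid
#'   vs pure members of hybrid candidates), `tree`, `summaries`, `hybrids`.
#' @export
distortion_experiment <- function(seed = 1L, n_candidates = 24,
                                  n_hybrids = 2, n_loci = 30,
                                  locus_length = 500, rate = 0.01) {
  stopifnot(n_candidates %% 4 == 0)
  cand_ids <- sprintf("c%02d", seq_len(n_candidates))
  cand_txt <- vapply(cand_ids, function(cid) {
    s <- sprintf("%ss%d", cid, 1:6)
    sprintf("(((%s:0.5,%s:0.5):0.5,%s:1):1,((%s:0.6,%s:0.6):0.6,%s:1.2):0.8)",
            s[1], s[2], s[3], s[4], s[5], s[6])
  }, character(1))
  # cherries of candidates at depth 3, quartets at 4, then a ladder
  pair_txt <- vapply(seq_len(n_candidates / 2), function(i) {
    sprintf("(%s:1,%s:1)", cand_txt[2 * i - 1], cand_txt[2 * i])
  }, character(1))
  quad_txt <- vapply(seq_len(n_candidates / 4), function(i) {
    sprintf("(%s:1,%s:1)", pair_txt[2 * i - 1], pair_txt[2 * i])
  }, character(1))
  txt <- quad_txt[length(quad_txt)]
  for (i in rev(seq_len(length(quad_txt) - 1))) {
    txt <- sprintf("(%s:%d,%s:1)", quad_txt[i], length(quad_txt) - i, txt)
  }
  tree <- ape::read.tree(text = paste0(txt, ";"))
  pops <- tree$tip.label
  model <- population_model(pops = pops, tree = tree)
  withr_seed(seed, {
    samples <- tibble(specimen = paste0(pops, "_i1"), population = pops,
                      candidate = substr(pops, 1, 3))
    hybrid_cands <- cand_ids[seq(1, n_candidates, by = 2)]
    # clinal first-parent fractions kept <= 0.75 so every seeded individual
    # clears the >20% secondary-ancestry hybrid definition
    clinal_q <- rep(c(0.6, 0.65, 0.7, 0.75), length.out = length(hybrid_cands))
    hybrids <- purrr::map_dfr(seq_along(hybrid_cands), function(i) {
      cid <- hybrid_cands[i]
      partner <- cand_ids[match(cid, cand_ids) + 1L]
      hs <- sprintf("%ss%d", cid, c(6, 3))[seq_len(n_hybrids)]
      tibble(specimen = paste0(hs, "_i1"), pop_a = hs,
             pop_b = sub(cid, partner, hs, fixed = TRUE),
             class = c("F1", "clinal")[seq_len(n_hybrids)],
             q_a = c(0.5, clinal_q[i])[seq_len(n_hybrids)])
    })
    pure_samples <- samples %>%
      select("specimen", "population") %>%
      filter(!.data$specimen %in% hybrids$specimen)
    gene_trees <- simulate_gene_trees(model, pure_samples, n_loci,
                                      seed = sample.int(2^30, 1),
                                      hybrids = hybrids)
    alignments <- purrr::map2(gene_trees, seq_len(n_loci), function(gt, l) {
      evolve_sequences(gt, locus_length, rate, seed = sample.int(2^30, 1),
                       locus = sprintf("locus%03d", l))
    })
    gm <- genotypes_from_alignments(alignments)
    concat_tree <- nj_tree(gm)
    concat_tree <- ape::root(concat_tree,
                             outgroup = paste0(pops[1], "_i1"),
                             resolve.root = TRUE)
    spec_trees <- lapply(gene_trees, function(gt) {
      specs <- unique(sub("\\|[12]$", "", gt$tip.label))
      pick <- paste0(specs, "|", sample(1:2, length(specs), replace = TRUE))
      pick <- intersect(pick, gt$tip.label)
      st <- ape::keep.tip(gt, pick)
      st$tip.label <- sub("\\|[12]$", "", st$tip.label)
      st
    })
    Q_true <- matrix(0, nrow(samples), n_candidates,
                     dimnames = list(samples$specimen, cand_ids))
    Q_true[cbind(seq_len(nrow(samples)), match(samples$candidate, cand_ids))] <- 1
    for (i in seq_len(nrow(hybrids))) {
      h <- hybrids[i, ]
      Q_true[h$specimen, ] <- 0
      Q_true[h$specimen, substr(h$pop_a, 1, 3)] <- h$q_a
      Q_true[h$specimen, substr(h$pop_b, 1, 3)] <- 1 - h$q_a
    }
    assignments <- samples %>% select("specimen", "candidate")
    summaries <- clade_admixture_summary(Q_true, assignments)
    regression <- imbalance_vs_admixture(concat_tree, summaries, assignments)
    gcf <- gcf_vs_ancestry(concat_tree, spec_trees, Q_true)
    rootward <- purrr::map_dfr(hybrid_cands, function(cid) {
      members <- samples$specimen[samples$candidate == cid]
      rootward_shift(concat_tree, members,
                     intersect(members, hybrids$specimen)) %>%
        mutate(candidate = cid, .before = 1)
    })
    # pooled across candidates: within-candidate ranks, hybrids vs pure
    pooled <- purrr::map_dfr(hybrid_cands, function(cid) {
      members <- samples$specimen[samples$candidate == cid]
      divergence_ranks(concat_tree, members) %>%
        mutate(class = ifelse(.data$specimen %in% hybrids$specimen,
                              "hybrid", "pure"))
    })
    pooled_rank_p <- suppressWarnings(wilcox.test(
      pooled$rank[pooled$class == "hybrid"],
      pooled$rank[pooled$class == "pure"], alternative = "less"))$p.value
    hyb_cand_members <- samples$specimen[samples$candidate %in% hybrid_cands]
    tg <- gcf$table %>% filter(.data$specimen %in% hyb_cand_members,
                               !is.na(.data$gcf))
    gcf_by_class <- tg %>%
      mutate(class = ifelse(.data$specimen %in% hybrids$specimen,
                            "hybrid", "pure")) %>%
      group_by(.data$class) %>%
      summarise(median_gcf = median(.data$gcf), n = n(), .groups = "drop")
    list(regression = regression, gcf = gcf, rootward = rootward,
         pooled_rank_p = pooled_rank_p, gcf_by_class = gcf_by_class,
         tree = concat_tree, summaries = summaries, hybrids = hybrids)
  })
}
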