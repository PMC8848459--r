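#' Simulate gene trees under the multispecies coalescent with pulse admixture
#'
#' Structured coalescent on the model's population tree: within every
#' population branch, lineages coalesce with exponential waiting times at
#' rate `choose(k, 2)` (time in coalescent units, pairwise rate 1); at each
#' population split (backwards in time) the daughter branches' lineages merge;
#' at a pulse event `(time, donor, recipient, a)` every lineage currently in
#' the recipient branch is rerouted to the donor's branch with probability
#' `a`. One rooted gene tree per locus, deterministic under a fixed seed.
#'
#' Hybrid individuals are simulated by reassigning their haplotypes' source
#' populations per locus: an F1 draws one haplotype from each parent, a BC1
#' draws the second haplotype from either parent with probability 1/2, and a
#' clinal individual draws each haplotype from the first parent with its
#' target fraction `q_a`.
#'
#' @param model a [population_model()] with a tree.
#' @param samples tibble (`specimen`, `population`) of diploid individuals;
#'   haplotypes are labeled `"<specimen>|1"` / `"<specimen>|2"`.
#' @param n_loci number of independent gene trees.
#' @param seed integer seed.
#' @param hybrids optional hybrid spec tibble (see [sim_config()]); hybrid
#'   specimens may be absent from `samples`.
#' @return A `multiPhylo` list of rooted gene trees with haplotype tip labels.
#' @export
simulate_gene_trees <- function(model, samples, n_loci, seed = 1L,
                                hybrids = NULL) {
  stopifnot(inherits(model, "population_model"))
  tree <- model$tree
  if (is.null(tree)) abort("gene-tree simulation needs a population tree")
  samples <- as_tibble(samples)
  bad <- setdiff(samples$population, tree$tip.label)
  if (length(bad)) {
    abort(sprintf("samples reference populations absent from the model: %s",
                  paste(bad, collapse = ", ")))
  }
  if (!is.null(hybrids)) {
    hybrids <- as_tibble(hybrids)
    if (!"q_a" %in% names(hybrids)) hybrids$q_a <- 0.5
    samples <- samples %>% filter(!.data$specimen %in% hybrids$specimen)
  }
  times <- node_times(tree)
  withr_seed(seed, {
    trees <- vector("list", n_loci)
    for (l in seq_len(n_loci)) {
      hap <- tibble(
        hap_id = c(paste0(samples$specimen, "|1"), paste0(samples$specimen, "|2")),
        population = rep(samples$population, 2)
      )
      if (!is.null(hybrids) && nrow(hybrids)) {
        hy <- purrr::map_dfr(seq_len(nrow(hybrids)), function(i) {
          h <- hybrids[i, ]
          src <- switch(h$class,
            F1 = c(h$pop_a, h$pop_b),
            BC1 = c(h$pop_a, if (runif(1) < 0.5) h$pop_a else h$pop_b),
            clinal = ifelse(runif(2) < h$q_a, h$pop_a, h$pop_b))
          tibble(hap_id = paste0(h$specimen, "|", 1:2), population = src)
        })
        hap <- bind_rows(hap, hy)
      }
      trees[[l]] <- msc_one_locus(tree, times, hap, model$pulses)
    }
    class(trees) <- "multiPhylo"
    trees
  })
}

msc_one_locus <- function(tree, times, hap, pulses) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  n_nodes <- ntip + tree$Nnode
  # lineage state: occupied population branch, subtree string, node height
  lin_branch <- match(hap$population, tree$tip.label)
  lin_str <- hap$hap_id
  lin_h <- numeric(nrow(hap))
  events <- tibble(time = times[(ntip + 1L):n_nodes],
                   type = "merge", node = (ntip + 1L):n_nodes,
                   donor_b = NA_integer_, prop = NA_real_)
  if (nrow(pulses)) {
    events <- bind_rows(events, purrr::map_dfr(seq_len(nrow(pulses)), function(i) {
      tibble(time = pulses$time[i], type = "pulse",
             node = branch_node(tree, pulses$recipient[i]),
             donor_b = branch_at_time(tree, times, pulses$donor[i],
                                      pulses$time[i]),
             prop = pulses$prop[i])
    }))
  }
  events <- events %>% arrange(.data$time, .data$type != "pulse")
  coalesce_in <- function(t0, t1) {
    for (b in unique(lin_branch)) {
      idx <- which(lin_branch == b)
      tt <- t0
      while (length(idx) >= 2) {
        w <- rexp(1, length(idx) * (length(idx) - 1) / 2)
        if (tt + w >= t1) break
        tt <- tt + w
        pair <- sample(idx, 2)
        i <- pair[1]; j <- pair[2]
        lin_str[i] <<- sprintf("(%s:%.9g,%s:%.9g)", lin_str[i], tt - lin_h[i],
                               lin_str[j], tt - lin_h[j])
        lin_h[i] <<- tt
        lin_branch[j] <<- NA_integer_
        idx <- setdiff(idx, j)
      }
    }
  }
  t_cur <- 0
  for (e in seq_len(nrow(events))) {
    te <- events$time[e]
    coalesce_in(t_cur, te)
    if (events$type[e] == "merge") {
      v <- events$node[e]
      kids <- tree$edge[tree$edge[, 1] == v, 2]
      lin_branch[lin_branch %in% kids] <- v
    } else {
      in_rec <- which(!is.na(lin_branch) & lin_branch == events$node[e])
      move <- in_rec[runif(length(in_rec)) < events$prop[e]]
      lin_branch[move] <- events$donor_b[e]
    }
    t_cur <- te
  }
  # above the root: coalesce to completion
  alive <- which(!is.na(lin_branch))
  tt <- t_cur
  while (length(alive) >= 2) {
    k <- length(alive)
    tt <- tt + rexp(1, k * (k - 1) / 2)
    pair <- sample(alive, 2)
    i <- pair[1]; j <- pair[2]
    lin_str[i] <- sprintf("(%s:%.9g,%s:%.9g)", lin_str[i], tt - lin_h[i],
                          lin_str[j], tt - lin_h[j])
    lin_h[i] <- tt
    lin_branch[j] <- NA_integer_
    alive <- setdiff(alive, j)
  }
  ape::read.tree(text = paste0(lin_str[alive], ";"))
}
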