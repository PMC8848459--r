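#' Terminal gCF versus maximum individual ancestry
#'
#' Tests the constraining ("triangular") relationship between how admixed a
#' specimen is and how well gene trees support its placement: highly admixed
#' specimens cannot, by definition, be supported by high terminal gCF. The
#' envelope test bins `q_max` into ten equal-width bins, takes the maximum
#' gCF per occupied bin, and computes a one-sided Spearman correlation of the
#' bin maxima against the bin centers; the plain Pearson correlation is also
#' reported. Sister-pair specimens share a terminal branch and therefore
#' duplicate gCF values; that is expected.
#'
#' @param tree specimen-level `phylo`.
#' @param gene_trees gene trees for [terminal_gcf()].
#' @param Q ancestry matrix (specimens x K, rownames = specimens) or an
#'   `snmf_fit`.
#' @return Object of class `gcf_ancestry`: `table` (specimen, q_max, gcf),
#'   `envelope` (rho, p, skipped, reason), `pearson` (r, p).
#' @export
gcf_vs_ancestry <- function(tree, gene_trees, Q) {
  if (inherits(Q, "snmf_fit")) Q <- Q$Q
  Q <- as.matrix(Q)
  qmax <- apply(Q, 1, max)
  tg <- terminal_gcf(tree, gene_trees,
                     specimens = intersect(rownames(Q), tree$tip.label))
  tab <- tg %>%
    mutate(q_max = qmax[.data$specimen]) %>%
    select("specimen", "q_max", "gcf", "undefined")
  usable <- tab %>% filter(!.data$undefined, !is.na(.data$gcf))
  envelope <- list(rho = NA_real_, p = NA_real_, skipped = TRUE, reason = "")
  pearson <- list(r = NA_real_, p = NA_real_)
  if (nrow(usable) < 10) {
    envelope$reason <- "fewer than 10 specimens with defined terminal gCF"
  } else if (sd(usable$q_max) == 0) {
    envelope$reason <- "degenerate: all specimens share the same q_max"
  } else {
    bins <- cut(usable$q_max, breaks = seq(0, 1, 0.1), include.lowest = TRUE)
    centers <- seq(0.05, 0.95, 0.1)
    bin_max <- tapply(usable$gcf, bins, max)
    occupied <- !is.na(bin_max)
    if (sum(occupied) >= 3) {
      ct <- suppressWarnings(
        cor.test(centers[occupied], bin_max[occupied], method = "spearman",
                 alternative = "greater"))
      envelope <- list(rho = unname(ct$estimate), p = ct$p.value,
                       skipped = FALSE, reason = "")
    } else {
      envelope$reason <- "fewer than 3 occupied ancestry bins"
    }
    pt <- suppressWarnings(cor.test(usable$q_max, usable$gcf))
    pearson <- list(r = unname(pt$estimate), p = pt$p.value)
  }
  structure(list(table = tab, envelope = envelope, pearson = pearson),
            class = "gcf_ancestry")
}

#' @export
print.gcf_ancestry <- function(x, ...) {
  cat(sprintf("<gcf_ancestry> %d specimens; envelope rho = %.3f (p = %.3g)%s\n",
              nrow(x$table), x$envelope$rho, x$envelope$p,
              if (x$envelope$skipped) sprintf(" [skipped: %s]", x$envelope$reason) else ""))
  invisible(x)
}

#' @export
autoplot.gcf_ancestry <- function(object, ...) {
  ggplot2::ggplot(object$table %>% filter(!.data$undefined),
                  ggplot2::aes(.data$q_max, .data$gcf)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "maximum individual ancestry",
                  y = "terminal gCF (%)") +
    ggplot2::theme_minimal()
}

#' Per-candidate admixture summaries
#'
#' For each candidate: specimen count, mean and standard deviation of the
#' per-specimen maximum ancestry coefficient (0 when every member is a pure
#' parental), and the count of hybrid-classified members. Single-specimen
#' candidates are flagged for exclusion from the imbalance regression.
#'
#' @param Q ancestry matrix or `snmf_fit`.
#' @param assignments tibble (`specimen`, `candidate`).
#' @param hybrid_calls optional [classify_hybrids()] output for hybrid counts.
#' @return Tibble: `candidate`, `n`, `mean_qmax`, `sd_qmax`, `n_hybrid`,
#'   `excluded` (n < 2).
#' @export
clade_admixture_summary <- function(Q, assignments, hybrid_calls = NULL) {
  if (inherits(Q, "snmf_fit")) Q <- Q$Q
  Q <- as.matrix(Q)
  qmax <- tibble(specimen = rownames(Q), q_max = apply(Q, 1, max))
  df <- as_tibble(assignments) %>% left_join(qmax, by = "specimen")
  hy <- if (is.null(hybrid_calls)) {
    tibble(specimen = character(), class = character())
  } else as_tibble(hybrid_calls)
  df %>% group_by(.data$candidate) %>%
    summarise(n = n(), mean_qmax = mean(.data$q_max),
              sd_qmax = if (n() > 1) sd(.data$q_max) else 0,
              n_hybrid = sum(.data$specimen %in%
                               hy$specimen[hy$class == "hybrid"]),
              .groups = "drop") %>%
    mutate(excluded = .data$n < 2)
}

#' Imbalance of candidate subtrees versus within-candidate admixture
#'
#' Regresses PDA-normalized Colless imbalance of each candidate's subtree on
#' the standard deviation of its members' maximum ancestry coefficients
#' (ordinary least squares). Candidates with fewer than 3 tips (imbalance
#' undefined) or a single specimen are excluded.
#'
#' @param tree specimen-level `phylo`; candidate subtrees are extracted as
#'   the clade spanned by each candidate's members.
#' @param summaries output of [clade_admixture_summary()].
#' @param assignments tibble (`specimen`, `candidate`).
#' @return Object of class `imbalance_admixture`: `table` (candidate, n,
#'   sd_qmax, i_pda), `slope`, `r2`, `p`, `undefined` (zero variance in
#'   SD(q_max)).
#' @export
imbalance_vs_admixture <- function(tree, summaries, assignments) {
  assignments <- as_tibble(assignments)
  tab <- purrr::map_dfr(seq_len(nrow(summaries)), function(i) {
    cand <- summaries$candidate[i]
    members <- assignments$specimen[assignments$candidate == cand]
    members <- intersect(members, tree$tip.label)
    if (length(members) < 3 || summaries$excluded[i]) {
      return(tibble(candidate = cand, n = length(members),
                    sd_qmax = summaries$sd_qmax[i], i_pda = NA_real_))
    }
    sub <- ape::keep.tip(tree, members)
    if (!ape::is.rooted(sub)) sub <- ape::root(sub, outgroup = sub$tip.label[1],
                                               resolve.root = TRUE)
    if (!ape::is.binary(sub)) sub <- ape::multi2di(sub, random = FALSE)
    tibble(candidate = cand, n = length(members),
           sd_qmax = summaries$sd_qmax[i],
           i_pda = colless(sub)$i_norm)
  })
  usable <- tab %>% filter(!is.na(.data$i_pda))
  if (nrow(usable) < 3) {
    return(structure(list(table = tab, slope = NA_real_, r2 = NA_real_,
                          p = NA_real_, undefined = TRUE,
                          reason = "fewer than 3 candidates with >= 3 tips"),
                     class = "imbalance_admixture"))
  }
  if (sd(usable$sd_qmax) == 0) {
    return(structure(list(table = tab, slope = NA_real_, r2 = NA_real_,
                          p = NA_real_, undefined = TRUE,
                          reason = "zero variance in SD(q_max)"),
                     class = "imbalance_admixture"))
  }
  fit <- lm(i_pda ~ sd_qmax, data = usable)
  sm <- summary(fit)
  structure(list(table = tab, slope = unname(coef(fit)[2]),
                 r2 = sm$r.squared,
                 p = sm$coefficients[2, 4], undefined = FALSE,
                 reason = ""),
            class = "imbalance_admixture")
}

#' @export
print.imbalance_admixture <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<imbalance_admixture> undefined: %s\n", x$reason))
  } else {
    cat(sprintf("<imbalance_admixture> slope = %.3f, R2 = %.3f, p = %.4f (%d candidates)\n",
                x$slope, x$r2, x$p, sum(!is.na(x$table$i_pda))))
  }
  invisible(x)
}

#' @export
glance.imbalance_admixture <- function(x, ...) {
  tibble(slope = x$slope, r2 = x$r2, p = x$p, undefined = x$undefined,
         n_candidates = sum(!is.na(x$table$i_pda)))
}

#' @export
autoplot.imbalance_admixture <- function(object, ...) {
  ggplot2::ggplot(object$table %>% filter(!is.na(.data$i_pda)),
                  ggplot2::aes(.data$sd_qmax, .data$i_pda)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "SD of maximum individual ancestry",
                  y = expression(I[PDA])) +
    ggplot2::theme_minimal()
}

#' Divergence rank and terminal branch length of clade members
#'
#' For each member of a candidate clade: the number of internal nodes between
#' the clade's crown and the member's attachment point (0 =
#' earliest-diverging) and its terminal branch length. By default positions
#' are measured on the candidate's induced subtree (the tree pruned to the
#' members), so a member pulled outside the candidate's core — the typical
#' fate of a strong hybrid — registers as basal; pruning also accumulates its
#' inflated path length onto the terminal branch. The node-count rank is
#' robust to rate variation, which is why the rootward-shift test uses it
#' rather than substitution depth.
#'
#' @param tree specimen-level `phylo`.
#' @param members specimen ids (must be tips).
#' @param induced measure on the induced subtree of the members (default
#'   TRUE) rather than on the full tree.
#' @return Tibble: `specimen`, `rank`, `terminal_length`.
#' @export
divergence_ranks <- function(tree, members, induced = TRUE) {
  members <- intersect(members, tree$tip.label)
  if (induced && length(members) >= 2 && length(members) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, members)
  }
  crown <- ape::getMRCA(tree, members)
  depth_of <- function(sp) {
    v <- match(sp, tree$tip.label)
    d <- 0L
    repeat {
      parent <- tree$edge[tree$edge[, 2] == v, 1]
      if (!length(parent) || parent == crown) break
      v <- parent
      d <- d + 1L
    }
    d
  }
  tibble(specimen = members,
         rank = vapply(members, depth_of, integer(1)),
         terminal_length = vapply(members, function(sp) {
           tree$edge.length[tree$edge[, 2] == match(sp, tree$tip.label)]
         }, numeric(1)))
}

#' Do hybrids occupy earlier-diverging positions within their candidate?
#'
#' For one candidate: ranks each member by the number of internal nodes
#' between the candidate's crown and the member's attachment point (smaller =
#' earlier-diverging), then compares hybrid against pure members with a
#' one-sided rank-sum test (hybrids earlier). Terminal branch lengths are
#' compared likewise (hybrids longer).
#'
#' @param tree specimen-level `phylo` with branch lengths.
#' @param candidate_members specimen ids of the candidate.
#' @param hybrid_specimens which of the members are hybrid-classified.
#' @return One-row tibble: `n`, `n_hybrid`, `p_rank` (rank-sum, hybrids
#'   earlier), `p_length` (hybrids on longer terminal branches), `skipped`,
#'   `reason`.
#' @export
rootward_shift <- function(tree, candidate_members, hybrid_specimens) {
  members <- intersect(candidate_members, tree$tip.label)
  hybrids <- intersect(hybrid_specimens, members)
  pure <- setdiff(members, hybrids)
  if (length(members) < 4 || !length(hybrids) || !length(pure)) {
    return(tibble(n = length(members), n_hybrid = length(hybrids),
                  p_rank = NA_real_, p_length = NA_real_, skipped = TRUE,
                  reason = "needs >= 4 members including >= 1 hybrid and >= 1 pure"))
  }
  dr <- divergence_ranks(tree, members)
  ranks <- setNames(dr$rank, dr$specimen)
  term_len <- setNames(dr$terminal_length, dr$specimen)
  wt_rank <- suppressWarnings(
    wilcox.test(ranks[hybrids], ranks[pure], alternative = "less"))
  wt_len <- suppressWarnings(
    wilcox.test(term_len[hybrids], term_len[pure], alternative = "greater"))
  tibble(n = length(members), n_hybrid = length(hybrids),
         p_rank = wt_rank$p.value, p_length = wt_len$p.value,
         skipped = FALSE, reason = "")
}
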