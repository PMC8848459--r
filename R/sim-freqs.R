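bn_drift <- function(p, F) {
  if (F <= 0 || F >= 1) abort("Balding-Nichols F must lie strictly inside (0, 1)")
  out <- p
  mid <- p > 0 & p < 1
  out[mid] <- rbeta(sum(mid), p[mid] * (1 - F) / F, (1 - p[mid]) * (1 - F) / F)
  out
}

#' Simulate per-population derived-allele frequencies (star model)
#'
#' The Balding-Nichols generator behind the fast frequency-level tier: an
#' ancestral frequency `p` is drawn per site (default Uniform(0.05, 0.95)) and
#' each population draws `p_k ~ Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)`, so that
#' `Var(p_k) = F_k p (1-p)`. Pulse events in the model act as frequency
#' mixtures, applied in order: `p_recipient <- (1-a) p_recipient + a p_donor`.
#'
#' @param model a [population_model()] with per-population `F`.
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @param ancestral function of `n` returning ancestral frequencies.
#' @return An object of class `pop_freqs`: list with `freq` (populations x
#'   sites matrix), `ancestral` and `pops`.
#' @export
simulate_allele_frequencies <- function(model, n_sites, seed = 1L,
                                        ancestral = function(n) runif(n, 0.05, 0.95)) {
  stopifnot(inherits(model, "population_model"))
  if (is.null(model$F)) abort("frequency-tier simulation needs per-population F")
  withr_seed(seed, {
    p <- ancestral(n_sites)
    freq <- do.call(rbind, lapply(model$pops, function(k) {
      bn_drift(p, model$F[[k]])
    }))
    rownames(freq) <- model$pops
    if (nrow(model$pulses)) {
      for (i in seq_len(nrow(model$pulses))) {
        d <- model$pulses$donor[i]; r <- model$pulses$recipient[i]
        a <- model$pulses$prop[i]
        freq[r, ] <- (1 - a) * freq[r, ] + a * freq[d, ]
      }
    }
    structure(list(freq = freq, ancestral = p, pops = model$pops),
              class = "pop_freqs")
  })
}

#' Simulate allele frequencies hierarchically along the population tree
#'
#' Tree-structured Balding-Nichols drift: the root draws the ancestral
#' frequency, and every branch of length `t` applies a Beta drift step with
#' `F = 1 - exp(-t)`. Pulse-admixture events mix the recipient branch's
#' frequency with the donor lineage's frequency at the event time
#' (drift to the pulse point, mix, drift on), so that downstream f4-ratio and
#' f-branch statistics can localize donors on the tree.
#'
#' @inheritParams simulate_allele_frequencies
#' @param drift_scale drift accumulated per coalescent unit of branch length
#'   (`F = 1 - exp(-drift_scale * dt)` per segment). The default 0.1 keeps
#'   per-branch drift modest so compounded Beta drift stays in the
#'   quasi-additive regime that f4-type statistics assume; larger values
#'   saturate differentiation and distort admixture-fraction estimates.
#' @return A `pop_freqs` object (tip populations only).
#' @export
simulate_frequencies_tree <- function(model, n_sites, seed = 1L,
                                      ancestral = function(n) runif(n, 0.05, 0.95),
                                      drift_scale = 0.1) {
  stopifnot(inherits(model, "population_model"))
  tree <- model$tree
  if (is.null(tree)) abort("tree-tier simulation needs a population tree")
  withr_seed(seed, {
    times <- node_times(tree)
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    pl <- model$pulses
    # every branch is simulated segment-wise between "breakpoints": its two
    # end nodes plus any pulse time at which it donates or receives, so the
    # donor's sampled frequency shares all drift above the pulse point with
    # the introgressed material (this is what makes f4-ratios consistent)
    brk <- vector("list", ntip + tree$Nnode)
    add_brk <- function(v, t) brk[[v]] <<- sort(unique(c(brk[[v]], t)),
                                                decreasing = TRUE)
    recip <- list()  # key "v@t" -> list(donor branch, time, prop)
    if (nrow(pl)) {
      for (i in seq_len(nrow(pl))) {
        rv <- branch_node(tree, pl$recipient[i])
        dv <- branch_at_time(tree, times, pl$donor[i], pl$time[i])
        add_brk(rv, pl$time[i]); add_brk(dv, pl$time[i])
        key <- sprintf("%d@%.9g", rv, pl$time[i])
        recip[[key]] <- c(recip[[key]],
                          list(list(donor = dv, time = pl$time[i],
                                    prop = pl$prop[i])))
      }
    }
    drift_seg <- function(p, dt) {
      if (dt <= 1e-9) return(p)
      bn_drift(p, min(1 - 1e-9, 1 - exp(-drift_scale * dt)))
    }
    memo <- new.env(parent = emptyenv())
    # frequency of branch v's lineage at breakpoint time t (memoised)
    freq_at <- function(v, t) {
      key <- sprintf("%d@%.9g", v, t)
      if (!is.null(memo[[key]])) return(memo[[key]])
      val <- if (v == root && t >= times[root]) {
        if (is.null(memo[["root"]])) memo[["root"]] <- ancestral(n_sites)
        memo[["root"]]
      } else {
        parent <- tree$edge[tree$edge[, 2] == v, 1]
        above <- c(times[parent], brk[[v]])
        above <- min(above[above > t + 1e-12])
        prev <- if (above >= times[parent] - 1e-12) {
          freq_at(parent, times[parent])
        } else freq_at(v, above)
        p <- drift_seg(prev, above - t)
        for (ev in recip[[key]]) {
          p <- (1 - ev$prop) * p + ev$prop * freq_at(ev$donor, ev$time)
        }
        p
      }
      memo[[key]] <- val
      val
    }
    freq <- do.call(rbind, lapply(seq_len(ntip), function(v) freq_at(v, 0)))
    rownames(freq) <- tree$tip.label
    structure(list(freq = freq, ancestral = memo[["root"]],
                   pops = tree$tip.label),
              class = "pop_freqs")
  })
}

#' Simulate diploid genotypes from population frequencies and ancestry
#'
#' Draws `g_il ~ Binomial(2, sum_k q_ik p_kl)` and applies missingness
#' afterwards at the configured per-site and per-individual rates. Sites are
#' assigned to `n_loci` contiguous pseudo-loci so downstream statistics can
#' block-jackknife.
#'
#' @param freqs a `pop_freqs` object (or a populations x sites matrix).
#' @param Q_true individuals x populations ancestry matrix; rows must sum
#'   to 1. Rownames become specimen ids.
#' @param n_loci number of contiguous site blocks to label as loci.
#' @param site_missing,ind_missing missingness rates in `[0, 1]`
#'   (`ind_missing` may be a per-individual vector).
#' @param seed integer seed.
#' @return A [geno_matrix()].
#' @export
simulate_genotypes <- function(freqs, Q_true, n_loci = 1,
                               site_missing = 0, ind_missing = 0, seed = 1L) {
  P <- if (inherits(freqs, "pop_freqs")) freqs$freq else as.matrix(freqs)
  Q_true <- as.matrix(Q_true)
  if (ncol(Q_true) != nrow(P)) {
    abort(sprintf("Q_true has %d columns but freqs has %d populations",
                  ncol(Q_true), nrow(P)))
  }
  if (any(abs(rowSums(Q_true) - 1) > 1e-6)) abort("Q_true rows must sum to 1")
  n <- nrow(Q_true); L <- ncol(P)
  withr_seed(seed, {
    mix <- Q_true %*% P
    G <- matrix(rbinom(n * L, 2L, as.vector(mix)), n, L)
    if (site_missing > 0) G[runif(n * L) < site_missing] <- NA_integer_
    im <- rep_len(ind_missing, n)
    for (i in which(im > 0)) G[i, runif(L) < im[i]] <- NA_integer_
    specs <- rownames(Q_true)
    if (is.null(specs)) specs <- paste0("ind", seq_len(n))
    locus_of <- paste0("locus", ceiling(seq_len(L) / ceiling(L / n_loci)))
    geno_matrix(G, sites = tibble(site = paste0("s", seq_len(L)),
                                  locus = locus_of, pos = seq_len(L)),
                specimens = specs)
  })
}
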