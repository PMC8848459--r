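#' Population model for the synthetic-data generators
#'
#' Describes the demographic scenario both generator tiers draw from: a set
#' of population labels with per-population drift (Balding-Nichols F) for the
#' fast frequency-level tier, an optional rooted binary population tree with
#' branch lengths in coalescent units for the multispecies-coalescent tier,
#' pulse-admixture events, and "ghost" populations present in the model but
#' excluded from output sampling.
#'
#' @param pops character population labels (defaults to the tree's tips).
#' @param tree optional rooted binary `phylo`, branch lengths in coalescent
#'   units (time scaled so the pairwise coalescence rate is 1).
#' @param F named per-population drift parameters in (0, 1), used by the
#'   star-shaped frequency generator; may be omitted when only the tree tier
#'   is used.
#' @param pulses tibble of pulse-admixture events with columns `donor`,
#'   `recipient` (population label, or several labels joined by `+` to name
#'   an internal branch via its tip set), `time` (before present, coalescent
#'   units; 0 for frequency-tier mixtures) and `prop` in `[0, 1]`.
#' @param ghosts labels of populations never sampled in the output.
#' @return An object of class `population_model`.
#' @export
population_model <- function(pops = NULL, tree = NULL, F = NULL,
                             pulses = NULL, ghosts = character()) {
  if (is.null(pops)) {
    if (is.null(tree)) abort("supply population labels or a population tree")
    pops <- tree$tip.label
  }
  if (!is.null(tree)) {
    if (!ape::is.rooted(tree)) abort("population tree must be rooted")
    if (!ape::is.binary(tree)) abort("population tree must be binary")
    if (is.null(tree$edge.length)) abort("population tree needs branch lengths")
    if (!all(pops %in% c(tree$tip.label))) {
      abort("all population labels must be tree tips")
    }
  }
  if (!is.null(F)) {
    if (is.null(names(F))) names(F) <- pops
    if (any(F <= 0 | F >= 1)) {
      abort("drift parameters F must lie strictly inside (0, 1); F = 0 or 1 is degenerate")
    }
  }
  if (is.null(pulses)) {
    pulses <- tibble(donor = character(), recipient = character(),
                     time = numeric(), prop = numeric())
  }
  pulses <- as_tibble(pulses)
  if (nrow(pulses)) {
    if (any(pulses$prop < 0 | pulses$prop > 1)) {
      abort("admixture proportions must lie in [0, 1]")
    }
    if (!is.null(tree)) {
      times <- node_times(tree)
      for (i in seq_len(nrow(pulses))) {
        for (side in c("donor", "recipient")) {
          iv <- branch_interval(tree, times, pulses[[side]][i])
          if (pulses$time[i] < iv[1] || pulses$time[i] >= iv[2]) {
            abort(sprintf(
              "pulse %d: time %.3f outside the existence interval [%.3f, %.3f) of %s branch '%s'",
              i, pulses$time[i], iv[1], iv[2], side, pulses[[side]][i]))
          }
        }
      }
    }
  }
  structure(list(pops = pops, tree = tree, F = F, pulses = pulses,
                 ghosts = ghosts),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> %d populations%s, %d pulse event(s)%s\n",
              length(x$pops),
              if (is.null(x$tree)) " (star)" else " on a tree",
              nrow(x$pulses),
              if (length(x$ghosts)) sprintf(", ghosts: %s",
                                            paste(x$ghosts, collapse = ", ")) else ""))
  invisible(x)
}

# time before present of every node (assumes tips contemporary)
node_times <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

# the pop-tree node whose branch is named by `label` (tip, or "+"-joined tip
# set meaning the branch above their MRCA)
branch_node <- function(tree, label) {
  tips <- strsplit(label, "+", fixed = TRUE)[[1]]
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) abort(sprintf("unknown population(s) in '%s'", label))
  if (length(idx) == 1) idx else ape::getMRCA(tree, idx)
}

branch_interval <- function(tree, times, label) {
  v <- branch_node(tree, label)
  root <- length(tree$tip.label) + 1L
  if (v == root) return(c(times[v], Inf))
  parent <- tree$edge[tree$edge[, 2] == v, 1]
  c(times[v], times[parent])
}

# walk rootward from a branch until its interval contains time t
branch_at_time <- function(tree, times, label, t) {
  v <- branch_node(tree, label)
  root <- length(tree$tip.label) + 1L
  if (t < times[v]) abort(sprintf("time %.3f predates branch '%s'", t, label))
  while (v != root) {
    parent <- tree$edge[tree$edge[, 2] == v, 1]
    if (times[parent] > t) break
    v <- parent
  }
  v
}

#' Synthetic-dataset configuration
#'
#' Holds the generator knobs for [simulate_dataset()]. Defaults mirror the
#' target-capture study design at quarter scale: 60 loci of 2 kb, 8 diploids
#' per population, no missingness.
#'
#' @param n_loci number of loci.
#' @param locus_length locus length in bp.
#' @param rate per-site substitution rate per coalescent unit (Jukes-Cantor).
#' @param n_per_pop diploid sample size per population (scalar or named).
#' @param hybrids optional tibble of hybrid individuals: `specimen`, `pop_a`,
#'   `pop_b`, `class` in `{"F1", "BC1", "clinal"}`, optional `q_a` (target
#'   first-parent fraction for clinal individuals; default 0.5).
#' @param site_missing per-site missing-data rate applied to haplotype bases.
#' @param ind_missing per-individual missing rate: scalar, or a named vector
#'   to mark "degraded" specimens with elevated rates.
#' @param ambig_rate fraction of bases replaced by IUPAC ambiguity codes.
#' @param mito_capture `NULL`, or a list with `carriers` (specimen ids) and
#'   `donor` (population): locus 1 is flagged maternal and captured.
#' @param seed RNG seed; a fixed seed gives byte-identical datasets.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 60, locus_length = 2000, rate = 0.01,
                       n_per_pop = 8, hybrids = NULL,
                       site_missing = 0, ind_missing = 0, ambig_rate = 0,
                       mito_capture = NULL, seed = 1L) {
  rates <- c(site_missing = site_missing, ambig_rate = ambig_rate,
             ind_missing = unname(ind_missing))
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (!is.null(hybrids)) {
    hybrids <- as_tibble(hybrids)
    if (!"q_a" %in% names(hybrids)) hybrids$q_a <- 0.5
    stopifnot(all(hybrids$class %in% c("F1", "BC1", "clinal")))
  }
  structure(list(n_loci = n_loci, locus_length = locus_length, rate = rate,
                 n_per_pop = n_per_pop, hybrids = hybrids,
                 site_missing = site_missing, ind_missing = ind_missing,
                 ambig_rate = ambig_rate, mito_capture = mito_capture,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Quarter-scale study-shaped default scenario
#'
#' Twelve populations in three clades of four on a symmetric coalescent-unit
#' tree (within-clade splits at 2, clade crowns at 4, root at 8), moderate
#' drift, no admixture. Pair with [sim_config()] defaults for the standard
#' desk-scale dataset.
#'
#' @param f drift parameter shared by all populations (default 0.2).
#' @param outgroup also include a basal outgroup population `"OUT"`
#'   (diverging at 12 coalescent units) for polarization and D-statistics;
#'   site-pattern tests polarized by a within-radiation population are biased
#'   for trios containing its relatives.
#' @return A [population_model()].
#' @export
default_study_model <- function(f = 0.2, outgroup = FALSE) {
  clade_tree <- function(tag) {
    sprintf("((%s1:2,%s2:2):2,(%s3:2,%s4:2):2)", tag, tag, tag, tag)
  }
  txt <- sprintf("(%s:4,(%s:2,%s:2):2)",
                 clade_tree("A"), clade_tree("B"), clade_tree("C"))
  if (outgroup) txt <- sprintf("(%s:4,OUT:12)", txt)
  tree <- ape::read.tree(text = paste0(txt, ";"))
  pops <- tree$tip.label
  population_model(pops = pops, tree = tree,
                   F = setNames(rep(f, length(pops)), pops))
}
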