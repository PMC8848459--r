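#' Colless imbalance with PDA normalization
#'
#' Colless' I is the sum over internal nodes of a rooted binary tree of the
#' absolute difference in tip counts between the two daughter subtrees. The
#' default normalization divides by n^(3/2), the scaling of the expected index
#' under the proportional-to-distinguishable-arrangements (PDA) null model of
#' tree shape; `normalization = "max"` divides instead by the caterpillar
#' maximum (n-1)(n-2)/2.
#'
#' @param tree a rooted, binary `phylo` object with at least 3 tips.
#' @param normalization `"pda"` (I / n^1.5, default) or `"max"`.
#' @return A one-row tibble: `n_tips`, `colless_i` (raw sum), `i_norm`
#'   (normalized), `normalization`.
#' @export
#' @examples
#' colless(ape::read.tree(text = "(((a,b),c),d);"))
colless <- function(tree, normalization = c("pda", "max")) {
  normalization <- match.arg(normalization)
  if (!inherits(tree, "phylo")) abort("tree must be a phylo object")
  n <- length(tree$tip.label)
  if (n < 3) abort("colless requires at least 3 tips")
  if (!ape::is.rooted(tree)) abort("colless requires a rooted tree")
  if (!ape::is.binary(tree)) {
    abort("colless requires a fully binary tree; resolve polytomies first (see resolve_polytomies())")
  }
  counts <- tip_counts(tree)
  internal <- (n + 1):(n + tree$Nnode)
  i_raw <- 0
  for (v in internal) {
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    i_raw <- i_raw + abs(counts[kids[1]] - counts[kids[2]])
  }
  denom <- if (normalization == "pda") n^1.5 else (n - 1) * (n - 2) / 2
  tibble(n_tips = n, colless_i = i_raw,
         i_norm = i_raw / denom, normalization = normalization)
}

# tips descending from every node, indexed by node number
tip_counts <- function(tree) {
  n <- length(tree$tip.label)
  counts <- integer(n + tree$Nnode)
  counts[seq_len(n)] <- 1L
  # postorder: children before parents
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (i in seq_len(nrow(edge))) {
    counts[edge[i, 1]] <- counts[edge[i, 1]] + counts[edge[i, 2]]
  }
  counts
}

#' Resolve polytomies by seeded random bifurcation
#'
#' Utility for feeding multifurcating trees to [colless()]; off by default in
#' every pipeline because the analyses assume binary input trees.
#'
#' @param tree a `phylo` object.
#' @param seed integer seed for the random resolution.
#' @return A binary `phylo`.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  withr_seed(seed, ape::multi2di(tree, random = TRUE))
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
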