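#' Neighbor-joining tree from genotypes or an alignment
#'
#' Stand-in tree builder for externally estimated ML topologies: Saitou-Nei
#' neighbor joining on p-distances with pairwise deletion of missing data.
#' Negative NJ branch lengths are clamped to zero with the (negative) amount
#' transferred to the adjacent branches below, preserving tip-to-tip path
#' lengths. Taxa are ordered by label before joining so ties break
#' deterministically.
#'
#' @param x a [geno_matrix()] (genotype Manhattan distance / 2 per shared
#'   site), a [locus_alignment()] (per-haplotype or per-specimen sequence
#'   p-distance), or a ready `dist`.
#' @param tips for alignments: `"specimen"` (first haplotype of each
#'   specimen, default) or `"haplotype"`.
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(x, tips = c("specimen", "haplotype")) {
  tips <- match.arg(tips)
  d <- if (inherits(x, "dist")) x
  else if (inherits(x, "geno_matrix")) geno_dist(x)
  else if (inherits(x, "locus_alignment")) aln_dist(x, tips)
  else abort("x must be a geno_matrix, locus_alignment or dist")
  m <- as.matrix(d)
  if (nrow(m) < 3) abort("neighbor joining needs at least 3 taxa")
  bad <- which(!is.finite(m) & row(m) < col(m), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("no shared called sites between '%s' and '%s'",
                  rownames(m)[bad[1, 1]], rownames(m)[bad[1, 2]]))
  }
  ord <- order(rownames(m))
  tree <- ape::nj(stats::as.dist(m[ord, ord]))
  clamp_negative_branches(tree)
}

geno_dist <- function(gm) {
  G <- gm$G
  n <- nrow(G)
  m <- matrix(0, n, n, dimnames = list(gm$specimens, gm$specimens))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(G[i, ]) & !is.na(G[j, ])
      m[i, j] <- m[j, i] <- if (!any(ok)) NA_real_ else
        mean(abs(G[i, ok] - G[j, ok])) / 2
    }
  }
  stats::as.dist(m)
}

aln_dist <- function(aln, tips = "specimen") {
  M <- aln$seqs
  if (tips == "specimen") {
    specs <- unique(aln$specimen)
    M <- M[match(paste0(specs, "|1"), rownames(M)), , drop = FALSE]
    rownames(M) <- specs
  }
  valid <- matrix(M %in% BASES, nrow(M))
  n <- nrow(M)
  m <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      m[i, j] <- m[j, i] <- if (!any(ok)) NA_real_ else
        mean(M[i, ok] != M[j, ok])
    }
  }
  stats::as.dist(m)
}

clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    child <- tree$edge[e, 2]
    below <- which(tree$edge[, 1] == child)
    tree$edge.length[below] <- tree$edge.length[below] + tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (!length(below)) break   # terminal negative edge: clamp only
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Test monophyly of a label set
#'
#' Rooted: some clade's tip set equals the labels exactly. Unrooted: some
#' bipartition isolates the labels (tested by rooting at a tip outside the
#' set). The full tip set and singletons are trivially monophyletic.
#'
#' @param tree a `phylo`.
#' @param labels character tip labels.
#' @param rooted treat the tree as rooted (default: its rooted flag).
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, labels, rooted = ape::is.rooted(tree)) {
  labels <- unique(labels)
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown)) {
    abort(sprintf("unknown label(s): %s", paste(unknown, collapse = ", ")))
  }
  n <- length(tree$tip.label)
  if (length(labels) %in% c(1L, n)) return(TRUE)
  if (!rooted) {
    out <- setdiff(tree$tip.label, labels)[1]
    tree <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  }
  mrca <- ape::getMRCA(tree, labels)
  desc <- ape::extract.clade(tree, mrca)$tip.label
  setequal(desc, labels)
}

# Internal branches of a (rooted) tree in unrooted terms: for each branch a
# bipartition and the four clades adjacent to it. Returns a list of entries
# (id = child node, clades = list of 4 tip sets, side1 = clades 1+2).
internal_branches <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  desc <- descendant_tips(tree)
  kids_of <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  root_kids <- kids_of(root)
  out <- list()
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    if (v == root) next
    parent <- tree$edge[tree$edge[, 2] == v, 1]
    kv <- kids_of(v)
    if (parent == root) {
      if (v != root_kids[1] && all(root_kids > ntip)) next  # same unrooted branch
      sib <- setdiff(root_kids, v)
      if (sib <= ntip) next                    # adjacent to a tip: terminal
      ks <- kids_of(sib)
      clades <- list(desc[[kv[1]]], desc[[kv[2]]], desc[[ks[1]]], desc[[ks[2]]])
    } else {
      sib <- setdiff(kids_of(parent), v)
      rest <- setdiff(tree$tip.label, c(desc[[v]], desc[[sib]]))
      if (!length(rest)) next
      clades <- list(desc[[kv[1]]], desc[[kv[2]]], desc[[sib]], rest)
    }
    out[[length(out) + 1L]] <- list(id = v, clades = clades,
                                    side1 = c(clades[[1]], clades[[2]]))
  }
  out
}

# canonical split keys of a tree restricted to its own taxa
split_keys <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  desc <- descendant_tips(tree)
  ntip <- length(tree$tip.label)
  keys <- character()
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    side <- desc[[v]]
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Gene concordance factors
#'
#' For every internal branch of the species tree, the percentage of decisive
#' gene trees whose (taxon-restricted) splits contain the branch's
#' bipartition. A gene tree is decisive for a branch when it carries at least
#' one taxon from each of the four clades adjacent to the branch; gene trees
#' may omit taxa. Branches with no decisive tree are `NA` with a flag, never
#' silently 0.
#'
#' @param species_tree a `phylo` (rooted or not) whose tips are specimens.
#' @param gene_trees a list / `multiPhylo` of gene trees.
#' @return Tibble with one row per internal branch: `branch` (child-node id
#'   in the species tree), `clade` (its descendant tip set, collapsed),
#'   `n_concordant`, `n_decisive`, `gcf` in `[0, 100]`, `undefined`.
#' @export
gene_concordance <- function(species_tree, gene_trees) {
  if (!length(gene_trees)) abort("no gene trees supplied")
  branches <- internal_branches(species_tree)
  gt_info <- lapply(gene_trees, function(gt) {
    list(taxa = gt$tip.label, keys = split_keys(gt))
  })
  purrr::map_dfr(branches, function(b) {
    conc <- 0L; dec <- 0L
    for (g in gt_info) {
      present <- lapply(b$clades, intersect, g$taxa)
      if (any(vapply(present, length, integer(1)) == 0)) next
      dec <- dec + 1L
      side <- intersect(b$side1, g$taxa)
      ref <- sort(g$taxa)[1]
      if (ref %in% side) side <- setdiff(g$taxa, side)
      if (length(side) <= 1 || length(side) >= length(g$taxa) - 1) {
        # restricted split is trivial: every tree displays it
        conc <- conc + 1L
        next
      }
      key <- paste(sort(side), collapse = "\r")
      if (key %in% g$keys) conc <- conc + 1L
    }
    tibble(branch = b$id,
           clade = paste(sort(intersect(b$side1, species_tree$tip.label)),
                         collapse = ","),
           n_concordant = conc, n_decisive = dec,
           gcf = if (dec > 0) 100 * conc / dec else NA_real_,
           undefined = dec == 0)
  })
}

#' Site concordance factors by quartet sampling
#'
#' For every internal branch, samples `n_quartets` quartets (one taxon from
#' each adjacent clade) and counts, per quartet, the decisive sites (exactly
#' two states, two taxa each) supporting each of the three quartet
#' topologies; sCF is the mean over quartets of the percentage of decisive
#' sites concordant with the branch. Deterministic under `seed`.
#'
#' @param species_tree a `phylo` whose tips are specimens.
#' @param alignments list of [locus_alignment()] covering the tree's taxa
#'   (first haplotype per specimen is used).
#' @param n_quartets quartets sampled per branch (default 100).
#' @param seed integer seed.
#' @return Tibble per internal branch: `branch`, `clade`, `scf`,
#'   `n_quartets_used`, `undefined` (no decisive site in any quartet).
#' @export
site_concordance <- function(species_tree, alignments, n_quartets = 100,
                             seed = 1L) {
  if (inherits(alignments, "locus_alignment")) alignments <- list(alignments)
  specs <- unique(unlist(lapply(alignments, `[[`, "specimen")))
  seqs <- do.call(cbind, lapply(alignments, function(a) {
    M <- a$seqs[match(paste0(specs, "|1"), rownames(a$seqs)), , drop = FALSE]
    rownames(M) <- specs
    M
  }))
  missing_taxa <- setdiff(species_tree$tip.label, specs)
  if (length(missing_taxa)) {
    abort(sprintf("alignments do not cover taxa: %s",
                  paste(missing_taxa, collapse = ", ")))
  }
  branches <- internal_branches(species_tree)
  withr_seed(seed, {
    purrr::map_dfr(branches, function(b) {
      stopifnot(all(lengths(b$clades) > 0))
      vals <- numeric(); used <- 0L
      for (q in seq_len(n_quartets)) {
        pick <- vapply(b$clades, function(cl) cl[sample.int(length(cl), 1)], "")
        S <- seqs[pick, , drop = FALSE]
        valid <- colSums(matrix(S %in% BASES, 4)) == 4
        S <- S[, valid, drop = FALSE]
        if (!ncol(S)) next
        e12 <- S[1, ] == S[2, ]; e34 <- S[3, ] == S[4, ]
        e13 <- S[1, ] == S[3, ]; e24 <- S[2, ] == S[4, ]
        e14 <- S[1, ] == S[4, ]; e23 <- S[2, ] == S[3, ]
        conc <- e12 & e34 & !e13
        disc1 <- e13 & e24 & !e12
        disc2 <- e14 & e23 & !e12
        dec <- sum(conc) + sum(disc1) + sum(disc2)
        if (dec == 0) next
        used <- used + 1L
        vals <- c(vals, 100 * sum(conc) / dec)
      }
      tibble(branch = b$id,
             clade = paste(sort(b$side1), collapse = ","),
             scf = if (used > 0) mean(vals) else NA_real_,
             n_quartets_used = used, undefined = used == 0)
    })
  })
}

#' Terminal gene concordance factor per specimen
#'
#' The gCF of the internal branch immediately ancestral to each specimen's
#' terminal edge (the smallest enclosing informative split). Specimens in a
#' cherry share that branch, so sister pairs duplicate values by design;
#' specimens whose parent branch is not an internal branch (e.g. adjacent to
#' the root) are flagged undefined.
#'
#' @param tree species tree (`phylo`, specimen tips).
#' @param gene_trees gene trees as in [gene_concordance()].
#' @param specimens specimens to report (default: all tips).
#' @return Tibble: `specimen`, `branch`, `gcf`, `n_decisive`, `undefined`.
#' @export
terminal_gcf <- function(tree, gene_trees, specimens = tree$tip.label) {
  unknown <- setdiff(specimens, tree$tip.label)
  if (length(unknown)) {
    abort(sprintf("specimen(s) not in tree: %s", paste(unknown, collapse = ", ")))
  }
  gc <- gene_concordance(tree, gene_trees)
  # bipartition key -> row, so root-duplicated branches resolve correctly
  key_of <- function(ids) paste(sort(ids), collapse = ",")
  desc <- descendant_tips(tree)
  gc_key <- setNames(seq_len(nrow(gc)), gc$clade)
  purrr::map_dfr(specimens, function(sp) {
    tip <- match(sp, tree$tip.label)
    parent <- tree$edge[tree$edge[, 2] == tip, 1]
    k1 <- key_of(desc[[parent]])
    k2 <- key_of(setdiff(tree$tip.label, desc[[parent]]))
    row <- if (k1 %in% names(gc_key)) gc_key[[k1]]
    else if (k2 %in% names(gc_key)) gc_key[[k2]] else NA_integer_
    if (is.na(row)) {
      tibble(specimen = sp, branch = NA_integer_, gcf = NA_real_,
             n_decisive = 0L, undefined = TRUE)
    } else {
      tibble(specimen = sp, branch = gc$branch[row], gcf = gc$gcf[row],
             n_decisive = gc$n_decisive[row], undefined = gc$undefined[row])
    }
  })
}

#' Write a tree annotated with concordance factors
#'
#' Attaches per-branch support as internal node labels in the
#' `"label/gCF/sCF"` dialect and writes Newick.
#'
#' @param tree the species tree used for the concordance computations.
#' @param gcf [gene_concordance()] output (optional).
#' @param scf [site_concordance()] output (optional).
#' @param path output file; omit to return the annotated tree invisibly.
#' @return The annotated `phylo`, invisibly.
#' @export
write_concordance_tree <- function(tree, gcf = NULL, scf = NULL, path = NULL) {
  ntip <- length(tree$tip.label)
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep("", tree$Nnode)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  for (i in seq_len(tree$Nnode)) {
    v <- ntip + i
    g <- if (!is.null(gcf) && v %in% gcf$branch) {
      fmt(gcf$gcf[match(v, gcf$branch)])
    } else "NA"
    s <- if (!is.null(scf) && v %in% scf$branch) {
      fmt(scf$scf[match(v, scf$branch)])
    } else "NA"
    labs[i] <- paste(labs[i], g, s, sep = "/")
  }
  tree$node.label <- labs
  if (!is.null(path)) ape::write.tree(tree, path)
  invisible(tree)
}
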