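#' f-branch matrix: excess allele sharing assigned to tree branches
#'
#' For every branch b of a rooted species tree and every donor population C
#' not descended from b, computes
#' `f_b(C) = median over A in tips(sister(b)) of min over B in tips(desc(b))
#' of f4_ratio(A, B, C, O)`, the tree-aware summary that assigns excess allele
#' sharing to specific (recipient branch, donor) pairs. Negative medians are
#' clamped to 0 (raw values retained); significance is by composing the
#' per-trio delete-one-block f4-ratios into delete-one f_b values and
#' jackknifing those. Cells whose donor lies inside the recipient clade are
#' structural `NA`s. The display mask follows the convention of showing a cell
#' only when `f_b > threshold` and the jackknife p < 0.05; full values are
#' always retained.
#'
#' @param tree rooted `phylo` whose tips are the ingroup populations of
#'   `freqs` (the outgroup is taken from `freqs`, not the tree).
#' @param freqs an [allele_freqs()] table containing every tree tip and the
#'   outgroup.
#' @param threshold display threshold on f_b (default 0.20).
#' @param seed integer seed for the donor haplotype splits.
#' @return An object of class `fbranch`: list with `cells` (tibble: `branch`,
#'   `donor`, `f_b`, `f_b_raw`, `se`, `z`, `p`, `display`), `tree`,
#'   `threshold`. Branch ids name the most recent common ancestor's tip set
#'   for internal branches and the tip for terminal branches.
#' @export
f_branch <- function(tree, freqs, threshold = 0.20, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), inherits(freqs, "allele_freq_table"))
  if (!ape::is.rooted(tree)) abort("f_branch requires a rooted species tree")
  tips <- tree$tip.label
  missing_pops <- setdiff(tips, freqs$pops)
  if (length(missing_pops)) {
    abort(sprintf("tree tips absent from frequency table: %s",
                  paste(missing_pops, collapse = ", ")))
  }
  ntip <- length(tips)
  root <- ntip + 1L
  # cached per-donor haplotype splits (vary by donor + seed only)
  split_cache <- new.env(parent = emptyenv())
  donor_split <- function(C) {
    if (is.null(split_cache[[C]])) {
      ci <- match(C, freqs$pops)
      dC <- freqs$d[ci, ]; nC <- freqs$n[ci, ]
      half <- nC %/% 2L
      d_a <- withr_seed(seed + ci, stats::rhyper(length(dC), dC, nC - dC, half))
      split_cache[[C]] <- list(
        p_ca = ifelse(half > 0, d_a / half, NA_real_),
        p_cb = ifelse(nC - half > 0, (dC - d_a) / (nC - half), NA_real_),
        usable = nC >= 2
      )
    }
    split_cache[[C]]
  }
  pO <- freq_of(freqs, freqs$outgroup)
  pop_freq <- lapply(setNames(tips, tips), function(p) freq_of(freqs, p))
  trio_cache <- new.env(parent = emptyenv())
  # full-data and delete-one-block f4-ratio for a trio
  trio_f <- function(A, B, C) {
    key <- paste(A, B, C, sep = "\r")
    if (is.null(trio_cache[[key]])) {
      sp <- donor_split(C)
      ok <- !is.na(pop_freq[[A]]) & !is.na(pop_freq[[B]]) & !is.na(pO) &
        sp$usable & !is.na(sp$p_ca) & !is.na(sp$p_cb)
      w <- (1 - pO[ok]) * sp$p_ca[ok]
      num <- rowsum(w * (pop_freq[[B]][ok] - pop_freq[[A]][ok]),
                    freqs$block[ok])[, 1]
      den <- rowsum(w * (sp$p_cb[ok] - pop_freq[[A]][ok]),
                    freqs$block[ok])[, 1]
      S <- sum(num); T_ <- sum(den)
      full <- if (T_ <= 0) NA_real_ else S / T_
      den_del <- T_ - den
      deleted <- ifelse(den_del <= 0, full, (S - num) / den_del)
      trio_cache[[key]] <- list(full = full, deleted = deleted)
    }
    trio_cache[[key]]
  }
  desc <- descendant_tips(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  nodes <- setdiff(seq_len(ntip + tree$Nnode), root)
  cells <- purrr::map_dfr(nodes, function(v) {
    b_tips <- desc[[v]]
    parent <- tree$edge[tree$edge[, 2] == v, 1]
    sibs <- setdiff(children[[as.character(parent)]], v)
    sister_tips <- unlist(desc[sibs])
    branch_id <- if (v <= ntip) tips[v] else paste(sort(b_tips), collapse = "+")
    donors <- setdiff(tips, b_tips)
    purrr::map_dfr(donors, function(C) {
      a_set <- setdiff(sister_tips, C)
      if (!length(a_set)) {
        return(tibble(branch = branch_id, donor = C, f_b = NA_real_,
                      f_b_raw = NA_real_, se = NA_real_, z = NA_real_,
                      p = NA_real_, display = FALSE))
      }
      res <- lapply(a_set, function(A) {
        per_b <- lapply(b_tips, function(B) trio_f(A, B, C))
        fulls <- vapply(per_b, `[[`, numeric(1), "full")
        dels <- do.call(cbind, lapply(per_b, `[[`, "deleted"))
        i_min <- which.min(fulls)
        if (!length(i_min)) return(NULL)
        list(full = fulls[i_min], deleted = dels[, i_min])
      })
      res <- res[!vapply(res, is.null, logical(1))]
      if (!length(res)) {
        return(tibble(branch = branch_id, donor = C, f_b = NA_real_,
                      f_b_raw = NA_real_, se = NA_real_, z = NA_real_,
                      p = NA_real_, display = FALSE))
      }
      f_raw <- median(vapply(res, `[[`, numeric(1), "full"))
      del_mat <- do.call(cbind, lapply(res, `[[`, "deleted"))
      f_del <- apply(del_mat, 1, median)
      jk <- jackknife_se(f_del, f_raw)
      f_val <- min(max(f_raw, 0), 1)
      tibble(branch = branch_id, donor = C, f_b = f_val, f_b_raw = f_raw,
             se = jk$se, z = jk$z, p = jk$p,
             display = !is.na(jk$p) && f_val > threshold && jk$p < 0.05)
    })
  })
  # structural NAs: donors inside the recipient clade
  all_cells <- tidyr::expand_grid(
    branch = unique(cells$branch), donor = tips
  ) %>% left_join(cells, by = c("branch", "donor")) %>%
    mutate(display = !is.na(.data$display) & .data$display)
  structure(list(cells = all_cells, tree = tree, threshold = threshold),
            class = "fbranch")
}

# tip labels descending from every node (tips included), list by node number
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  out <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) out[[i]] <- tree$tip.label[i]
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (i in seq_len(nrow(edge))) {
    out[[edge[i, 1]]] <- c(out[[edge[i, 1]]], out[[edge[i, 2]]])
  }
  out
}

#' @export
print.fbranch <- function(x, ...) {
  shown <- sum(x$cells$display, na.rm = TRUE)
  cat(sprintf("<fbranch> %d branches x %d donors; %d cell(s) above display threshold %.2f\n",
              length(unique(x$cells$branch)), length(unique(x$cells$donor)),
              shown, x$threshold))
  invisible(x)
}

#' @export
tidy.fbranch <- function(x, ...) x$cells

#' Heatmap of an f-branch matrix
#'
#' Rows are tree branches (recipients), columns donor populations; cells below
#' the display rule (f_b above threshold and jackknife p < 0.05) are blanked,
#' structural cells (donor inside recipient clade) are grey.
#'
#' @param object an [f_branch()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fbranch <- function(object, ...) {
  df <- object$cells %>%
    mutate(shown = ifelse(.data$display, .data$f_b, NA_real_),
           structural = is.na(.data$f_b_raw))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$donor, y = .data$branch)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$shown), colour = "grey80") +
    ggplot2::geom_tile(data = df %>% filter(.data$structural),
                       fill = "grey50") +
    ggplot2::scale_fill_viridis_c(na.value = "white", limits = c(0, 1),
                                  name = expression(f[b])) +
    ggplot2::labs(x = "donor population", y = "recipient branch") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
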