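AMBIG_CODES <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
BASES <- c("A", "C", "G", "T")

#' Per-locus phased alignment
#'
#' Container for one locus of phased haplotype sequences. Haplotypes are named
#' `"<specimen>|1"` and `"<specimen>|2"`. Gaps (`-`), `N` and `?` count as
#' missing data; IUPAC two-to-four-fold codes count as ambiguities — the two
#' categories are tracked separately because the trimming rules treat them
#' separately.
#'
#' @param locus locus id (character scalar).
#' @param seqs named character vector of equal-length sequences, or a
#'   character matrix (haplotypes x sites) with rownames.
#' @return An object of class `locus_alignment`: list with `locus`, `seqs`
#'   (character matrix), `specimen` (per-haplotype specimen id).
#' @export
locus_alignment <- function(locus, seqs) {
  if (!is.matrix(seqs)) {
    if (is.null(names(seqs))) abort("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      abort(sprintf("locus '%s': unequal sequence lengths", locus))
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
    seqs <- m
  }
  if (nrow(seqs) == 0 || ncol(seqs) == 0) {
    abort(sprintf("locus '%s': empty alignment", locus))
  }
  structure(list(locus = locus, seqs = seqs,
                 specimen = sub("\\|[12]$", "", rownames(seqs))),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> '%s': %d haplotypes (%d specimens) x %d bp\n",
              x$locus, nrow(x$seqs), length(unique(x$specimen)), ncol(x$seqs)))
  invisible(x)
}

is_missing_char <- function(m) m == "-" | m == "N" | m == "?"
is_ambig_char <- function(m) matrix(m %in% AMBIG_CODES, nrow(m), ncol(m))

filter_report <- function(rule, dropped, retained, ids = character()) {
  tibble(rule = rule, dropped = dropped, retained = retained,
         dropped_ids = list(ids))
}

#' Trim low-quality haplotypes from a locus alignment
#'
#' Removes haplotypes ("alleles") with strictly more than `max_missing`
#' missing data or strictly more than `max_ambig` ambiguous bases. Thresholds
#' are strict inequalities, so a haplotype at exactly 80% missing survives the
#' default rule. Survivor order is preserved.
#'
#' @param aln a [locus_alignment()].
#' @param max_missing haplotypes with missing fraction > this are removed
#'   (default 0.80).
#' @param max_ambig haplotypes with ambiguity fraction > this are removed
#'   (default 0.05).
#' @return List with `alignment` (trimmed [locus_alignment()], or `NULL` if
#'   nothing survives) and `report` (tibble: rule, dropped, retained,
#'   dropped_ids).
#' @export
trim_alleles <- function(aln, max_missing = 0.80, max_ambig = 0.05) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (max_missing < 0 || max_missing > 1 || max_ambig < 0 || max_ambig > 1) {
    abort("thresholds must lie in [0, 1]")
  }
  miss <- rowMeans(is_missing_char(aln$seqs))
  ambig <- rowMeans(is_ambig_char(aln$seqs))
  drop <- miss > max_missing | ambig > max_ambig
  report <- bind_rows(
    filter_report("allele_missing", sum(miss > max_missing), sum(miss <= max_missing),
                  rownames(aln$seqs)[miss > max_missing]),
    filter_report("allele_ambiguity", sum(drop & miss <= max_missing),
                  sum(!drop), rownames(aln$seqs)[drop & miss <= max_missing])
  )
  alignment <- if (all(drop)) NULL else {
    locus_alignment(aln$locus, aln$seqs[!drop, , drop = FALSE])
  }
  list(alignment = alignment, report = report)
}

#' Drop high-missingness individuals from a genotype matrix
#'
#' Specimens with strictly more than `max_missing` missing genotype calls are
#' removed (they remain usable for tree analyses upstream; this rule only
#' gates SNP-based population-genetic inference). The threshold is a strict
#' inequality: a specimen at exactly 50% missing is retained under the
#' default.
#'
#' @param gm a [geno_matrix()].
#' @param max_missing drop specimens with missing fraction > this (default 0.50).
#' @return List with `genotypes` (filtered [geno_matrix()]) and `report`.
#' @export
drop_individuals <- function(gm, max_missing = 0.50) {
  stopifnot(inherits(gm, "geno_matrix"))
  miss <- rowMeans(is.na(gm$G))
  drop <- miss > max_missing
  if (all(drop)) abort("all individuals exceed the missingness threshold")
  report <- filter_report("individual_missing", sum(drop), sum(!drop),
                          gm$specimens[drop])
  list(genotypes = subset_geno(gm, specimens = gm$specimens[!drop]),
       report = report)
}

#' Extract a clade-specific SNP matrix from phased alignments
#'
#' Walks per-locus phased alignments and emits biallelic variable sites among
#' the clade members as a genotype matrix coded by minor-allele count.
#' Sites with genotype missingness of `max_site_missing` or more among clade
#' members are removed (the retained sites have strictly less), singletons
#' (minor allele observed on exactly one haplotype, or in one genotype copy
#' with `singleton_on = "genotype"`) are removed, and multi-allelic sites are
#' dropped. A haplotype base that is missing or ambiguous makes the specimen's
#' genotype missing at that site. Site provenance (locus, position) is kept.
#'
#' @param alignments list of [locus_alignment()] objects.
#' @param clade_members character vector of specimen ids to extract for.
#' @param max_site_missing sites with missingness >= this among clade members
#'   are removed (default 0.20, i.e. retained sites have < 20% missing).
#' @param drop_singletons remove singleton sites (default TRUE).
#' @param singleton_on `"haplotype"` (default: minor allele on exactly one
#'   haplotype) or `"genotype"` (minor allele in exactly one individual).
#' @return List with `genotypes` (a [geno_matrix()]; zero columns with a
#'   warning when no site survives) and `report`.
#' @export
extract_snps <- function(alignments, clade_members,
                         max_site_missing = 0.20, drop_singletons = TRUE,
                         singleton_on = c("haplotype", "genotype")) {
  singleton_on <- match.arg(singleton_on)
  if (!length(clade_members)) abort("clade_members must be non-empty")
  if (inherits(alignments, "locus_alignment")) alignments <- list(alignments)
  n_drop <- c(invariant = 0L, multiallelic = 0L, high_missing = 0L, singleton = 0L)
  per_locus <- lapply(alignments, function(aln) {
    rows <- which(aln$specimen %in% clade_members)
    if (!length(rows)) return(NULL)
    M <- aln$seqs[rows, , drop = FALSE]
    spec <- aln$specimen[rows]
    called <- matrix(M %in% BASES, nrow(M), ncol(M))
    counts <- vapply(BASES, function(b) colSums(M == b & called),
                     numeric(ncol(M)))
    if (ncol(M) == 1) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, BASES))
    n_alleles <- rowSums(counts > 0)
    variable <- n_alleles == 2
    n_drop["invariant"] <<- n_drop["invariant"] + sum(n_alleles <= 1)
    n_drop["multiallelic"] <<- n_drop["multiallelic"] + sum(n_alleles > 2)
    if (!any(variable)) return(NULL)
    specs <- unique(spec)
    hap1 <- match(paste0(specs, "|1"), rownames(M))
    hap2 <- match(paste0(specs, "|2"), rownames(M))
    jv <- which(variable)
    cnt <- counts[jv, , drop = FALSE]
    # minor allele = lower count; tie broken toward the later base
    pos_cnt <- cnt
    pos_cnt[cnt == 0] <- NA_real_
    lo <- apply(pos_cnt, 1, function(x) {
      i <- which(x == min(x, na.rm = TRUE))
      BASES[max(i)]
    })
    hi_base <- vapply(seq_along(jv), function(k) {
      present <- BASES[cnt[k, ] > 0]
      setdiff(present, lo[k])
    }, character(1))
    Mv <- M[, jv, drop = FALSE]
    is_alt <- t(t(Mv) == lo)
    okhap <- matrix(Mv %in% BASES, nrow(Mv))
    g1 <- is_alt[hap1, , drop = FALSE]; o1 <- okhap[hap1, , drop = FALSE]
    g2 <- is_alt[hap2, , drop = FALSE]; o2 <- okhap[hap2, , drop = FALSE]
    hap_na <- is.na(hap1) | is.na(hap2)
    G <- g1 + g2
    G[!(o1 & o2)] <- NA_integer_
    G[hap_na, ] <- NA_integer_
    miss_frac <- colMeans(is.na(G))
    high_missing <- miss_frac >= max_site_missing
    n_drop["high_missing"] <<- n_drop["high_missing"] + sum(high_missing)
    keep <- !high_missing
    if (drop_singletons) {
      mac <- if (singleton_on == "haplotype") colSums(G, na.rm = TRUE)
      else colSums(G > 0, na.rm = TRUE)
      singleton <- !high_missing & mac == 1
      n_drop["singleton"] <<- n_drop["singleton"] + sum(singleton)
      keep <- keep & !singleton
    }
    if (!any(keep)) return(NULL)
    keep_j <- jv[keep]
    storage.mode(G) <- "integer"
    list(G = G[, keep, drop = FALSE], specs = specs,
         sites = tibble(site = paste0(aln$locus, ":", keep_j),
                        locus = aln$locus, pos = keep_j,
                        ref = hi_base[keep], alt = lo[keep]))
  })
  per_locus <- per_locus[!vapply(per_locus, is.null, logical(1))]
  all_specs <- unique(unlist(lapply(per_locus, `[[`, "specs")))
  if (!length(all_specs)) all_specs <- intersect(
    clade_members, unique(unlist(lapply(alignments, `[[`, "specimen"))))
  if (!length(per_locus)) {
    warn("no variable sites survive filtering; returning an empty matrix")
    gm <- geno_matrix(matrix(NA_integer_, length(all_specs), 0),
                      sites = tibble(site = character(), locus = character(),
                                     pos = integer()),
                      specimens = all_specs)
  } else {
    G <- do.call(cbind, lapply(per_locus, function(pl) {
      out <- matrix(NA_integer_, length(all_specs), ncol(pl$G))
      out[match(pl$specs, all_specs), ] <- pl$G
      out
    }))
    sites <- bind_rows(lapply(per_locus, `[[`, "sites"))
    gm <- geno_matrix(G, sites, all_specs)
  }
  report <- bind_rows(lapply(names(n_drop), function(r) {
    filter_report(paste0("site_", r), n_drop[[r]], ncol(gm$G))
  }))
  list(genotypes = gm, report = report)
}

#' PCA of a SNP matrix
#'
#' Mean-imputes missing genotypes per site, centers (optionally scales) and
#' decomposes; visualization companion to the clustering analyses.
#'
#' @param gm a [geno_matrix()].
#' @param n_axes number of axes to return; truncated to the rank with a
#'   warning when too large.
#' @param scale divide sites by their standard deviation (default FALSE).
#' @return Object of class `geno_pca`: list with `scores` (tibble: specimen,
#'   PC1..PCk) and `var_explained` (fractions).
#' @export
pca_genotypes <- function(gm, n_axes = 2, scale = FALSE) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (nrow(gm$G) < 2 || ncol(gm$G) < 1) abort("PCA needs >= 2 specimens and >= 1 site")
  X <- gm$G
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  keep <- apply(X, 2, function(v) var(v) > 0)
  X <- X[, keep, drop = FALSE]
  p <- prcomp(X, center = TRUE, scale. = scale)
  r <- sum(p$sdev > 1e-12)
  if (n_axes > r) {
    warn(sprintf("n_axes = %d exceeds rank %d; truncated", n_axes, r))
    n_axes <- r
  }
  scores <- as_tibble(p$x[, seq_len(n_axes), drop = FALSE])
  scores$specimen <- gm$specimens
  structure(list(scores = scores[, c("specimen", setdiff(names(scores), "specimen"))],
                 var_explained = p$sdev^2 / sum(p$sdev^2)),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d specimens; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$var_explained[1],
              100 * ifelse(length(x$var_explained) > 1, x$var_explained[2], 0)))
  invisible(x)
}

#' @export
tidy.geno_pca <- function(x, ...) x$scores

#' @rdname pca_genotypes
#' @param object a `geno_pca`.
#' @param colour_by optional tibble (`specimen`, `population`) to colour points.
#' @param ... unused.
#' @export
autoplot.geno_pca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  if (!is.null(colour_by)) df <- left_join(df, as_tibble(colour_by), by = "specimen")
  aes <- if (!is.null(colour_by)) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$population)
  } else ggplot2::aes(.data$PC1, .data$PC2)
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
}
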