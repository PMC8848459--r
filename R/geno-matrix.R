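#' Genotype matrix container
#'
#' A light container for a specimens-by-sites matrix of diploid genotypes
#' coded as the count of the derived (or minor/alternate) allele: 0, 1, 2,
#' with `NA` for missing calls. Site provenance (locus of origin, position,
#' alleles) travels alongside so that downstream statistics can block-jackknife
#' by locus.
#'
#' @param G integer matrix, specimens in rows, sites in columns; values in
#'   `{0, 1, 2, NA}`.
#' @param sites tibble with one row per site: columns `site` (id), `locus`,
#'   `pos`, and optionally `ref`/`alt` allele characters.
#' @param specimens character vector of specimen ids (defaults to rownames).
#'
#' @return An object of class `geno_matrix`: a list with elements `G`,
#'   `sites`, `specimens`.
#' @export
geno_matrix <- function(G, sites = NULL, specimens = rownames(G)) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  bad <- !is.na(G) & !(G %in% 0:2)
  if (any(bad)) abort("genotype values must be 0, 1, 2 or NA")
  if (is.null(specimens)) specimens <- paste0("ind", seq_len(nrow(G)))
  if (is.null(sites)) {
    sites <- tibble(
      site = paste0("s", seq_len(ncol(G))),
      locus = "locus1", pos = seq_len(ncol(G))
    )
  }
  sites <- as_tibble(sites)
  if (nrow(sites) != ncol(G)) abort("sites table must have one row per column of G")
  rownames(G) <- specimens
  structure(list(G = G, sites = sites, specimens = specimens),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d specimens x %d sites (%d loci), %.1f%% missing\n",
              nrow(x$G), ncol(x$G), length(unique(x$sites$locus)),
              100 * mean(is.na(x$G))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$G)

#' @export
as_tibble.geno_matrix <- function(x, ...) {
  g <- as_tibble(x$G, .name_repair = ~ x$sites$site)
  g$specimen <- x$specimens
  tidyr::pivot_longer(g, -"specimen", names_to = "site", values_to = "genotype") %>%
    left_join(x$sites, by = "site")
}

#' Per-specimen and per-site missingness of a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @return A list with tibbles `by_specimen` (`specimen`, `missing`) and
#'   `by_site` (`site`, `missing`), fractions in `[0, 1]`.
#' @export
missingness <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  list(
    by_specimen = tibble(specimen = gm$specimens,
                         missing = rowMeans(is.na(gm$G))),
    by_site = tibble(site = gm$sites$site, missing = colMeans(is.na(gm$G)))
  )
}

subset_geno <- function(gm, specimens = NULL, site_keep = NULL) {
  G <- gm$G; sites <- gm$sites; sp <- gm$specimens
  if (!is.null(specimens)) {
    idx <- match(specimens, sp)
    if (anyNA(idx)) abort("unknown specimen(s) requested")
    G <- G[idx, , drop = FALSE]; sp <- sp[idx]
  }
  if (!is.null(site_keep)) {
    G <- G[, site_keep, drop = FALSE]
    sites <- sites[site_keep, , drop = FALSE]
  }
  geno_matrix(G, sites, sp)
}
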