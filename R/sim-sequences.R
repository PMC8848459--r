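#' Evolve sequences along a gene tree (Jukes-Cantor)
#'
#' Simulates one phased haplotype sequence per gene-tree tip under the JC69
#' model, with branch lengths in coalescent units scaled by `rate`
#' substitutions per site per unit. Ambiguity codes can be injected at a
#' configured rate to emulate uncertain base calls.
#'
#' @param gene_tree a `phylo` with nonnegative branch lengths; tip labels are
#'   haplotype ids.
#' @param length alignment length in bp (> 0).
#' @param rate substitutions per site per coalescent unit.
#' @param seed integer seed.
#' @param ambig_rate fraction of bases replaced by random IUPAC two-fold
#'   ambiguity codes.
#' @param locus locus id for the returned alignment.
#' @return A [locus_alignment()] of phased haplotypes.
#' @export
evolve_sequences <- function(gene_tree, length, rate, seed = 1L,
                             ambig_rate = 0, locus = "locus1") {
  if (length < 1) abort("zero-length alignment requested")
  if (any(gene_tree$edge.length < 0)) abort("branch lengths must be nonnegative")
  withr_seed(seed, {
    sim <- phangorn::simSeq(gene_tree, l = length, rate = rate)
    M <- toupper(as.character(sim))
    if (ambig_rate > 0) {
      hit <- which(matrix(runif(base::length(M)) < ambig_rate, nrow(M)))
      M[hit] <- sample(AMBIG_CODES, base::length(hit), replace = TRUE)
    }
    locus_alignment(locus, M)
  })
}

#' Synthetic dataset with ground truth
#'
#' Runs the full multispecies-coalescent tier: per-locus gene trees (with
#' hybrid haplotype routing and pulse admixture), Jukes-Cantor sequences,
#' missingness and ambiguity injection, optional mitochondrial capture on the
#' maternal locus (locus 1), and the derived genotype matrix. Everything is
#' deterministic under the config seed.
#'
#' @param model a [population_model()] with a tree; ghost populations are
#'   simulated but never sampled.
#' @param config a [sim_config()].
#' @return An object of class `synthetic_dataset`: list with `alignments`
#'   (list of [locus_alignment()]), `genotypes` ([geno_matrix()]),
#'   `gene_trees` (`multiPhylo`), `Q_true` (individuals x populations),
#'   `population_map` (tibble: specimen, population, clade, geo_distinct),
#'   `mito_locus` (locus id or `NA`), `config`, `provenance`.
#' @export
simulate_dataset <- function(model, config = sim_config()) {
  stopifnot(inherits(model, "population_model"), inherits(config, "sim_config"))
  sampled_pops <- setdiff(model$pops, model$ghosts)
  n_per <- config$n_per_pop
  if (is.null(names(n_per))) {
    n_per <- setNames(rep_len(n_per, length(sampled_pops)), sampled_pops)
  }
  samples <- purrr::map_dfr(sampled_pops, function(p) {
    tibble(specimen = sprintf("%s_i%02d", p, seq_len(n_per[[p]])),
           population = p)
  })
  hybrids <- config$hybrids
  withr_seed(config$seed, {
    locus_ids <- sprintf("locus%03d", seq_len(config$n_loci))
    gene_trees <- simulate_gene_trees(model, samples, config$n_loci,
                                      seed = sample.int(2^30, 1),
                                      hybrids = hybrids)
    alignments <- purrr::map2(gene_trees, locus_ids, function(gt, id) {
      evolve_sequences(gt, config$locus_length, config$rate,
                       seed = sample.int(2^30, 1),
                       ambig_rate = config$ambig_rate, locus = id)
    })
    all_specs <- c(samples$specimen,
                   if (!is.null(hybrids)) hybrids$specimen)
    # missingness: per-site MCAR, plus per-individual rates (degraded mode)
    im <- rep_len(config$ind_missing, length(all_specs))
    if (!is.null(names(config$ind_missing))) {
      im <- rep(0, length(all_specs))
      hitidx <- match(names(config$ind_missing), all_specs)
      im[hitidx[!is.na(hitidx)]] <- config$ind_missing[!is.na(hitidx)]
    }
    names(im) <- all_specs
    if (config$site_missing > 0 || any(im > 0)) {
      alignments <- lapply(alignments, function(aln) {
        M <- aln$seqs
        if (config$site_missing > 0) {
          M[matrix(runif(length(M)) < config$site_missing, nrow(M))] <- "N"
        }
        for (sp in all_specs[im > 0]) {
          rows <- which(aln$specimen == sp)
          if (length(rows)) {
            M[rows, ][matrix(runif(length(rows) * ncol(M)) < im[[sp]],
                             length(rows))] <- "N"
          }
        }
        locus_alignment(aln$locus, M)
      })
    }
    Q_true <- matrix(0, length(all_specs), length(sampled_pops),
                     dimnames = list(all_specs, sampled_pops))
    Q_true[cbind(match(samples$specimen, all_specs),
                 match(samples$population, sampled_pops))] <- 1
    pmap <- samples
    if (!is.null(hybrids)) {
      for (i in seq_len(nrow(hybrids))) {
        h <- hybrids[i, ]
        qa <- switch(h$class, F1 = 0.5, BC1 = 0.75, clinal = h$q_a)
        Q_true[h$specimen, h$pop_a] <- qa
        Q_true[h$specimen, h$pop_b] <- 1 - qa
      }
      pmap <- bind_rows(pmap, tibble(specimen = hybrids$specimen,
                                     population = hybrids$pop_a))
    }
    pmap <- pmap %>%
      mutate(clade = sub("[0-9]+$", "", .data$population), geo_distinct = TRUE)
    ds <- structure(list(
      alignments = alignments, genotypes = NULL, gene_trees = gene_trees,
      Q_true = Q_true, population_map = pmap,
      mito_locus = if (is.null(config$mito_capture)) NA_character_ else locus_ids[1],
      config = config,
      provenance = list(seed = config$seed,
                        config_hash = rlang::hash(unclass(config)),
                        n_loci = config$n_loci,
                        populations = sampled_pops)
    ), class = "synthetic_dataset")
    if (!is.null(config$mito_capture)) {
      ds <- make_mito_capture_locus(ds, config$mito_capture$carriers,
                                    config$mito_capture$donor,
                                    seed = sample.int(2^30, 1))
    }
    ds$genotypes <- genotypes_from_alignments(ds$alignments)
    ds
  })
}

#' Rebuild the genotype matrix from a dataset's alignments
#'
#' Biallelic variable sites from the phased alignments with no filtering
#' beyond dropping fully missing and non-biallelic sites; used both to emit
#' the dataset's genotype matrix and to verify it is recomputable.
#'
#' @param alignments list of [locus_alignment()].
#' @return A [geno_matrix()].
#' @export
genotypes_from_alignments <- function(alignments) {
  specs <- unique(unlist(lapply(alignments, `[[`, "specimen")))
  extract_snps(alignments, specs, max_site_missing = 1,
               drop_singletons = FALSE)$genotypes
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d specimens, %d loci, %d SNPs%s\n",
              nrow(x$Q_true), length(x$alignments),
              if (is.null(x$genotypes)) 0L else ncol(x$genotypes$G),
              if (is.na(x$mito_locus)) "" else
                sprintf(", maternal locus '%s' captured", x$mito_locus)))
  invisible(x)
}

#' Replace the maternal locus of carrier individuals with donor haplotypes
#'
#' Emulates mitochondrial capture: each carrier's maternal locus (both stored
#' haplotype rows — the locus is effectively haploid) is replaced by a
#' captured haplotype derived from one donor individual's sequence, carrying
#' a shared set of post-capture substitutions (so carriers form their own
#' clade nested inside the donor lineage) plus a little private variation.
#' Nuclear loci are untouched.
#'
#' @param dataset a `synthetic_dataset`.
#' @param carrier_individuals specimen ids receiving the captured haplotype.
#' @param donor_population population supplying the haplotype.
#' @param seed integer seed.
#' @param shared_div,private_div per-site substitution probabilities for the
#'   shared (post-capture) and private mutation layers.
#' @return The modified `synthetic_dataset` (genotypes rebuilt).
#' @export
make_mito_capture_locus <- function(dataset, carrier_individuals,
                                    donor_population, seed = 1L,
                                    shared_div = 0.01, private_div = 0.002) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!length(carrier_individuals)) return(dataset)
  pmap <- dataset$population_map
  unknown <- setdiff(carrier_individuals, pmap$specimen)
  if (length(unknown)) {
    abort(sprintf("carrier(s) not in dataset: %s", paste(unknown, collapse = ", ")))
  }
  if (!donor_population %in% pmap$population) {
    abort(sprintf("donor population '%s' not in dataset", donor_population))
  }
  locus_id <- if (is.na(dataset$mito_locus)) dataset$alignments[[1]]$locus else
    dataset$mito_locus
  li <- which(vapply(dataset$alignments, `[[`, character(1), "locus") == locus_id)
  aln <- dataset$alignments[[li]]
  donor_specs <- pmap$specimen[pmap$population == donor_population]
  donor_row <- match(paste0(donor_specs[1], "|1"), rownames(aln$seqs))
  if (is.na(donor_row)) abort("donor haplotype missing from the maternal locus")
  withr_seed(seed, {
    base_seq <- aln$seqs[donor_row, ]
    L <- length(base_seq)
    mutate_at <- function(s, p) {
      hit <- which(runif(L) < p & s %in% BASES)
      s[hit] <- vapply(s[hit], function(b) sample(setdiff(BASES, b), 1), "")
      s
    }
    captured <- mutate_at(base_seq, shared_div)
    M <- aln$seqs
    for (sp in carrier_individuals) {
      hap <- mutate_at(captured, private_div)
      for (h in 1:2) {
        r <- match(paste0(sp, "|", h), rownames(M))
        if (!is.na(r)) M[r, ] <- hap
      }
    }
    dataset$alignments[[li]] <- locus_alignment(locus_id, M)
    dataset$mito_locus <- locus_id
    dataset$genotypes <- genotypes_from_alignments(dataset$alignments)
    dataset
  })
}
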