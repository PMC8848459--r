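#' Write a synthetic dataset to disk
#'
#' Emits the standard interchange files: one phased FASTA per locus
#' (haplotypes suffixed `|1` / `|2`), a VCF v4.2 of the genotype matrix
#' (diploid GT, `./.` for missing), the true gene trees as one Newick per
#' line, the population map as CSV, and a YAML provenance record carrying the
#' seed and config hash.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(file.path(dir, "loci"), recursive = TRUE, showWarnings = FALSE)
  for (aln in dataset$alignments) {
    path <- file.path(dir, "loci", paste0(aln$locus, ".fasta"))
    seqs <- apply(aln$seqs, 1, paste, collapse = "")
    writeLines(rbind(paste0(">", names(seqs)), seqs), path)
  }
  write_vcf(dataset$genotypes, file.path(dir, "genotypes.vcf"))
  ape::write.tree(dataset$gene_trees, file.path(dir, "gene_trees.nwk"))
  utils::write.csv(dataset$population_map,
                   file.path(dir, "population_map.csv"), row.names = FALSE)
  yaml::write_yaml(dataset$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Write a genotype matrix as VCF v4.2
#'
#' @param gm a [geno_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$specimens), collapse = "\t"))
  ref <- if ("ref" %in% names(gm$sites)) gm$sites$ref else rep("A", ncol(gm$G))
  alt <- if ("alt" %in% names(gm$sites)) gm$sites$alt else rep("T", ncol(gm$G))
  body <- vapply(seq_len(ncol(gm$G)), function(j) {
    g <- gm$G[, j]
    paste(c(gm$sites$locus[j], gm$sites$pos[j], gm$sites$site[j],
            ref[j], alt[j], ".", ".", ".", "GT",
            ifelse(is.na(g), "./.", gt_code[as.character(g)])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Reads diploid GT fields from a VCF (via the vcfR parser) into a
#' [geno_matrix()] coded by alternate-allele count, with the CHROM field as
#' the locus for jackknife blocking.
#'
#' @param path VCF file.
#' @return A [geno_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  rlang::check_installed("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  G <- t(apply(gt, 2, code))
  colnames(G) <- NULL
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sites <- tibble(site = ifelse(is.na(fix$ID) | fix$ID == ".",
                                paste0(fix$CHROM, ":", fix$POS), fix$ID),
                  locus = fix$CHROM, pos = as.integer(fix$POS),
                  ref = fix$REF, alt = fix$ALT)
  geno_matrix(G, sites, colnames(gt))
}

#' Read per-locus FASTA alignments
#'
#' @param paths FASTA files, one locus each; locus ids default to file names.
#' @return List of [locus_alignment()].
#' @export
read_alignments <- function(paths) {
  lapply(paths, function(p) {
    lines <- readLines(p)
    at <- grepl("^>", lines)
    ids <- sub("^>", "", lines[at])
    seq_idx <- cumsum(at)
    seqs <- vapply(seq_along(ids), function(i) {
      paste(lines[!at & seq_idx == i], collapse = "")
    }, character(1))
    names(seqs) <- ids
    locus_alignment(sub("\\.(fa|fasta)$", "", basename(p)), seqs)
  })
}
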