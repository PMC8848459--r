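#' Apply the delimitation rubric to clusters, tree and hybrid calls
#'
#' Rule engine turning genetic clusters, a specimen tree, hybrid
#' classifications and prior candidate-species labels into a candidate table.
#' Reciprocal monophyly of geographically distinct clusters is the strongest
#' evidence for candidate species; the rules fire in order:
#'
#' * **R1 (lump)** — prior candidates merged into a single cluster and not
#'   reciprocally monophyletic become one lumped candidate named by joining
#'   the prior labels.
#' * **R2 (promote)** — clusters that are reciprocally monophyletic and
#'   geographically distinct become candidate species (status `split` when
#'   they subdivide a prior candidate, `kept` when they match one).
#' * **R3 (lineages)** — clusters distinct in ancestry but non-monophyletic,
#'   with admixture clines between them (at least `hybrid_frac` of the
#'   enclosing candidate's members classified hybrid), become phylogeographic
#'   lineages within the enclosing candidate.
#' * **R4 (hybrid flag)** — candidates none of whose members has a majority
#'   (`q_max >= majority`) single-source ancestry are flagged as putative
#'   hybrid clusters.
#'
#' A cluster spanning multiple disjoint (each monophyletic) prior clades with
#' neither monophyly nor admixture evidence is reported `unresolved`, never
#' silently assigned. Output is deterministic and invariant to input row
#' order.
#'
#' @param tree specimen-level `phylo`.
#' @param assignments tibble: `specimen`, `cluster`, optional `prior`
#'   (prior candidate label), optional `geo_distinct` (logical, default TRUE),
#'   optional `clade`.
#' @param hybrid_calls output of [classify_hybrids()] (needs `specimen`,
#'   `class`, `q_max`).
#' @param hybrid_frac fraction of members that must be hybrid-classified to
#'   count as an admixture cline (default 0.10).
#' @param majority majority-ancestry threshold for the hybrid-cluster flag
#'   (default 0.5).
#' @return A tibble (`candidate_table`): `clade`, `candidate`, `lineage`,
#'   `status`, `n_members`, `members` (list), `evidence`.
#' @export
delimit <- function(tree, assignments, hybrid_calls = NULL,
                    hybrid_frac = 0.10, majority = 0.5) {
  assignments <- as_tibble(assignments) %>% arrange(.data$specimen)
  if (!"prior" %in% names(assignments)) assignments$prior <- assignments$cluster
  if (!"geo_distinct" %in% names(assignments)) assignments$geo_distinct <- TRUE
  if (!"clade" %in% names(assignments)) assignments$clade <- "-"
  if (anyNA(assignments$cluster)) abort("every specimen needs a cluster")
  missing_tips <- setdiff(assignments$specimen, tree$tip.label)
  if (length(missing_tips)) {
    abort(sprintf("specimens absent from tree: %s",
                  paste(missing_tips, collapse = ", ")))
  }
  if (is.null(hybrid_calls)) {
    hybrid_calls <- tibble(specimen = assignments$specimen,
                           class = "pure", q_max = 1)
  }
  hc <- as_tibble(hybrid_calls)
  members_of <- function(col, value) {
    sort(assignments$specimen[assignments[[col]] == value])
  }
  mono <- function(members) {
    length(members) >= 1 && is_monophyletic(tree, members)
  }
  hybrid_count <- function(members) {
    sum(hc$class[hc$specimen %in% members] == "hybrid")
  }
  all_minority <- function(members) {
    qm <- hc$q_max[hc$specimen %in% members]
    length(qm) > 0 && all(qm < majority)
  }
  clusters <- sort(unique(assignments$cluster))
  priors <- sort(unique(assignments$prior))
  cluster_mono <- setNames(vapply(clusters, function(cl) mono(members_of("cluster", cl)),
                                  logical(1)), clusters)
  prior_mono <- setNames(vapply(priors, function(p) mono(members_of("prior", p)),
                                logical(1)), priors)
  cluster_geo <- setNames(vapply(clusters, function(cl) {
    all(assignments$geo_distinct[assignments$cluster == cl])
  }, logical(1)), clusters)
  # connected components of the cluster <-> prior bipartite overlap graph:
  # each component is decided as one unit
  overlap <- assignments %>% distinct(.data$cluster, .data$prior)
  comp_of <- local({
    ids <- c(paste0("c\r", clusters), paste0("p\r", priors))
    comp <- setNames(seq_along(ids), ids)
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(overlap))) {
        a <- paste0("c\r", overlap$cluster[i]); b <- paste0("p\r", overlap$prior[i])
        m <- min(comp[a], comp[b])
        if (comp[a] != m || comp[b] != m) { comp[a] <- m; comp[b] <- m; changed <- TRUE }
      }
      if (!changed) break
    }
    comp
  })
  rows <- list()
  emit <- function(clade, candidate, lineage, status, members, evidence) {
    rows[[length(rows) + 1L]] <<- tibble(
      clade = clade, candidate = candidate, lineage = lineage,
      status = status, n_members = length(members),
      members = list(members), evidence = evidence)
  }
  for (cid in unique(comp_of[paste0("c\r", clusters)])) {
    comp_clusters <- clusters[comp_of[paste0("c\r", clusters)] == cid]
    comp_priors <- priors[comp_of[paste0("p\r", priors)] == cid]
    comp_members <- sort(unique(unlist(lapply(comp_clusters, members_of,
                                              col = "cluster"))))
    clade_lab <- sort(unique(assignments$clade[assignments$specimen %in% comp_members]))[1]
    if (length(comp_clusters) == 1 && length(comp_priors) > 1) {
      # R1: several priors collapsed into one cluster
      lumped_name <- paste(comp_priors, collapse = "/")
      priors_all_mono <- all(prior_mono[comp_priors])
      cl_mono <- cluster_mono[[comp_clusters]]
      admixed <- hybrid_count(comp_members) >= hybrid_frac * length(comp_members)
      if (!priors_all_mono || cl_mono || admixed) {
        emit(clade_lab, lumped_name, "-", "lumped", comp_members,
             sprintf("priors %s form one cluster%s",
                     paste(comp_priors, collapse = " + "),
                     if (!priors_all_mono) ", interdigitated on the tree" else ""))
      } else {
        emit(clade_lab, lumped_name, "-", "unresolved", comp_members,
             "one cluster spans disjoint monophyletic prior clades without admixture evidence")
      }
    } else if (length(comp_clusters) == 1) {
      # one cluster <-> (at most) one prior
      cl <- comp_clusters
      status <- if (length(comp_priors) &&
                    setequal(comp_members, members_of("prior", comp_priors[1]))) {
        "kept"
      } else "new"
      note <- if (cluster_mono[[cl]]) "reciprocally monophyletic" else
        "not monophyletic on the tree"
      emit(clade_lab, if (length(comp_priors)) comp_priors[1] else cl,
           "-", status, comp_members, note)
    } else {
      # one or more priors subdivided into several clusters
      promoted <- comp_clusters[cluster_mono[comp_clusters] &
                                  cluster_geo[comp_clusters]]
      residual <- setdiff(comp_clusters, promoted)
      res_members <- sort(unique(unlist(lapply(residual, members_of,
                                               col = "cluster"))))
      admixed <- length(res_members) > 0 &&
        hybrid_count(res_members) >= hybrid_frac * length(res_members)
      if (length(residual) >= 2 && !admixed && all(prior_mono[comp_priors])) {
        # distinct in ancestry, non-monophyletic, no cline: cannot be placed
        for (cl in residual) {
          emit(clade_lab, cl, "-", "unresolved", members_of("cluster", cl),
               "non-monophyletic cluster without admixture evidence")
        }
        residual <- character()
      }
      for (cl in promoted) {
        m <- members_of("cluster", cl)
        pr <- unique(assignments$prior[assignments$cluster == cl])
        status <- if (length(pr) == 1 && setequal(m, members_of("prior", pr)))
          "kept" else "split"
        emit(clade_lab, cl, "-", status, m,
             "reciprocally monophyletic, geographically distinct")
      }
      if (length(residual)) {
        cand_name <- paste(sort(unique(
          assignments$prior[assignments$cluster %in% residual])), collapse = "/")
        if (length(residual) == 1) {
          emit(clade_lab, cand_name, "-", "kept",
               members_of("cluster", residual),
               "single residual cluster of its prior candidate")
        } else {
          emit(clade_lab, cand_name, paste(residual, collapse = ","),
               "kept", res_members,
               sprintf("%d intergrading phylogeographic lineages (%.0f%% hybrids)",
                       length(residual),
                       100 * hybrid_count(res_members) / length(res_members)))
        }
      }
    }
  }
  out <- bind_rows(rows)
  # R4: hybrid-cluster flag
  out$status <- ifelse(
    vapply(out$members, all_minority, logical(1)) & out$status != "unresolved",
    "hybrid-flagged", out$status)
  out %>% arrange(.data$clade, .data$candidate)
}
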