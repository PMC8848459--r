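#' Match ancestry clusters to labeled populations
#'
#' Resolves the label-switching of an ancestry fit against a-priori population
#' assignments by maximizing the summed mean ancestry of each population in
#' its matched cluster: exhaustive best-permutation for K <= 8, greedy
#' maximal assignment above.
#'
#' @param Q specimens x K ancestry matrix with specimen rownames.
#' @param assignments tibble (`specimen`, `population`); the number of
#'   distinct populations must equal K (extra clusters stay unlabeled).
#' @return Character vector of length K: the population label matched to each
#'   cluster (NA for unmatched clusters).
#' @export
match_clusters <- function(Q, assignments) {
  assignments <- as_tibble(assignments)
  pops <- unique(assignments$population)
  K <- ncol(Q)
  # mean ancestry of each labeled population in each cluster
  Mq <- t(vapply(pops, function(p) {
    sp <- assignments$specimen[assignments$population == p]
    colMeans(Q[rownames(Q) %in% sp, , drop = FALSE])
  }, numeric(K)))
  if (!is.matrix(Mq)) Mq <- matrix(Mq, nrow = length(pops))
  labels <- rep(NA_character_, K)
  if (length(pops) <= K && K <= 8 && length(pops) == K) {
    perms <- all_permutations(K)
    score <- vapply(perms, function(pm) sum(Mq[cbind(seq_len(K), pm)]),
                    numeric(1))
    best <- perms[[which.max(score)]]
    labels[best] <- pops
  } else {
    M <- Mq
    for (i in seq_len(min(length(pops), K))) {
      ij <- which(M == max(M), arr.ind = TRUE)[1, ]
      labels[ij[2]] <- pops[ij[1]]
      M[ij[1], ] <- -Inf; M[, ij[2]] <- -Inf
    }
  }
  labels
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    sub <- all_permutations(n - 1L)
    out <- c(out, lapply(sub, function(p) c(i, ifelse(p >= i, p + 1L, p))))
  }
  out
}

#' Classify hybrid individuals from ancestry coefficients
#'
#' Deterministic labeling from a fitted `Q` matrix: an individual is a
#' `hybrid` when its largest secondary ancestry exceeds the hybrid threshold
#' (default > 0.20), `notable` when the secondary ancestry is in
#' (0.10, 0.20], and a `streak` carrier when minor ancestry totalling at least
#' 0.10 is spread over >= 3 clusters each individually below 0.10.
#' `highly_admixed` (maximum individual ancestry <= 0.8) is reported as an
#' orthogonal flag since it co-occurs with the hybrid class.
#'
#' @param fit an [fit_snmf()] result (or any object with a `Q` matrix).
#' @param assignments optional tibble (`specimen`, `population`) used to name
#'   clusters via [match_clusters()]; cluster columns are otherwise `q1..qK`.
#' @param thresholds named list overriding `hybrid` (0.20), `notable` (0.10),
#'   `q_max` (0.8) and `streak` (0.10).
#' @return Tibble with one row per specimen: `specimen`, `primary` (cluster or
#'   matched population), `q_max`, `secondary`, `class` (pure / notable /
#'   hybrid / streak), `highly_admixed`.
#' @export
classify_hybrids <- function(fit, assignments = NULL,
                             thresholds = list()) {
  th <- utils::modifyList(
    list(hybrid = 0.20, notable = 0.10, q_max = 0.8, streak = 0.10),
    thresholds)
  Q <- if (inherits(fit, "snmf_fit")) fit$Q else as.matrix(fit)
  K <- ncol(Q)
  cluster_names <- colnames(Q)
  if (is.null(cluster_names)) cluster_names <- paste0("q", seq_len(K))
  if (!is.null(assignments)) {
    lab <- match_clusters(Q, assignments)
    if (K != length(lab)) abort("cluster count mismatch with assignments")
    cluster_names <- ifelse(is.na(lab), cluster_names, lab)
  }
  purrr::map_dfr(seq_len(nrow(Q)), function(i) {
    q <- Q[i, ]
    pk <- which.max(q)
    minor <- q[-pk]
    secondary <- if (length(minor)) max(minor) else 0
    is_hybrid <- secondary > th$hybrid
    is_notable <- !is_hybrid && secondary > th$notable
    small <- minor[minor < th$notable]
    is_streak <- !is_hybrid && !is_notable &&
      length(small) >= 3 && sum(minor) >= th$streak
    tibble(specimen = rownames(Q)[i],
           primary = cluster_names[pk],
           q_max = q[pk], secondary = secondary,
           class = if (is_hybrid) "hybrid" else if (is_notable) "notable"
           else if (is_streak) "streak" else "pure",
           highly_admixed = q[pk] <= th$q_max)
  })
}
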