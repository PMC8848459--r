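#' Estimate individual ancestry coefficients by regularized NMF
#'
#' Fits the sparse nonnegative matrix factorization model of ancestry: the
#' one-hot expanded genotype matrix `X` (three indicator columns per site,
#' missing genotypes all-zero and excluded from the loss) is approximated by
#' `Q %*% G`, where rows of `Q` (specimen ancestry coefficients) live on the
#' K-simplex and each per-site 3-column block of `G` (cluster genotype-class
#' frequencies) is a probability simplex. Optimization is alternating ridge
#' least squares with simplex projection; a backtracking damping step makes
#' the observed-entry training objective non-increasing at every iteration.
#' Missing (and held-out) entries are imputed EM-style with the current
#' reconstruction. A fraction of non-missing entries can be masked before
#' fitting; the cross-entropy on those entries is the model-choice criterion.
#'
#' @param gm a [geno_matrix()], typically after QC filtering.
#' @param K number of ancestry clusters (1 <= K <= specimens).
#' @param alpha nonnegative ridge penalty on `Q` (regularization weight).
#' @param masking fraction of non-missing entries to hold out for validation
#'   (0 disables masking; must be < 0.5).
#' @param max_iter,tol iteration cap and relative-loss convergence tolerance.
#' @param seed integer seed controlling initialization and masking.
#' @param restarts independent initializations; the fit with the lowest final
#'   training objective is returned (default 3 — the alternating scheme can
#'   stall in a poor local optimum from an unlucky start, which the training
#'   loss identifies reliably). The held-out mask is shared across restarts.
#' @return An object of class `snmf_fit`: `Q` (specimens x K, rows sum to 1),
#'   `G` (K x 3*sites), `loss` (per-iteration training objective),
#'   `ce_train`, `ce_masked` (NA when `masking = 0`), `alpha`, `K`, `seed`,
#'   `converged`, `masked` (held-out entry indices).
#' @export
fit_snmf <- function(gm, K, alpha = 10, masking = 0, max_iter = 200,
                     tol = 1e-6, seed = 1L, restarts = 3) {
  stopifnot(inherits(gm, "geno_matrix"))
  n <- nrow(gm$G); L <- ncol(gm$G)
  if (K < 1 || K > n) abort("K must be between 1 and the number of specimens")
  if (alpha < 0) abort("alpha must be nonnegative")
  if (masking < 0 || masking >= 0.5) abort("masking fraction must be in [0, 0.5)")
  withr_seed(seed, {
    obs <- !is.na(gm$G)
    masked <- NULL
    if (masking > 0) {
      cand <- which(obs)
      masked <- sort(sample(cand, max(1L, round(masking * length(cand)))))
      obs[masked] <- FALSE
    }
    X <- onehot_expand(gm$G, obs)
    obs3 <- obs[, rep(seq_len(L), each = 3), drop = FALSE]
    pooled <- pooled_geno_freqs(gm$G, obs)
    midx <- which(!obs3)
    loss_fn <- function(Q, G) {
      R <- X - Q %*% G
      sum(R * R) - sum(R[midx]^2) + alpha * sum(Q^2)
    }
    fit_once <- function() {
      Q <- matrix(rgamma(n * K, 1), n, K)
      Q <- Q / rowSums(Q)
      G <- matrix(rep(as.vector(t(pooled)), each = K), K, 3L * L) +
        matrix(runif(K * 3 * L, 0, 0.1), K)
      G <- project_g_blocks(G)
      loss <- loss_fn(Q, G)
      trace <- loss
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        pred <- Q %*% G
        Xc <- X
        Xc[midx] <- pred[midx]
        Gp <- project_g_blocks(solve(crossprod(Q) + 1e-8 * diag(K),
                                     crossprod(Q, Xc)))
        Qp <- proj_simplex_rows(t(solve(tcrossprod(Gp) + (alpha + 1e-8) * diag(K),
                                        tcrossprod(Gp, Xc))))
        theta <- 1
        repeat {
          Qn <- (1 - theta) * Q + theta * Qp
          Gn <- (1 - theta) * G + theta * Gp
          new_loss <- loss_fn(Qn, Gn)
          if (new_loss <= loss || theta < 1e-4) break
          theta <- theta / 2
        }
        if (new_loss > loss) { converged <- TRUE; break }
        rel <- (loss - new_loss) / max(loss, 1e-12)
        Q <- Qn; G <- Gn; loss <- new_loss
        trace <- c(trace, loss)
        if (rel < tol) { converged <- TRUE; break }
      }
      list(Q = Q, G = G, trace = trace, converged = converged)
    }
    best <- fit_once()
    if (restarts > 1) {
      for (r in seq_len(restarts - 1)) {
        cand_fit <- fit_once()
        if (tail(cand_fit$trace, 1) < tail(best$trace, 1)) best <- cand_fit
      }
    }
    Q <- best$Q; G <- best$G
    rownames(Q) <- gm$specimens
    colnames(Q) <- paste0("q", seq_len(K))
    fit <- structure(list(Q = Q, G = G, loss = best$trace, alpha = alpha,
                          K = K, seed = seed, converged = best$converged,
                          masked = masked, sites = gm$sites),
                     class = "snmf_fit")
    fit$ce_train <- cross_entropy(fit, gm, entries = which(obs))
    fit$ce_masked <- if (is.null(masked)) NA_real_ else
      cross_entropy(fit, gm, entries = masked)
    fit
  })
}

onehot_expand <- function(G, obs) {
  n <- nrow(G); L <- ncol(G)
  X <- matrix(0, n, 3L * L)
  ij <- which(obs, arr.ind = TRUE)
  X[cbind(ij[, 1], 3L * (ij[, 2] - 1L) + G[ij] + 1L)] <- 1
  X
}

pooled_geno_freqs <- function(G, obs) {
  L <- ncol(G)
  t(vapply(seq_len(L), function(j) {
    g <- G[obs[, j], j]
    if (!length(g)) return(rep(1 / 3, 3))
    (tabulate(g + 1L, 3L) + 0.5) / (length(g) + 1.5)
  }, numeric(3)))
}

# Euclidean projection of each row onto the probability simplex (vectorized:
# per-row descending sort via order(row, -value), prefix property gives rho)
proj_simplex_rows <- function(M) {
  K <- ncol(M)
  if (K == 1) return(matrix(1, nrow(M), 1))
  n <- nrow(M)
  S <- matrix(M[order(row(M), -M)], nrow = n, byrow = TRUE)
  cs <- S %*% upper.tri(diag(K), diag = TRUE)
  k <- matrix(rep(seq_len(K), each = n), n)
  rho <- rowSums(S - (cs - 1) / k > 0)
  tau <- (cs[cbind(seq_len(n), rho)] - 1) / rho
  out <- pmax(M - tau, 0)
  out / rowSums(out)
}

project_g_blocks <- function(G) {
  K <- nrow(G); L3 <- ncol(G)
  stopifnot(L3 %% 3 == 0)
  B <- matrix(t(G), nrow = 3)            # 3 x (L * K), site blocks stacked
  P <- t(proj_simplex_rows(t(B)))
  matrix(P, nrow = K, byrow = TRUE)
}

#' @export
print.snmf_fit <- function(x, ...) {
  cat(sprintf("<snmf_fit> K = %d, alpha = %g, %d specimens x %d sites; CE(train) = %.4f%s\n",
              x$K, x$alpha, nrow(x$Q), ncol(x$G) / 3, x$ce_train,
              if (is.na(x$ce_masked)) "" else sprintf(", CE(masked) = %.4f", x$ce_masked)))
  invisible(x)
}

#' @export
tidy.snmf_fit <- function(x, ...) {
  as_tibble(x$Q) %>%
    mutate(specimen = rownames(x$Q), .before = 1) %>%
    tidyr::pivot_longer(-"specimen", names_to = "cluster", values_to = "q")
}

#' @export
glance.snmf_fit <- function(x, ...) {
  tibble(K = x$K, alpha = x$alpha, iterations = length(x$loss) - 1,
         converged = x$converged, ce_train = x$ce_train,
         ce_masked = x$ce_masked, loss = x$loss[length(x$loss)])
}

#' Ancestry barplot for a fitted ancestry model
#'
#' Stacked per-specimen ancestry proportions, specimens ordered by assigned
#' cluster and then by their maximum ancestry coefficient (the usual
#' admixture-barplot ordering).
#'
#' @param object an `snmf_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.snmf_fit <- function(object, ...) {
  ord <- order(max.col(object$Q), -apply(object$Q, 1, max))
  df <- tidy(object) %>%
    mutate(specimen = factor(.data$specimen,
                             levels = rownames(object$Q)[ord]))
  ggplot2::ggplot(df, ggplot2::aes(.data$specimen, .data$q, fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "ancestry coefficient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Masked-genotype cross-entropy of an ancestry fit
#'
#' `CE = -mean(log P(observed genotype))` over the given entries, where the
#' per-genotype-class probabilities are the corresponding 3-block of
#' `Q %*% G`, clipped to `[1e-10, 1]`.
#'
#' @param fit an [fit_snmf()] result.
#' @param gm the genotype matrix the fit was made from.
#' @param entries integer vector of entry indices into `gm$G` (defaults to the
#'   fit's held-out masked entries).
#' @return Scalar cross-entropy (nats).
#' @export
cross_entropy <- function(fit, gm, entries = fit$masked) {
  stopifnot(inherits(fit, "snmf_fit"), inherits(gm, "geno_matrix"))
  if (is.null(entries) || !length(entries)) abort("no masked entries to score")
  ij <- arrayInd(entries, dim(gm$G))
  g <- gm$G[entries]
  if (anyNA(g)) abort("cross-entropy entries must have observed genotypes")
  pred <- fit$Q %*% fit$G
  probs <- pred[cbind(ij[, 1], 3L * (ij[, 2] - 1L) + g + 1L)]
  -mean(log(pmin(pmax(probs, 1e-10), 1)))
}

#' Choose the regularization weight by median masked cross-entropy
#'
#' Fits `reps` replicates (fresh mask and initialization per replicate) for
#' each candidate weight and returns the weight minimizing the median
#' held-out cross-entropy, breaking exact ties toward the smallest (weakest)
#' regularization.
#'
#' @param gm a [geno_matrix()].
#' @param K cluster count.
#' @param grid candidate weights; default spans several orders of magnitude.
#' @param reps replicates per weight (the protocol value is 100; reduce for
#'   quick looks).
#' @param masking held-out fraction per replicate (default 0.05).
#' @param seed base seed; replicate r of weight i uses a distinct stream.
#' @param max_iter,tol per-replicate fit budget; selection fits default to a
#'   lighter budget than a final fit since only relative cross-entropy
#'   matters.
#' @param ... passed to [fit_snmf()].
#' @return Object of class `alpha_selection`: `alpha` (chosen), `ce` (tibble:
#'   alpha, rep, ce), `medians`.
#' @export
select_alpha <- function(gm, K, grid = c(1, 5, 10, 50, 100, 500, 1000),
                         reps = 100, masking = 0.05, seed = 1L,
                         max_iter = 80, tol = 1e-5, ...) {
  if (!length(grid)) abort("alpha grid must be non-empty")
  ce <- purrr::map_dfr(seq_along(grid), function(i) {
    purrr::map_dfr(seq_len(reps), function(r) {
      fit <- fit_snmf(gm, K, alpha = grid[i], masking = masking,
                      seed = seed + 1000L * i + r, restarts = 1,
                      max_iter = max_iter, tol = tol, ...)
      tibble(alpha = grid[i], rep = r, ce = fit$ce_masked)
    })
  })
  med <- ce %>% group_by(.data$alpha) %>%
    summarise(median_ce = median(.data$ce), .groups = "drop") %>%
    arrange(.data$alpha)
  best <- med$alpha[which.min(med$median_ce)]  # first minimum = smallest alpha
  structure(list(alpha = best, ce = ce, medians = med),
            class = "alpha_selection")
}

#' @export
print.alpha_selection <- function(x, ...) {
  cat(sprintf("<alpha_selection> alpha* = %g (median CE %.4f over %d reps)\n",
              x$alpha, min(x$medians$median_ce),
              max(x$ce$rep)))
  invisible(x)
}

#' @export
autoplot.alpha_selection <- function(object, ...) {
  ggplot2::ggplot(object$ce,
                  ggplot2::aes(factor(.data$alpha), .data$ce)) +
    ggplot2::geom_boxplot(notch = TRUE) +
    ggplot2::labs(x = expression(alpha), y = "masked cross-entropy") +
    ggplot2::theme_minimal()
}

#' Choose the number of ancestry clusters
#'
#' Primary rule: the elbow of the median masked cross-entropy curve (the K
#' with the largest positive second difference of medians, provided the curve
#' decreases into it). When no elbow forms, falls back to the boxplot notch
#' rule: the smallest K whose notch interval (median +/- 1.57 IQR / sqrt(reps),
#' approximating a 95% interval for the median) does not overlap that of K-1
#' while K+1's overlaps K's. If neither rule fires, returns the argmin of the
#' median curve with `no_elbow = TRUE`.
#'
#' @param gm a [geno_matrix()].
#' @param K_range contiguous integer range of K values (>= 2 values).
#' @param alpha regularization weight (e.g. from [select_alpha()]).
#' @param reps replicates per K.
#' @param masking held-out fraction per replicate.
#' @param seed base seed.
#' @param max_iter,tol per-replicate fit budget (see [select_alpha()]).
#' @param ... passed to [fit_snmf()].
#' @return Object of class `K_selection`: `K` (chosen), `rule` ("elbow",
#'   "notch" or "argmin"), `no_elbow` flag, `ce` (tibble), `medians` (with
#'   notch bounds).
#' @export
select_K <- function(gm, K_range, alpha = 10, reps = 20, masking = 0.05,
                     seed = 1L, max_iter = 80, tol = 1e-5, ...) {
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) < 2 || any(diff(K_range) != 1)) {
    abort("K_range must be a contiguous range of at least 2 values")
  }
  ce <- purrr::map_dfr(K_range, function(K) {
    purrr::map_dfr(seq_len(reps), function(r) {
      fit <- fit_snmf(gm, K, alpha = alpha, masking = masking,
                      seed = seed + 1000L * K + r, restarts = 1,
                      max_iter = max_iter, tol = tol, ...)
      tibble(K = K, rep = r, ce = fit$ce_masked)
    })
  })
  med <- ce %>% group_by(.data$K) %>%
    summarise(median_ce = median(.data$ce), iqr = stats::IQR(.data$ce),
              .groups = "drop") %>%
    arrange(.data$K) %>%
    mutate(notch_lo = .data$median_ce - 1.57 * .data$iqr / sqrt(reps),
           notch_hi = .data$median_ce + 1.57 * .data$iqr / sqrt(reps))
  m <- med$median_ce
  chosen <- NA_integer_; rule <- "argmin"; no_elbow <- TRUE
  if (length(m) >= 3) {
    d2 <- m[-c(length(m) - 1, length(m))] - 2 * m[-c(1, length(m))] +
      m[-c(1, 2)]
    cand <- which(d2 > 0 & diff(m)[seq_along(d2)] < 0)
    if (length(cand)) {
      chosen <- K_range[cand[which.max(d2[cand])] + 1L]
      rule <- "elbow"; no_elbow <- FALSE
    }
  }
  if (is.na(chosen)) {
    for (i in seq_along(K_range)[-1]) {
      sep_prev <- med$notch_lo[i] > med$notch_hi[i - 1] ||
        med$notch_hi[i] < med$notch_lo[i - 1]
      improves <- med$median_ce[i] < med$median_ce[i - 1]
      next_overlaps <- i == length(K_range) ||
        !(med$notch_lo[i + 1] > med$notch_hi[i] ||
            med$notch_hi[i + 1] < med$notch_lo[i])
      if (sep_prev && improves && next_overlaps) {
        chosen <- K_range[i]; rule <- "notch"
        break
      }
    }
  }
  if (is.na(chosen)) chosen <- K_range[which.min(m)]
  structure(list(K = chosen, rule = rule, no_elbow = no_elbow,
                 ce = ce, medians = med),
            class = "K_selection")
}

#' @export
print.K_selection <- function(x, ...) {
  cat(sprintf("<K_selection> K* = %d by %s rule%s\n", x$K, x$rule,
              if (x$no_elbow) " (no elbow in the median CE curve)" else ""))
  invisible(x)
}

#' @export
autoplot.K_selection <- function(object, ...) {
  ggplot2::ggplot(object$ce, ggplot2::aes(factor(.data$K), .data$ce)) +
    ggplot2::geom_boxplot(notch = TRUE) +
    ggplot2::geom_vline(xintercept = match(object$K, sort(unique(object$ce$K))),
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "K", y = "masked cross-entropy") +
    ggplot2::theme_minimal()
}
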