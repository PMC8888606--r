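#' Polarity-invariant modified k-means clustering of topographies
#'
#' Clusters scalp maps into `k` template topographies treating a map and its
#' sign-flipped copy as the same state. Each map is assigned to the template
#' with the largest squared spatial correlation; each template is then
#' replaced by the dominant eigenvector of the (GFP^2-weighted) scatter of
#' its assigned, unit-normalized maps — the polarity-invariant mean. Both
#' steps increase the global explained variance (GEV), which is the
#' convergence and restart-selection objective; the best of `n_restarts`
#' random initializations is returned.
#'
#' Maps with zero global field power are excluded from clustering (their
#' label is `NA`) rather than raising an error. An empty cluster during
#' iteration is re-seeded from the currently worst-fitting map.
#'
#' @param maps Numeric matrix, channels x maps; columns are topographies
#'   (average-referenced, or referenceable — the channel mean is removed).
#' @param k Number of clusters (`k >= 1`).
#' @param weights Per-map weights used in GEV and the template update;
#'   default is squared GFP.
#' @param n_restarts Number of random restarts.
#' @param max_iter Maximum sweeps per restart.
#' @param tol Relative GEV improvement below which a restart stops.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param warm_start Optional channels x k template matrix evaluated as one
#'   additional restart (used by [select_k_for_erp()] to warm-start each k
#'   from the best k-1 solution, which keeps the dispersion curve W(k)
#'   smooth for the Krzanowski-Lai criterion).
#' @return An object of class `ms_clustering` with elements `templates`
#'   (channels x k, unit-norm, zero-mean), `labels` (per input map, `NA` for
#'   excluded maps), `polarity` (+1/-1 aligning each map to its template),
#'   `gev`, `dispersion_W`, `n_iter`, `k`, `seed`, `excluded`.
#' @export
modified_kmeans <- function(maps, k, weights = NULL, n_restarts = 64,
                            max_iter = 300, tol = 1e-7, seed = NULL,
                            warm_start = NULL) {
  maps <- as.matrix(maps)
  if (k < 1) stop("k must be at least 1")
  nm <- .normalized_maps(maps)
  V <- nm$V[, nm$ok, drop = FALSE]
  N <- ncol(V)
  if (N < k) stop("k exceeds the number of usable maps")
  if (.n_distinct_maps(V) < k)
    stop("k exceeds the number of distinct maps")
  if (is.null(weights)) weights <- nm$gfp^2
  if (length(weights) != ncol(maps))
    stop("weights must have one entry per map")
  w <- weights[nm$ok]
  if (all(w == 0)) stop("all map weights (GFP) are zero")

  warm <- matrix(numeric(0), 0, 0)
  if (!is.null(warm_start)) {
    warm <- as.matrix(warm_start)
    if (nrow(warm) != nrow(V) || ncol(warm) != k)
      stop("warm_start must be a channels x k matrix")
    warm <- sweep(warm, 2, colMeans(warm), "-")
    warm <- sweep(warm, 2, pmax(sqrt(colSums(warm^2)), 1e-300), "/")
  }
  run <- function() {
    inits <- replicate(n_restarts, sample.int(N, k)) # k x R (or vector k=1)
    inits <- matrix(as.integer(inits) - 1L, nrow = k)
    mk_kmeans_engine(V, w, inits, as.integer(max_iter), tol, warm)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  templates <- res$templates
  lab <- as.integer(res$labels)
  corr <- crossprod(templates, V)                    # signed r, k x N
  pol <- sign(corr[cbind(lab, seq_len(N))])
  pol[pol == 0] <- 1

  labels <- rep(NA_integer_, ncol(maps))
  labels[nm$ok] <- lab
  polarity <- rep(NA_real_, ncol(maps))
  polarity[nm$ok] <- pol

  W <- sum(2 - 2 * abs(corr[cbind(lab, seq_len(N))]))

  structure(list(templates = templates, labels = labels, polarity = polarity,
                 gev = res$gev, dispersion_W = W, n_iter = res$n_iter,
                 k = k, seed = seed, excluded = which(!nm$ok)),
            class = "ms_clustering")
}

#' @export
print.ms_clustering <- function(x, ...) {
  cat(sprintf(
    "<ms_clustering> k = %d, %d maps, GEV = %.4f, W = %.4g, %d iterations\n",
    x$k, sum(!is.na(x$labels)), x$gev, x$dispersion_W, x$n_iter))
  invisible(x)
}

# distinct maps up to sign and amplitude, judged on unit-normalized columns
.n_distinct_maps <- function(V, tol = 1e-10) {
  if (ncol(V) == 0) return(0L)
  S <- abs(crossprod(V))
  keep <- rep(TRUE, ncol(V))
  for (j in seq_len(ncol(V))[-1])
    if (any(S[seq_len(j - 1), j] > 1 - tol & keep[seq_len(j - 1)]))
      keep[j] <- FALSE
  sum(keep)
}

#' Global explained variance of a labeling
#'
#' `GEV = sum_t GFP_t^2 r_t^2 / sum_t GFP_t^2`, where `r_t` is the
#' polarity-ignored spatial correlation between map `t` and the template of
#' its assigned cluster.
#'
#' @param maps Channels x maps matrix.
#' @param templates Channels x k template matrix (unit-norm columns).
#' @param labels Integer cluster index per map (`NA` allowed; such maps are
#'   skipped).
#' @param weights Per-map weights; default squared GFP.
#' @return Scalar in `[0, 1]`.
#' @export
global_explained_variance <- function(maps, templates, labels,
                                      weights = NULL) {
  maps <- as.matrix(maps)
  nm <- .normalized_maps(maps)
  if (is.null(weights)) weights <- nm$gfp^2
  use <- nm$ok & !is.na(labels)
  if (!any(use) || all(weights[use] == 0))
    stop("global explained variance undefined: all usable GFP are zero")
  V <- nm$V[, use, drop = FALSE]
  lab <- labels[use]
  r <- colSums(V * as.matrix(templates)[, lab, drop = FALSE])
  sum(weights[use] * r^2) / sum(weights[use])
}

#' Within-cluster dispersion W(k)
#'
#' `W = sum_clusters sum_members || s_m vhat_m - template ||^2` over the
#' unit-normalized member maps with their polarity signs `s_m`. Feeds the
#' Krzanowski-Lai criterion.
#'
#' @inheritParams global_explained_variance
#' @param polarity Sign (+1/-1) aligning each map to its template; when
#'   `NULL`, the polarity maximizing agreement is used.
#' @return Nonnegative scalar.
#' @export
within_dispersion <- function(maps, templates, labels, polarity = NULL) {
  maps <- as.matrix(maps)
  templates <- as.matrix(templates)
  nm <- .normalized_maps(maps)
  use <- nm$ok & !is.na(labels)
  V <- nm$V[, use, drop = FALSE]
  lab <- labels[use]
  r <- colSums(V * templates[, lab, drop = FALSE])
  s <- if (is.null(polarity)) {
    si <- sign(r); si[si == 0] <- 1; si
  } else {
    polarity[use]
  }
  sum(2 - 2 * s * r)
}
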