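#' Krzanowski-Lai criterion over a range of cluster numbers
#'
#' From within-cluster dispersions `W(k)` computed on a contiguous k range
#' starting at 1, builds `DIFF(k) = (k-1)^(2/p) W(k-1) - k^(2/p) W(k)` and
#' `KL(k) = |DIFF(k) / DIFF(k+1)|` (`p` = data dimensionality, here the
#' channel count). Candidate cluster numbers are the local maxima of the KL
#' curve; the selection rule decides among them:
#'
#' * `"second_max"` — local maxima ranked by KL value, second-ranked chosen
#'   (the "second KL maximum value" reading); falls back to the single
#'   maximum, with a warning, when only one exists;
#' * `"global_max"` — the top-ranked local maximum;
#' * `"first_max"` — the local maximum at the smallest k.
#'
#' When the KL curve has no strict structure (e.g. flat `W`), the smallest
#' available maximum is chosen and the curve is flagged
#' `no_clear_structure = TRUE`.
#'
#' @param W Numeric vector of dispersions, `W[i]` for `k = k_range[i]`.
#' @param p Dimensionality (number of channels).
#' @param k_range Integer vector of evaluated k values (contiguous, from 1).
#' @param rule Selection rule, see above.
#' @return An object of class `kl_curve`: data frame `curve` (k, W, DIFF,
#'   KL, is_local_max, chosen), `chosen_k`, `maxima` (ordered by KL value),
#'   `rule`, `no_clear_structure`.
#' @export
kl_criterion <- function(W, p, k_range = seq_along(W),
                         rule = c("second_max", "global_max", "first_max")) {
  rule <- match.arg(rule)
  k_range <- as.integer(k_range)
  if (length(W) != length(k_range))
    stop("W must have one value per k in k_range")
  if (!identical(k_range, seq.int(k_range[1], by = 1L,
                                  length.out = length(k_range))) ||
      k_range[1] != 1L)
    stop("k_range must be contiguous and start at 1")
  if (length(k_range) < 4)
    stop("KL needs at least k = 1..4: widen k_range ",
         "(no interior k can be a second maximum otherwise)")

  K <- max(k_range)
  e <- 2 / p
  w_scale <- max(W[1], max(W), 1e-300)
  DIFF <- rep(NA_real_, K)        # indexed by k
  for (k in 2:K) DIFF[k] <- (k - 1)^e * W[k - 1] - k^e * W[k]
  KL <- rep(NA_real_, K)
  for (k in 2:(K - 1)) {
    if (!is.na(DIFF[k + 1]) && DIFF[k + 1] != 0)
      KL[k] <- abs(DIFF[k] / DIFF[k + 1])
  }

  def <- which(!is.na(KL))
  is_max <- rep(FALSE, K)
  for (k in def) {
    left <- if ((k - 1) %in% def) KL[k] >= KL[k - 1] else TRUE
    right <- if ((k + 1) %in% def) KL[k] >= KL[k + 1] else TRUE
    is_max[k] <- left && right
  }
  no_structure <- FALSE
  if (!any(is_max) && length(def) > 0) {
    is_max[def[which.max(KL[def])]] <- TRUE
    no_structure <- TRUE
  }
  # a plateau where every point is a "maximum" carries no structure either
  if (length(def) > 1 && length(unique(KL[def])) == 1) no_structure <- TRUE

  # flat dispersion carries no cluster structure at all
  if ((max(W) - min(W)) <= 1e-12 * w_scale) no_structure <- TRUE

  cand <- which(is_max)
  ord <- cand[order(-KL[cand], cand)]
  # perfect fit: some k explains the maps exactly (noiseless planting);
  # the smallest such k is the planted structure and the successive-
  # difference ratios around it are meaningless (divisions by ~0)
  perfect <- which(W <= 1e-10 * w_scale)
  chosen_k <- if (length(perfect) > 0) {
    k_range[perfect[1]]
  } else if (length(ord) == 0) {
    warning("KL curve undefined everywhere; defaulting to k = 1")
    1L
  } else if (rule == "global_max") {
    ord[1]
  } else if (rule == "first_max") {
    min(cand)
  } else if (length(ord) >= 2) {
    ord[2]
  } else {
    warning("only one KL local maximum; choosing it (rule 'second_max')")
    ord[1]
  }

  curve <- data.frame(k = k_range, W = W, DIFF = DIFF[k_range],
                      KL = KL[k_range], is_local_max = is_max[k_range],
                      chosen = k_range == chosen_k)
  structure(list(curve = curve, chosen_k = as.integer(chosen_k),
                 maxima = data.frame(k = ord, KL = KL[ord]),
                 rule = rule, no_clear_structure = no_structure),
            class = "kl_curve")
}

#' @export
print.kl_curve <- function(x, ...) {
  cat(sprintf("<kl_curve> rule = %s, chosen k = %d%s\n", x$rule, x$chosen_k,
              if (x$no_clear_structure) " (no clear structure)" else ""))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

# Run modified_kmeans for each k in ascending order, warm-starting k from
# the best (k-1) templates plus the map they fit worst. Keeps the best-of-
# restarts dispersion curve W(k) smooth and (in practice) monotone, which
# the Krzanowski-Lai successive-difference ratios need to be interpretable.
.kmeans_over_k <- function(maps, k_eval, weights = NULL, n_restarts = 64,
                           max_iter = 300, tol = 1e-7) {
  nm <- .normalized_maps(as.matrix(maps))
  V <- nm$V[, nm$ok, drop = FALSE]
  fits <- vector("list", length(k_eval))
  prev <- NULL
  for (i in seq_along(k_eval)) {
    k <- k_eval[i]
    warm <- NULL
    if (!is.null(prev) && ncol(prev$templates) == k - 1) {
      fit_r <- apply(abs(crossprod(prev$templates, V)), 2, max)
      warm <- cbind(prev$templates, V[, which.min(fit_r)])
    }
    fits[[i]] <- modified_kmeans(maps, k = k, weights = weights,
                                 n_restarts = n_restarts,
                                 max_iter = max_iter, tol = tol,
                                 seed = NULL, warm_start = warm)
    prev <- fits[[i]]
  }
  fits
}

#' Select the number of microstates for one ERP
#'
#' Runs [modified_kmeans()] for every k in `k_range` on the frames of the
#' epoch's analysis window, builds the dispersion curve `W(k)`, applies the
#' Krzanowski-Lai criterion, and returns the clustering at the chosen k.
#'
#' @param epoch An [erp_epoch()]. The average reference is (re)applied and
#'   the analysis window cropped before clustering.
#' @param k_range Contiguous k values starting at 1 (default 1..12).
#' @param rule KL selection rule, see [kl_criterion()].
#' @param window_ms Analysis window in ms (default `c(0, 400)`).
#' @param n_restarts,max_iter,tol Passed to [modified_kmeans()].
#' @param seed Optional integer seed for the whole selection.
#' @return List with `kl` (a `kl_curve`), `clustering` (the `ms_clustering`
#'   at the chosen k), and `per_k` (GEV and W per evaluated k).
#' @export
select_k_for_erp <- function(epoch, k_range = 1:12,
                             rule = c("second_max", "global_max",
                                      "first_max"),
                             window_ms = c(0, 400), n_restarts = 64,
                             max_iter = 300, tol = 1e-7, seed = NULL) {
  rule <- match.arg(rule)
  run <- function() {
    ep <- apply_average_reference(crop_window(epoch, window_ms))
    maps <- ep$data
    nm <- .normalized_maps(maps)
    n_distinct <- .n_distinct_maps(nm$V[, nm$ok, drop = FALSE])
    k_eval <- k_range[k_range <= n_distinct]
    if (length(k_eval) == 0)
      stop("no usable maps in the analysis window")
    fits <- .kmeans_over_k(maps, k_eval, n_restarts = n_restarts,
                           max_iter = max_iter, tol = tol)
    W <- vapply(fits, `[[`, numeric(1), "dispersion_W")
    gev <- vapply(fits, `[[`, numeric(1), "gev")
    if (length(k_eval) >= 4) {
      kl <- kl_criterion(W, p = nrow(maps), k_range = k_eval, rule = rule)
    } else {
      # degenerate data (fewer distinct maps than needed for a KL curve):
      # take the smallest k attaining the best explained variance
      chosen <- k_eval[which(gev >= max(gev) - 1e-12)[1]]
      warning("fewer than 4 evaluable k values; choosing smallest k with ",
              "maximal GEV instead of the KL rule")
      kl <- structure(list(
        curve = data.frame(k = k_eval, W = W, DIFF = NA_real_,
                           KL = NA_real_, is_local_max = FALSE,
                           chosen = k_eval == chosen),
        chosen_k = as.integer(chosen),
        maxima = data.frame(k = integer(), KL = numeric()),
        rule = rule, no_clear_structure = TRUE), class = "kl_curve")
    }
    list(kl = kl, clustering = fits[[match(kl$chosen_k, k_eval)]],
         per_k = data.frame(k = k_eval, W = W, gev = gev))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
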