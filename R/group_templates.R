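#' Pool subject-level template maps
#'
#' Concatenates the template maps of all per-subject, per-condition
#' clustering results into one channels x maps matrix (unit-norm columns)
#' with a provenance record, ready for the second-level group clustering.
#'
#' @param results List of `ms_clustering` objects (one per subject x
#'   condition), all over the same montage. Named lists propagate names to
#'   the provenance.
#' @return List with `maps` (channels x total-templates matrix) and
#'   `provenance` (data frame: source, template index within source).
#' @export
pool_subject_templates <- function(results) {
  if (length(results) < 1) stop("need at least one clustering result")
  dims <- vapply(results, function(r) nrow(r$templates), integer(1))
  if (length(unique(dims)) != 1)
    stop("montage mismatch: subject templates have differing channel counts")
  maps <- do.call(cbind, lapply(results, `[[`, "templates"))
  maps <- sweep(maps, 2, colMeans(maps), "-")
  maps <- sweep(maps, 2, sqrt(colSums(maps^2)), "/")
  src <- names(results)
  if (is.null(src)) src <- sprintf("result%03d", seq_along(results))
  provenance <- data.frame(
    source = rep(src, vapply(results, function(r) ncol(r$templates),
                             integer(1))),
    template = unlist(lapply(results, function(r)
      seq_len(ncol(r$templates)))),
    row.names = NULL)
  list(maps = maps, provenance = provenance)
}

#' Group-level clustering of pooled subject templates
#'
#' Second-level modified k-means across `k_range`, with the group k chosen
#' by the Krzanowski-Lai rule (templates enter unweighted: one map, one
#' vote, unless `gev_weights` are supplied). Templates are in arbitrary
#' order here; [order_templates_by_coverage()] canonicalizes them after
#' backfitting.
#'
#' @param pooled Channels x maps matrix (e.g. `$maps` from
#'   [pool_subject_templates()]).
#' @param k_range Contiguous k values starting at 1 (default 1..12).
#' @param rule KL selection rule, see [kl_criterion()].
#' @param weights Optional per-map weights (e.g. subject-level GEV).
#' @param n_restarts,max_iter,tol Passed to [modified_kmeans()].
#' @param seed Optional integer seed.
#' @return An object of class `ms_templates`: `templates` (channels x
#'   k_global), `k_global`, `kl`, `clustering`, `provenance_n` (number of
#'   pooled maps), `rule`, `seed`.
#' @export
cluster_group <- function(pooled, k_range = 1:12,
                          rule = c("second_max", "global_max", "first_max"),
                          weights = NULL, n_restarts = 64, max_iter = 300,
                          tol = 1e-7, seed = NULL) {
  rule <- match.arg(rule)
  pooled <- as.matrix(pooled)
  if (ncol(pooled) == 0) stop("no pooled maps")
  if (is.null(weights)) weights <- rep(1, ncol(pooled))
  run <- function() {
    nm <- .normalized_maps(pooled)
    n_distinct <- .n_distinct_maps(nm$V[, nm$ok, drop = FALSE])
    k_eval <- k_range[k_range <= n_distinct]
    fits <- .kmeans_over_k(pooled, k_eval, weights = weights,
                           n_restarts = n_restarts, max_iter = max_iter,
                           tol = tol)
    W <- vapply(fits, `[[`, numeric(1), "dispersion_W")
    if (length(k_eval) >= 4) {
      kl <- kl_criterion(W, p = nrow(pooled), k_range = k_eval, rule = rule)
      chosen <- kl$chosen_k
    } else {
      gev <- vapply(fits, `[[`, numeric(1), "gev")
      chosen <- k_eval[which(gev >= max(gev) - 1e-12)[1]]
      kl <- NULL
      warning("fewer than 4 evaluable k values at group level; ",
              "choosing smallest k with maximal GEV")
    }
    fit <- fits[[match(chosen, k_eval)]]
    structure(list(templates = fit$templates,
                   k_global = as.integer(chosen), kl = kl,
                   clustering = fit, provenance_n = ncol(pooled),
                   rule = rule, seed = seed),
              class = "ms_templates")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.ms_templates <- function(x, ...) {
  cat(sprintf(
    "<ms_templates> k_global = %d from %d pooled maps (rule %s, GEV %.4f)\n",
    x$k_global, x$provenance_n, x$rule, x$clustering$gev))
  invisible(x)
}

#' Build a template set from a plain matrix
#'
#' Wraps a channels x k matrix (e.g. planted synthetic templates) as an
#' `ms_templates` object so it can be backfitted or matched.
#'
#' @param templates Channels x k numeric matrix.
#' @return An `ms_templates` object.
#' @export
as_ms_templates <- function(templates) {
  templates <- as.matrix(templates)
  templates <- sweep(templates, 2, colMeans(templates), "-")
  templates <- sweep(templates, 2, sqrt(colSums(templates^2)), "/")
  structure(list(templates = templates, k_global = ncol(templates),
                 kl = NULL, clustering = NULL,
                 provenance_n = ncol(templates), rule = "fixed",
                 seed = NULL), class = "ms_templates")
}

#' Match two template sets
#'
#' Optimal one-to-one assignment between the templates of two sets,
#' maximizing total absolute spatial correlation (exhaustive over
#' permutations; k is small). With differing k, the smaller set is matched
#' and the surplus templates of the larger are reported unmatched.
#'
#' @param recovered,reference `ms_templates` objects (or matrices) over the
#'   same montage.
#' @return List with `assignment` (data frame: recovered, reference,
#'   abs_r), `mean_abs_r`, `min_abs_r`, `unmatched` (list of indices).
#' @export
match_templates <- function(recovered, reference) {
  A <- if (inherits(recovered, "ms_templates")) recovered$templates
       else as_ms_templates(recovered)$templates
  B <- if (inherits(reference, "ms_templates")) reference$templates
       else as_ms_templates(reference)$templates
  if (nrow(A) != nrow(B)) stop("montage mismatch between template sets")
  R <- abs(crossprod(A, B)) # kA x kB
  kA <- ncol(A); kB <- ncol(B)
  swap <- kA > kB
  if (swap) R <- t(R)
  n_small <- nrow(R); n_big <- ncol(R)
  perms <- .permutations(n_big)
  best <- NULL; best_val <- -Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, seq_len(n_small)]
    v <- sum(R[cbind(seq_len(n_small), p)])
    if (v > best_val) { best_val <- v; best <- p }
  }
  small_idx <- seq_len(n_small)
  if (swap) {
    assignment <- data.frame(recovered = best, reference = small_idx,
                             abs_r = R[cbind(small_idx, best)])
  } else {
    assignment <- data.frame(recovered = small_idx, reference = best,
                             abs_r = R[cbind(small_idx, best)])
  }
  assignment <- assignment[order(assignment$recovered), , drop = FALSE]
  unmatched <- list(
    recovered = setdiff(seq_len(kA), assignment$recovered),
    reference = setdiff(seq_len(kB), assignment$reference))
  list(assignment = assignment, mean_abs_r = mean(assignment$abs_r),
       min_abs_r = min(assignment$abs_r), unmatched = unmatched)
}

# all permutations of 1..n (n small: group template counts)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  if (n > 8) stop("template matching supports up to 8 templates")
  sub <- .permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Canonically order global templates by cohort coverage
#'
#' Microstate labels are arbitrary after clustering; the conventional fix is
#' to order templates by how much analysis time they cover across the whole
#' cohort after backfitting (descending).
#'
#' @param templates An `ms_templates` object.
#' @param sequences List of `ms_sequence` objects backfitted with
#'   `templates`.
#' @return The reordered `ms_templates`, with an `ordering` element giving
#'   the permutation applied (new index -> old index).
#' @export
order_templates_by_coverage <- function(templates, sequences) {
  k <- templates$k_global
  cov <- vapply(seq_len(k), function(cl)
    mean(vapply(sequences, function(s) coverage(s, cl), numeric(1))),
    numeric(1))
  ord <- order(-cov, seq_len(k))
  templates$templates <- templates$templates[, ord, drop = FALSE]
  templates$ordering <- ord
  templates
}
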