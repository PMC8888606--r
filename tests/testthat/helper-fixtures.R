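# Shared fixtures, all generated in code.

# a zero-mean random map
rand_map <- function(C, seed = NULL) {
  f <- function() { v <- rnorm(C); v - mean(v) }
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

# k exactly orthogonal zero-mean unit-norm templates over C channels
ortho_templates <- function(C, k, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(C * k), C, k)
    M <- sweep(M, 2, colMeans(M), "-")
    Q <- qr.Q(qr(M))[, seq_len(k), drop = FALSE]
    Q <- sweep(Q, 2, colMeans(Q), "-")
    sweep(Q, 2, sqrt(colSums(Q^2)), "/")
  })
}

# epoch whose frames are templates with random signs/amplitudes (noiseless)
template_epoch <- function(templates, labels, sfreq = 250, seed = 1,
                           subject = "s01", condition = "AN-LVF") {
  withr::with_seed(seed, {
    amp <- runif(length(labels), 0.5, 2)
    sgn <- sample(c(-1, 1), length(labels), replace = TRUE)
    data <- templates[, labels, drop = FALSE] *
      rep(amp * sgn, each = nrow(templates))
    erp_epoch(data, sfreq = sfreq, subject = subject, condition = condition,
              referenced = TRUE)
  })
}

# small synthetic spec for fast pipeline tests
small_spec <- function(...) {
  synthetic_spec(n_channels = 24, n_subjects = 3,
                 conditions = c("AN-LVF", "AN-RVF", "HA-HA"), k_true = 3,
                 ...)
}

# independent one-way within-subject sums-of-squares oracle (textbook
# decomposition, computed from scratch without aov)
oracle_oneway_rm <- function(d, dv, factor, subject = "subject") {
  y <- d[[dv]]
  A <- factor(d[[factor]]); S <- factor(d[[subject]])
  a <- nlevels(A); n <- nlevels(S)
  grand <- mean(y)
  ss_A <- n * sum((tapply(y, A, mean) - grand)^2)
  ss_S <- a * sum((tapply(y, S, mean) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_A - ss_S
  df_A <- a - 1; df_err <- (a - 1) * (n - 1)
  F <- (ss_A / df_A) / (ss_err / df_err)
  list(F = F, df = c(df_A, df_err), MSE = ss_err / df_err,
       p = pf(F, df_A, df_err, lower.tail = FALSE),
       pes = ss_A / (ss_A + ss_err))
}

# exhaustive max-GEV oracle: enumerate all surjective labelings of maps
# into k clusters; for each labeling the optimal template of a cluster is
# the dominant eigenvector of the weighted scatter of its members, so the
# labeling's best GEV is the sum of top eigenvalues over clusters divided
# by the total weight.
oracle_best_gev <- function(maps, k) {
  maps <- sweep(maps, 2, colMeans(maps), "-")
  g2 <- colMeans(maps^2)
  V <- sweep(maps, 2, sqrt(colSums(maps^2)), "/")
  N <- ncol(V)
  labelings <- as.matrix(expand.grid(rep(list(seq_len(k)), N - 1)))
  best <- 0
  for (i in seq_len(nrow(labelings))) {
    lab <- c(1L, labelings[i, ]) # fix first label (label symmetry)
    if (length(unique(lab)) < k) next
    tot <- 0
    for (j in seq_len(k)) {
      idx <- which(lab == j)
      X <- sweep(V[, idx, drop = FALSE], 2, sqrt(g2[idx]), "*")
      tot <- tot + max(eigen(crossprod(X), symmetric = TRUE,
                             only.values = TRUE)$values)
    }
    best <- max(best, tot / sum(g2))
  }
  best
}
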