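#' @importFrom stats aov as.formula cor.test ptukey qtukey aggregate
NULL

#' Repeated-measures ANOVA on a metrics table
#'
#' Classical univariate within-subject decomposition with the subject as a
#' random blocking factor, fitted through `stats::aov` with an
#' `Error(subject/...)` stratum. Supports one or two within factors (main
#' effects and, for two factors, their interaction), each tested against its
#' own subject-by-effect error term with uncorrected degrees of freedom.
#' Requires a complete balanced design: exactly one non-missing value per
#' subject x cell.
#'
#' @param table Data frame with a `subject` column, the factor columns and
#'   the dependent variable.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of 1 or 2 within-subject factor columns.
#' @param subject Name of the subject column.
#' @return Data frame of class `anova_result`, one row per effect:
#'   `effect`, `df_effect`, `df_error`, `F`, `MSE`, `p`, `partial_eta_sq`.
#' @export
rm_anova <- function(table, dv, within, subject = "subject") {
  if (!length(within) %in% 1:2)
    stop("rm_anova supports 1 or 2 within-subject factors")
  d <- table[, c(subject, within, dv)]
  names(d) <- c(".subject", paste0(".f", seq_along(within)), ".dv")
  for (nm in c(".subject", paste0(".f", seq_along(within))))
    d[[nm]] <- factor(d[[nm]])
  .check_complete(d, dv_name = dv, within_names = within)

  rhs <- paste(paste0(".f", seq_along(within)), collapse = " * ")
  f <- as.formula(paste0(".dv ~ ", rhs, " + Error(.subject/(", rhs, "))"))
  fit <- aov(f, data = d)
  sm <- summary(fit)

  total_ss <- sum(vapply(sm, function(s)
    sum(s[[1]][, "Sum Sq"]), numeric(1)))
  eps <- 1e-10 * max(total_ss, 1e-300)

  out <- list()
  for (stratum in names(sm)) {
    tab <- sm[[stratum]][[1]]
    terms <- trimws(rownames(tab))
    res_i <- which(terms == "Residuals")
    if (length(res_i) == 0) next
    ss_err <- tab[res_i, "Sum Sq"]
    df_err <- tab[res_i, "Df"]
    for (i in setdiff(seq_len(nrow(tab)), res_i)) {
      ss <- tab[i, "Sum Sq"]
      df <- tab[i, "Df"]
      if (ss < eps || ss_err < eps) {
        # degenerate strata: no effect variance gives F = 0, p = 1; an
        # exact effect with no error variance gives F = Inf, p = 0
        Fv <- if (ss < eps) 0 else Inf
        pv <- if (ss < eps) 1 else 0
        mse <- ss_err / max(df_err, 1)
      } else {
        mse <- ss_err / df_err
        Fv <- (ss / df) / mse
        pv <- stats::pf(Fv, df, df_err, lower.tail = FALSE)
      }
      eff <- gsub("\\.f1", within[1], terms[i])
      if (length(within) == 2) eff <- gsub("\\.f2", within[2], eff)
      out[[length(out) + 1]] <- data.frame(
        effect = eff, df_effect = df, df_error = df_err, F = Fv, MSE = mse,
        p = pv,
        partial_eta_sq = if (ss + ss_err > 0) ss / (ss + ss_err) else 0)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("anova_result", "data.frame")
  res
}

.check_complete <- function(d, dv_name, within_names) {
  cells <- interaction(d[setdiff(names(d), c(".subject", ".dv"))],
                       drop = FALSE, sep = ":")
  tab <- table(d$.subject, cells)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "incomplete design: subject '%s' has %d values in cell '%s'",
      rownames(tab)[bad[1]], tab[bad[1], bad[2]], colnames(tab)[bad[2]]))
  }
  if (anyNA(d$.dv)) {
    i <- which(is.na(d$.dv))[1]
    cell <- paste(vapply(grep("^\\.f", names(d), value = TRUE),
                         function(f) as.character(d[[f]][i]), ""),
                  collapse = ":")
    stop(sprintf("missing %s for subject '%s' in cell '%s'", dv_name,
                 d$.subject[i], cell), call. = FALSE)
  }
}

#' Duncan's multiple range test
#'
#' Post-hoc pairwise comparisons after a within-subject ANOVA. Level means
#' are ranked; a pair spanning `r` ranks is tested against the studentized
#' range critical value at protection level `1 - (1 - alpha)^(r-1)`, using
#' the ANOVA error term of the factor. The usual step-down protection
#' applies: a pair inside a non-significant wider range is declared
#' non-significant.
#'
#' @param table Metrics-style data frame (one value per subject x level).
#' @param dv Dependent-variable column name.
#' @param factor Factor column name (at least 2 levels).
#' @param subject Subject column name.
#' @param alpha Significance level (default 0.05).
#' @return Data frame of class `posthoc_result`: `pair`, `diff`
#'   (mean difference), `p`, `significant`.
#' @export
duncan_posthoc <- function(table, dv, factor, subject = "subject",
                           alpha = 0.05) {
  lv <- unique(as.character(table[[factor]]))
  if (length(lv) < 2) stop("post-hoc needs a factor with at least 2 levels")
  an <- rm_anova(table, dv = dv, within = factor, subject = subject)
  if (all(an$p > alpha))
    warning("omnibus effect not significant; Duncan comparisons are ",
            "exploratory")
  mse <- an$MSE[1]
  df_err <- an$df_error[1]
  means <- tapply(table[[dv]], as.character(table[[factor]]), mean)
  n <- length(unique(table[[subject]]))
  se <- sqrt(mse / n)
  ord <- order(means) # ascending
  k <- length(means)

  rows <- list()
  sig <- matrix(NA, k, k)
  # widest ranges first so the step-down blocking rule can propagate
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      a <- ord[i]; b <- ord[j]
      q_obs <- if (se > 0) abs(means[b] - means[a]) / se else
        if (means[b] == means[a]) 0 else Inf
      crit_p <- (1 - alpha)^(span - 1)
      p <- 1 - ptukey(q_obs, span, df_err)^(1 / (span - 1))
      is_sig <- q_obs > qtukey(crit_p, span, df_err)
      # blocked if any enclosing range was non-significant
      blocked <- FALSE
      if (span < k) {
        for (ii in seq_len(k - span)) {
          jj <- ii + span
          if (ii <= i && jj >= j && identical(sig[ii, jj], FALSE))
            blocked <- TRUE
        }
      }
      if (blocked) is_sig <- FALSE
      sig[i, j] <- is_sig
      rows[[length(rows) + 1]] <- data.frame(
        pair = paste(names(means)[b], "-", names(means)[a]),
        diff = unname(means[b] - means[a]), p = unname(p),
        significant = is_sig)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("posthoc_result", "data.frame")
  res
}

#' Correlation between handedness scores and microstate metrics
#'
#' Pearson correlation across subjects between each subject's mean metric
#' (averaged over conditions) and the handedness score, per class and
#' metric, with two-sided p values.
#'
#' @param table Metrics table ([build_metrics_table()] output).
#' @param scores Named numeric vector of handedness scores in `[-100, 100]`,
#'   one per subject (names = subject identifiers), or an unnamed vector in
#'   subject sort order.
#' @param metrics Which metric columns to correlate.
#' @return Data frame: `class`, `metric`, `r`, `p`, `n`.
#' @export
metric_handedness_correlation <- function(
    table, scores,
    metrics = c("duration_ms", "occurrence_hz", "coverage_pct")) {
  subjects <- sort(unique(table$subject))
  if (is.null(names(scores))) {
    if (length(scores) != length(subjects))
      stop("need one handedness score per subject")
    names(scores) <- subjects
  }
  out <- list()
  for (cl in sort(unique(table$class))) {
    sub <- table[table$class == cl, ]
    for (m in metrics) {
      sm <- tapply(sub[[m]], sub$subject, mean, na.rm = TRUE)
      sm <- sm[subjects]
      sc <- scores[subjects]
      if (sd(sm) == 0 || sd(sc) == 0)
        stop("correlation undefined: zero variance in ",
             if (sd(sc) == 0) "handedness scores" else m)
      ct <- cor.test(sm, sc, method = "pearson")
      out[[length(out) + 1]] <- data.frame(
        class = cl, metric = m, r = unname(ct$estimate), p = ct$p.value,
        n = length(subjects))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate per-cell metric values for power and calibration studies
#'
#' Draws a balanced subject x level table of one metric with a subject
#' random intercept and i.i.d. within-cell noise — the sampling model used
#' for the ANOVA calibration and power analyses.
#'
#' @param n_subjects Number of subjects.
#' @param level_means Named numeric vector: population mean per factor
#'   level.
#' @param sd_within Within-subject (cell) noise SD.
#' @param sd_subject Between-subject intercept SD.
#' @param dv Name for the value column.
#' @param factor Name for the level column.
#' @param seed Optional integer seed.
#' @return Data frame: `subject`, factor column, dv column.
#' @export
simulate_metric_cells <- function(n_subjects, level_means, sd_within,
                                  sd_subject = 0, dv = "value",
                                  factor = "condition", seed = NULL) {
  run <- function() {
    lv <- names(level_means)
    subj <- sprintf("s%02d", seq_len(n_subjects))
    b <- rnorm(n_subjects, 0, sd_subject)
    d <- expand.grid(subject = subj, level = lv, stringsAsFactors = FALSE)
    d$value <- level_means[d$level] + b[match(d$subject, subj)] +
      rnorm(nrow(d), 0, sd_within)
    names(d) <- c("subject", factor, dv)
    d
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
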