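#' Backfit global templates to an ERP
#'
#' Assigns every frame of the analysis window to the global template with
#' the highest absolute spatial correlation, yielding the microstate label
#' sequence. Ties break toward the lower template index; zero-GFP frames are
#' left unassigned (`NA`). No temporal smoothing is applied by default; a
#' minimum-duration hook exists but is off (`min_duration_ms = 0`).
#'
#' @param epoch An [erp_epoch()]; the average reference is (re)applied and
#'   the analysis window cropped.
#' @param templates An `ms_templates` object (or channels x k matrix).
#' @param window_ms Analysis window in ms (default `c(0, 400)`).
#' @param min_duration_ms Runs shorter than this are re-labeled to the
#'   neighboring run with the higher adjacent fit; default 0 (off).
#' @return An object of class `ms_sequence`: `labels` (integer per frame,
#'   `NA` = unassigned), `fit_r` (winning absolute correlation per frame),
#'   `sfreq`, `subject`, `condition`, `k`.
#' @export
backfit <- function(epoch, templates, window_ms = c(0, 400),
                    min_duration_ms = 0) {
  TT <- if (inherits(templates, "ms_templates")) templates$templates
        else as_ms_templates(templates)$templates
  ep <- apply_average_reference(crop_window(epoch, window_ms))
  if (nrow(ep$data) != nrow(TT))
    stop("montage mismatch between epoch and templates")
  nm <- .normalized_maps(ep$data)
  A <- abs(crossprod(TT, nm$V)) # k x frames
  labels <- apply(A, 2, which.max)
  fit_r <- A[cbind(labels, seq_len(ncol(A)))]
  labels[!nm$ok] <- NA_integer_
  fit_r[!nm$ok] <- NA_real_
  seq <- structure(list(labels = as.integer(labels), fit_r = fit_r,
                        sfreq = ep$sfreq, subject = ep$subject,
                        condition = ep$condition, k = ncol(TT)),
                   class = "ms_sequence")
  if (min_duration_ms > 0) seq <- .reject_short_runs(seq, min_duration_ms)
  seq
}

#' Construct a microstate sequence from labels
#'
#' Mainly for tests and hand-built examples.
#'
#' @param labels Integer (or factor/character coercible) class labels per
#'   frame; `NA` marks unassigned frames.
#' @param sfreq Sampling rate in Hz.
#' @param subject,condition Identifiers.
#' @param k Number of classes (default: max label).
#' @return An `ms_sequence` object.
#' @export
ms_sequence <- function(labels, sfreq, subject = "s01",
                        condition = "unknown", k = NULL) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(factor(labels, levels = unique(
      sort(as.character(labels)))))
  labels <- as.integer(labels)
  if (is.null(k)) k <- max(labels, na.rm = TRUE)
  structure(list(labels = labels, fit_r = rep(NA_real_, length(labels)),
                 sfreq = sfreq, subject = subject, condition = condition,
                 k = as.integer(k)),
            class = "ms_sequence")
}

#' @export
print.ms_sequence <- function(x, ...) {
  cat(sprintf("<ms_sequence> %s / %s: %d frames @ %g Hz, %d classes\n",
              x$subject, x$condition, length(x$labels), x$sfreq, x$k))
  invisible(x)
}

# contiguous runs of each class; NA frames break runs and belong to none
.class_runs <- function(seq) {
  r <- rle(ifelse(is.na(seq$labels), -1L, seq$labels))
  data.frame(class = r$values, length = r$lengths)[r$values != -1L, ,
                                                   drop = FALSE]
}

.reject_short_runs <- function(seq, min_duration_ms) {
  min_frames <- ceiling(min_duration_ms * seq$sfreq / 1000)
  repeat {
    r <- rle(ifelse(is.na(seq$labels), -1L, seq$labels))
    short <- which(r$lengths < min_frames & r$values != -1L)
    if (length(short) == 0) break
    i <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    repl <- if (i > 1 && r$values[i - 1] != -1L) r$values[i - 1]
            else if (i < length(r$values) && r$values[i + 1] != -1L)
              r$values[i + 1]
            else break
    seq$labels[starts[i]:ends[i]] <- repl
  }
  seq
}

#' Mean microstate duration
#'
#' Average length of the contiguous runs of a class, in ms. Runs truncated
#' by the window edges enter with their observed length. An absent class is
#' undefined and reported as `NA` (not 0).
#'
#' @param seq An `ms_sequence`.
#' @param class Integer class index.
#' @return Mean duration in ms, or `NA` if the class never occurs.
#' @export
mean_duration <- function(seq, class) {
  runs <- .class_runs(seq)
  len <- runs$length[runs$class == class]
  if (length(len) == 0) return(NA_real_)
  mean(len) * 1000 / seq$sfreq
}

#' Microstate occurrence
#'
#' Number of distinct runs of a class divided by the analysis-window length
#' in seconds (all frames, assigned or not).
#'
#' @inheritParams mean_duration
#' @return Occurrence in Hz (0 for an absent class).
#' @export
occurrence <- function(seq, class) {
  runs <- .class_runs(seq)
  n_runs <- sum(runs$class == class)
  n_runs / (length(seq$labels) / seq$sfreq)
}

#' Microstate coverage
#'
#' Percentage of assigned analysis time carrying a class.
#'
#' @inheritParams mean_duration
#' @return Coverage in percent (0 for an absent class).
#' @export
coverage <- function(seq, class) {
  assigned <- sum(!is.na(seq$labels))
  if (assigned == 0) stop("no assigned frames in sequence")
  100 * sum(seq$labels == class, na.rm = TRUE) / assigned
}

#' All three metrics for one sequence
#'
#' @param seq An `ms_sequence`.
#' @return Data frame with one row per class: `class`, `duration_ms`,
#'   `occurrence_hz`, `coverage_pct`.
#' @export
microstate_metrics <- function(seq) {
  cl <- seq_len(seq$k)
  data.frame(
    class = cl,
    duration_ms = vapply(cl, function(c) mean_duration(seq, c), numeric(1)),
    occurrence_hz = vapply(cl, function(c) occurrence(seq, c), numeric(1)),
    coverage_pct = vapply(cl, function(c) coverage(seq, c), numeric(1)))
}

#' Metrics table for a cohort of sequences
#'
#' One row per subject x condition x class; absent classes are explicit
#' (`duration_ms = NA`, `occurrence_hz = 0`, `coverage_pct = 0`).
#'
#' @param sequences List of `ms_sequence` objects.
#' @return Data frame with columns `subject`, `condition`, `class`,
#'   `duration_ms`, `occurrence_hz`, `coverage_pct`.
#' @export
build_metrics_table <- function(sequences) {
  rows <- lapply(sequences, function(s) {
    m <- microstate_metrics(s)
    cbind(data.frame(subject = s$subject, condition = s$condition), m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
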