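#' @useDynLib erpmicrostates, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm sd
NULL

# relative tolerance used when asserting that a map is average-referenced
.ref_tol <- 1e-6

#' Channel montage
#'
#' A montage is the ordered set of electrode labels, optionally with 3-D
#' positions (arbitrary units, nominally on the unit sphere). Positions are
#' only needed by the synthetic generator (spatial smoothing) and by plotting;
#' all clustering and backfitting operate on channel order alone.
#'
#' @param labels Character vector of unique channel labels.
#' @param positions Optional numeric matrix, one row per channel, columns
#'   x/y/z.
#' @return An object of class `channel_montage`.
#' @export
channel_montage <- function(labels, positions = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels) > 0) stop("montage labels must be unique")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != length(labels))
      stop("positions must have one row per channel label")
    if (ncol(positions) != 3) stop("positions must have columns x, y, z")
    rownames(positions) <- labels
  }
  structure(list(labels = labels, positions = positions),
            class = "channel_montage")
}

#' @export
print.channel_montage <- function(x, ...) {
  cat(sprintf("<channel_montage> %d channels%s\n", length(x$labels),
              if (is.null(x$positions)) "" else ", with 3-D positions"))
  invisible(x)
}

#' Number of channels in a montage
#' @param montage A [channel_montage()].
#' @return Integer channel count.
#' @export
n_channels <- function(montage) length(montage$labels)

#' ERP epoch
#'
#' One subject-by-condition event-related potential: a channels x frames
#' matrix with its sampling rate and reference state.
#'
#' @param data Numeric matrix, channels x frames (microvolts).
#' @param sfreq Sampling rate in Hz.
#' @param t0 Time of the first frame relative to stimulus onset, in ms.
#' @param subject Subject identifier.
#' @param condition Condition code.
#' @param montage A [channel_montage()] (or `NULL` to build an unlabeled one).
#' @param referenced Logical; whether columns are already average-referenced.
#' @return An object of class `erp_epoch`.
#' @export
erp_epoch <- function(data, sfreq, t0 = 0, subject = "s01",
                      condition = "unknown", montage = NULL,
                      referenced = FALSE) {
  data <- as.matrix(data)
  if (ncol(data) < 2) stop("an ERP epoch needs at least 2 frames")
  if (!is.numeric(sfreq) || length(sfreq) != 1 || sfreq <= 0)
    stop("sfreq must be a single positive number")
  if (is.null(montage))
    montage <- channel_montage(sprintf("E%03d", seq_len(nrow(data))))
  if (nrow(data) != n_channels(montage))
    stop("data rows must match the montage channel count")
  structure(list(data = data, sfreq = sfreq, t0 = t0,
                 subject = as.character(subject),
                 condition = as.character(condition),
                 montage = montage, referenced = isTRUE(referenced)),
            class = "erp_epoch")
}

#' @export
print.erp_epoch <- function(x, ...) {
  cat(sprintf(
    "<erp_epoch> %s / %s: %d channels x %d frames @ %g Hz (t0 = %g ms)%s\n",
    x$subject, x$condition, nrow(x$data), ncol(x$data), x$sfreq, x$t0,
    if (x$referenced) ", average-referenced" else ""))
  invisible(x)
}

#' Frame times of an epoch
#' @param epoch An [erp_epoch()].
#' @return Numeric vector of frame times in ms relative to stimulus onset.
#' @export
frame_times <- function(epoch) {
  epoch$t0 + (seq_len(ncol(epoch$data)) - 1) * 1000 / epoch$sfreq
}

#' Restrict an epoch to an analysis window
#'
#' Keeps frames with time in `[window_ms[1], window_ms[2])`.
#'
#' @param epoch An [erp_epoch()].
#' @param window_ms Length-2 numeric, window in ms relative to onset.
#' @return The cropped [erp_epoch()].
#' @export
crop_window <- function(epoch, window_ms = c(0, 400)) {
  tt <- frame_times(epoch)
  keep <- tt >= window_ms[1] & tt < window_ms[2]
  if (sum(keep) < 2) stop("analysis window retains fewer than 2 frames")
  epoch$data <- epoch$data[, keep, drop = FALSE]
  epoch$t0 <- tt[which(keep)[1]]
  epoch
}

#' Average-reference an ERP epoch
#'
#' Subtracts the channel mean from every frame, making each column zero-mean.
#' Idempotent; applied unconditionally by the clustering and backfitting
#' stages because the spatial-correlation machinery assumes zero-mean maps.
#'
#' @param epoch An [erp_epoch()].
#' @return The referenced [erp_epoch()] (`referenced = TRUE`).
#' @export
apply_average_reference <- function(epoch) {
  if (nrow(epoch$data) < 2)
    stop("average reference needs at least 2 channels")
  epoch$data <- sweep(epoch$data, 2, colMeans(epoch$data), "-")
  epoch$referenced <- TRUE
  epoch
}

.is_zero_mean <- function(v) {
  scale <- max(abs(v))
  scale == 0 || abs(mean(v)) <= .ref_tol * scale
}

#' Global field power of a topographic map
#'
#' The population standard deviation of the potential across channels,
#' `sqrt(mean(v^2))` for a zero-mean map: a reference-free amplitude measure.
#'
#' @param values Numeric map vector (one potential per channel), zero-mean.
#' @return Nonnegative scalar GFP (same units as the map).
#' @export
gfp <- function(values) {
  values <- as.numeric(values)
  if (!.is_zero_mean(values))
    stop("gfp() is defined on average-referenced (zero-mean) maps")
  sqrt(mean(values^2))
}

#' Global field power per frame of an epoch
#' @param epoch A referenced [erp_epoch()].
#' @return Numeric vector of per-frame GFP values.
#' @export
gfp_curve <- function(epoch) {
  d <- epoch$data
  d <- sweep(d, 2, colMeans(d), "-")
  sqrt(colMeans(d^2))
}

#' Spatial correlation between two topographic maps
#'
#' Pearson correlation across channels, which for zero-mean maps equals their
#' cosine similarity. With `ignore_polarity = TRUE` the absolute value is
#' returned, treating a map and its sign-flipped copy as identical.
#'
#' @param u,v Zero-mean numeric map vectors over the same montage.
#' @param ignore_polarity If `TRUE`, return `|r|`.
#' @return Scalar in `[-1, 1]` (or `[0, 1]` when polarity is ignored).
#' @export
spatial_correlation <- function(u, v, ignore_polarity = FALSE) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v))
    stop("maps must share a montage (equal length)")
  if (!.is_zero_mean(u) || !.is_zero_mean(v))
    stop("spatial correlation is defined on zero-mean maps")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("spatial correlation undefined for an all-zero map")
  r <- sum(u * v) / (nu * nv)
  r <- max(-1, min(1, r))
  if (ignore_polarity) abs(r) else r
}

# Columns of `data` as unit-norm zero-mean maps, with per-column GFP.
# Zero-GFP columns are flagged (excluded downstream rather than erroring).
.normalized_maps <- function(data) {
  data <- sweep(data, 2, colMeans(data), "-")
  g <- sqrt(colMeans(data^2))
  ok <- g > 0
  V <- data
  V[, ok] <- sweep(data[, ok, drop = FALSE], 2,
                   sqrt(colSums(data[, ok, drop = FALSE]^2)), "/")
  list(V = V, gfp = g, ok = ok)
}
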