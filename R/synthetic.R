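#' Synthetic electrode montage
#'
#' Deterministic quasi-uniform electrode layout on the upper unit
#' hemisphere (golden-angle spiral), standing in for a dense EEG net.
#'
#' @param n_channels Number of electrodes.
#' @return A [channel_montage()] with 3-D positions.
#' @export
synthetic_montage <- function(n_channels = 128) {
  i <- seq_len(n_channels) - 0.5
  z <- i / n_channels            # upper hemisphere: z in (0, 1)
  phi <- pi * (1 + sqrt(5)) * i  # golden angle
  r <- sqrt(1 - z^2)
  channel_montage(sprintf("E%03d", seq_len(n_channels)),
                  cbind(x = r * cos(phi), y = r * sin(phi), z = z))
}

# Gaussian spatial smoothing kernel over montage positions (chordal
# distance, length scale ell); rows normalized to sum 1.
.smoothing_kernel <- function(montage, ell) {
  P <- montage$positions
  if (is.null(P)) stop("montage has no positions for spatial smoothing")
  D2 <- outer(rowSums(P^2), rowSums(P^2), "+") - 2 * tcrossprod(P)
  K <- exp(-pmax(D2, 0) / (2 * ell^2))
  K / rowSums(K)
}

#' Specification of a synthetic ERP cohort
#'
#' Collects every knob of the generator. Defaults mirror the divided-
#' visual-field study design this package emulates: 16 subjects, the 8
#' conditions of [condition_design()], 128 channels, a 400 ms post-onset
#' window, 4 planted templates, ~100 ms planted state durations (the
#' quasi-stability range reported for microstates is 80-120 ms) and an
#' epoch-level SNR of 5 dB. The default condition effects plant the
#' qualitative pattern the pipeline is meant to recover: longer class-4
#' states for left-visual-field presentations and a higher class-2
#' occupancy for unilateral than bilateral presentations. Set
#' `null_effects = TRUE` for a fully exchangeable cohort.
#'
#' @param n_channels,sfreq,window_ms,k_true,n_subjects Core dimensions.
#' @param conditions Condition codes (default the 8-condition design).
#' @param duration_mean_ms Condition x class matrix of mean state durations
#'   (ms); default built by the planted pattern below.
#' @param occupancy Condition x class matrix of state occupancy weights
#'   (rows sum to 1).
#' @param duration_sd_ms SD of planted run lengths (ms).
#' @param min_run_frames Smallest admissible run (frames).
#' @param snr_db Signal-to-noise ratio: `10 log10(mean GFP_signal^2 /
#'   mean GFP_noise^2)` over the epoch. `Inf` disables noise.
#' @param amplitude_uv Peak signal GFP scale (microvolts).
#' @param envelope_peaks_ms,envelope_widths_ms,envelope_amps,envelope_floor
#'   Raised-cosine ERP amplitude envelope: component peak times, full
#'   widths, relative amplitudes, and a baseline floor keeping every frame
#'   nonzero.
#' @param template_smoothness,noise_smoothness Length scales (chordal
#'   distance on the unit sphere) of the spatial smoothing applied to
#'   templates and noise. Template patterns are global (0.7); noise is
#'   smoothed only at the nearest-neighbor electrode scale (0.1), i.e.
#'   spatially correlated but not confusable with state topographies.
#' @param template_max_abs_r Upper bound on pairwise `|r|` between planted
#'   templates.
#' @param subject_duration_sd Between-subject SD of duration means (ms).
#' @param subject_template_jitter Relative amplitude of subject-specific
#'   template perturbation.
#' @param hand_mean,hand_sd Handedness score distribution (clamped to
#'   `[-100, 100]`).
#' @param beta_hand Slope linking a subject's class-1 duration offset (ms)
#'   to the handedness score, for correlation-recovery tests.
#' @param null_effects If `TRUE`, all conditions share flat durations and
#'   equal occupancies.
#' @return An object of class `ms_synth_spec` (a validated list).
#' @export
synthetic_spec <- function(n_channels = 128, sfreq = 250, window_ms = 400,
                           k_true = 4, n_subjects = 16,
                           conditions = condition_design()$condition,
                           duration_mean_ms = NULL, occupancy = NULL,
                           duration_sd_ms = 20, min_run_frames = 2,
                           snr_db = 5, amplitude_uv = 5,
                           envelope_peaks_ms = c(100, 200),
                           envelope_widths_ms = c(160, 240),
                           envelope_amps = c(1, 0.8),
                           envelope_floor = 0.4,
                           template_smoothness = 0.7,
                           noise_smoothness = 0.1,
                           template_max_abs_r = 0.5,
                           subject_duration_sd = 5,
                           subject_template_jitter = 0.05,
                           hand_mean = 79, hand_sd = 9, beta_hand = 0,
                           null_effects = FALSE) {
  stopifnot(n_channels >= 3, sfreq > 0, window_ms > 0, k_true >= 1,
            n_subjects >= 1, length(conditions) >= 1, is.finite(snr_db) ||
              is.infinite(snr_db))
  if (is.null(duration_mean_ms))
    duration_mean_ms <- .default_durations(conditions, k_true, null_effects)
  if (is.null(occupancy))
    occupancy <- .default_occupancy(conditions, k_true, null_effects)
  duration_mean_ms <- as.matrix(duration_mean_ms)
  occupancy <- as.matrix(occupancy)
  stopifnot(nrow(duration_mean_ms) == length(conditions),
            ncol(duration_mean_ms) == k_true,
            nrow(occupancy) == length(conditions),
            ncol(occupancy) == k_true)
  if (any(abs(rowSums(occupancy) - 1) > 1e-8))
    stop("occupancy weights must sum to 1 per condition")
  rownames(duration_mean_ms) <- rownames(occupancy) <- conditions
  structure(list(
    n_channels = n_channels, sfreq = sfreq, window_ms = window_ms,
    k_true = k_true, n_subjects = n_subjects, conditions = conditions,
    duration_mean_ms = duration_mean_ms, occupancy = occupancy,
    duration_sd_ms = duration_sd_ms, min_run_frames = min_run_frames,
    snr_db = snr_db, amplitude_uv = amplitude_uv,
    envelope_peaks_ms = envelope_peaks_ms,
    envelope_widths_ms = envelope_widths_ms,
    envelope_amps = envelope_amps, envelope_floor = envelope_floor,
    template_smoothness = template_smoothness,
    noise_smoothness = noise_smoothness,
    template_max_abs_r = template_max_abs_r,
    subject_duration_sd = subject_duration_sd,
    subject_template_jitter = subject_template_jitter,
    hand_mean = hand_mean, hand_sd = hand_sd, beta_hand = beta_hand,
    null_effects = null_effects), class = "ms_synth_spec")
}

# Planted condition pattern: class 4 runs longer for LVF than RVF
# unilateral presentations; everything else at the 100 ms baseline.
.default_durations <- function(conditions, k, null_effects) {
  m <- matrix(100, length(conditions), k,
              dimnames = list(conditions, NULL))
  if (!null_effects && k >= 4) {
    des <- condition_design()
    lvf <- des$condition[!is.na(des$side) & des$side == "LVF"]
    rvf <- des$condition[!is.na(des$side) & des$side == "RVF"]
    m[intersect(conditions, lvf), 4] <- 125
    m[intersect(conditions, rvf), 4] <- 95
  }
  m
}

# Planted occupancy: class 2 favored in unilateral and suppressed in
# bilateral presentations (higher unilateral occurrence and coverage);
# class 4 favored for LVF over RVF unilateral presentations, so its
# higher LVF coverage is planted directly rather than only through the
# longer run lengths (which window truncation dampens).
.default_occupancy <- function(conditions, k, null_effects) {
  m <- matrix(1 / k, length(conditions), k,
              dimnames = list(conditions, NULL))
  if (!null_effects && k >= 2) {
    des <- condition_design()
    uni <- des$condition[des$presentation == "unilateral"]
    bil <- des$condition[des$presentation == "bilateral"]
    lvf <- des$condition[!is.na(des$side) & des$side == "LVF"]
    for (cc in intersect(conditions, uni)) {
      m[cc, ] <- (1 - 0.30) / (k - 1); m[cc, 2] <- 0.30
      if (k >= 4) {
        c4 <- if (cc %in% lvf) 0.26 else 0.18
        rest <- (1 - 0.30 - c4) / (k - 2)
        m[cc, ] <- rest; m[cc, 2] <- 0.30; m[cc, 4] <- c4
      }
    }
    for (cc in intersect(conditions, bil)) {
      m[cc, ] <- (1 - 0.18) / (k - 1); m[cc, 2] <- 0.18
    }
  }
  m
}

#' @export
print.ms_synth_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<ms_synth_spec> %d subjects x %d conditions, %d channels @ %g Hz,\n",
    "  %g ms window, k_true = %d, SNR %g dB%s\n"),
    x$n_subjects, length(x$conditions), x$n_channels, x$sfreq,
    x$window_ms, x$k_true, x$snr_db,
    if (x$null_effects) ", null effects" else ", planted effects"))
  invisible(x)
}

#' Planted template topographies
#'
#' Generates `k_true` zero-mean, unit-norm maps with pairwise `|r|` at or
#' below `template_max_abs_r`: smooth random maps are orthogonalized, then
#' blended back toward their smooth (correlated) versions as far as the
#' bound allows. Deterministic given the seed.
#'
#' @param spec An `ms_synth_spec`.
#' @param montage Montage with positions (default generated from the spec).
#' @param seed Optional integer seed.
#' @return Channels x `k_true` matrix of template maps.
#' @export
make_templates <- function(spec, montage = NULL, seed = NULL) {
  if (is.null(montage)) montage <- synthetic_montage(spec$n_channels)
  C <- n_channels(montage)
  k <- spec$k_true
  if (k > C - 1)
    stop("cannot plant more templates than channels - 1 ",
         "(zero-mean maps span a space of dimension channels - 1)")
  run <- function() {
    K <- .smoothing_kernel(montage, spec$template_smoothness)
    S <- K %*% matrix(rnorm(C * k), C, k)
    S <- sweep(S, 2, colMeans(S), "-")
    if (qr(S)$rank < k)
      stop("degenerate smooth maps; try another seed or smoothness")
    O <- qr.Q(qr(S))[, seq_len(k), drop = FALSE] # orthonormal, zero-mean
    O <- sweep(O, 2, colMeans(O), "-")           # guard numeric drift
    O <- sweep(O, 2, sqrt(colSums(O^2)), "/")
    Sn <- sweep(S, 2, sqrt(colSums(S^2)), "/")
    blend <- function(lambda) {
      TT <- (1 - lambda) * O + lambda * Sn
      TT <- sweep(TT, 2, colMeans(TT), "-")
      sweep(TT, 2, sqrt(colSums(TT^2)), "/")
    }
    max_r <- function(TT) {
      R <- abs(crossprod(TT)); max(R[upper.tri(R)], 0)
    }
    lambda <- 1
    TT <- blend(lambda)
    while (max_r(TT) > spec$template_max_abs_r && lambda > 1e-6) {
      lambda <- lambda / 2
      TT <- blend(lambda)
    }
    if (max_r(TT) > spec$template_max_abs_r) TT <- blend(0)
    colnames(TT) <- sprintf("M%d", seq_len(k))
    TT
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Planted microstate label sequence
#'
#' Semi-Markov sequence: the next class is drawn from the condition's
#' occupancy weights excluding the current class (no self-transitions); run
#' lengths are truncated-normal draws around the condition's class duration
#' mean (at least `min_run_frames`). The final run is cut at the window
#' edge.
#'
#' @param spec An `ms_synth_spec`.
#' @param condition Condition code (row of the spec's parameter matrices).
#' @param duration_offset_ms Optional per-class additive offset (subject
#'   random effect).
#' @param require_all_classes If `TRUE`, sequences are redrawn until every
#'   planted class occurs in the window. With run lengths around 100 ms and
#'   a 400 ms window a class can otherwise be absent by chance, in which
#'   case the epoch simply does not carry `k_true` states; planted-k
#'   recovery studies condition on presence through this flag.
#' @param seed Optional integer seed.
#' @return Integer label vector of `window_ms / 1000 * sfreq` frames, with
#'   attribute `runs`: data frame `class`, `frames` (as drawn), `truncated`.
#' @export
make_sequence <- function(spec, condition, duration_offset_ms = NULL,
                          require_all_classes = FALSE, seed = NULL) {
  mu <- spec$duration_mean_ms[condition, ]
  if (!is.null(duration_offset_ms)) mu <- pmax(mu + duration_offset_ms, 20)
  w <- spec$occupancy[condition, ]
  n_frames <- round(spec$window_ms / 1000 * spec$sfreq)
  sd_f <- spec$duration_sd_ms / 1000 * spec$sfreq
  mu_f <- mu / 1000 * spec$sfreq
  run <- function() {
    labels <- integer(0)
    runs <- list()
    prev <- 0L
    while (length(labels) < n_frames) {
      ww <- w
      if (prev > 0 && sum(w[-prev]) > 0) ww[prev] <- 0
      cl <- sample.int(spec$k_true, 1, prob = ww)
      len <- 0L
      for (try in 1:50) {
        len <- round(rnorm(1, mu_f[cl], sd_f))
        if (len >= spec$min_run_frames) break
      }
      len <- max(len, spec$min_run_frames)
      truncated <- length(labels) + len > n_frames
      runs[[length(runs) + 1]] <- data.frame(class = cl, frames = len,
                                             truncated = truncated)
      labels <- c(labels, rep(cl, len))
      prev <- cl
    }
    labels <- labels[seq_len(n_frames)]
    attr(labels, "runs") <- do.call(rbind, runs)
    labels
  }
  draw <- function() {
    for (try in 1:200) {
      lab <- run()
      if (!require_all_classes ||
          length(unique(lab)) == spec$k_true) return(lab)
    }
    stop("could not draw a sequence containing all classes; the window is ",
         "too short for the requested durations")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# raised-cosine ERP amplitude envelope over frame times (ms)
.envelope <- function(times_ms, spec) {
  env <- rep(spec$envelope_floor, length(times_ms))
  for (i in seq_along(spec$envelope_peaks_ms)) {
    p <- spec$envelope_peaks_ms[i]
    hw <- spec$envelope_widths_ms[i] / 2
    inside <- abs(times_ms - p) < hw
    env[inside] <- env[inside] + spec$envelope_amps[i] *
      0.5 * (1 + cos(pi * (times_ms[inside] - p) / hw))
  }
  env
}

#' Render one synthetic ERP epoch
#'
#' Frame t is `envelope(t) * sign(run) * template[label(t)]` plus spatially
#' correlated Gaussian noise scaled so that the epoch-level ratio of mean
#' squared signal GFP to mean squared noise GFP matches `snr_db`. Each run
#' carries an independent random polarity. The epoch is average-referenced.
#'
#' @param templates Channels x k template matrix.
#' @param labels Planted label sequence ([make_sequence()] output).
#' @param spec An `ms_synth_spec`.
#' @param montage Montage with positions.
#' @param subject,condition Identifiers stamped on the epoch.
#' @param seed Optional integer seed.
#' @return An [erp_epoch()] with attribute `ground_truth` (list: `labels`,
#'   `signs` per frame, `realized_snr_db`).
#' @export
render_epoch <- function(templates, labels, spec, montage = NULL,
                         subject = "s01", condition = "unknown",
                         seed = NULL) {
  if (is.null(montage)) montage <- synthetic_montage(spec$n_channels)
  C <- nrow(templates)
  n <- length(labels)
  times <- (seq_len(n) - 1) * 1000 / spec$sfreq
  env <- .envelope(times, spec)
  run <- function() {
    r <- rle(as.integer(labels))
    run_signs <- sample(c(-1, 1), length(r$lengths), replace = TRUE)
    signs <- rep(run_signs, r$lengths)
    amp <- env * spec$amplitude_uv * sqrt(C)
    signal <- templates[, labels, drop = FALSE] *
      rep(amp * signs, each = C)
    signal <- sweep(signal, 2, colMeans(signal), "-")
    realized <- Inf
    noise <- 0
    if (is.finite(spec$snr_db)) {
      K <- .smoothing_kernel(montage, spec$noise_smoothness)
      noise <- K %*% matrix(rnorm(C * n), C, n)
      noise <- sweep(noise, 2, colMeans(noise), "-")
      g_s <- mean(colMeans(signal^2))
      g_n <- mean(colMeans(noise^2))
      noise <- noise * sqrt(g_s / (g_n * 10^(spec$snr_db / 10)))
      realized <- 10 * log10(g_s / mean(colMeans(noise^2)))
    }
    data <- signal + noise
    ep <- erp_epoch(data, sfreq = spec$sfreq, t0 = 0, subject = subject,
                    condition = condition, montage = montage)
    ep <- apply_average_reference(ep)
    attr(ep, "ground_truth") <- list(labels = as.integer(labels),
                                     signs = signs,
                                     realized_snr_db = realized)
    ep
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a full synthetic cohort
#'
#' Epochs for every subject x condition with subject random effects (small
#' jitter on duration means and on the template maps) plus synthetic
#' handedness scores, optionally coupled to the subject's class-1 duration
#' offset through `beta_hand`. Fully deterministic given spec and seed.
#'
#' @param spec An `ms_synth_spec`.
#' @param seed Integer seed.
#' @return An object of class `ms_cohort`: `epochs` (named list,
#'   `subject.condition`), `templates` (planted, channels x k),
#'   `sequences` (planted label vectors, same names), `handedness` (named
#'   per-subject scores), `subject_offsets` (subjects x classes duration
#'   offsets, ms), `montage`, `spec`, `seed`.
#' @export
make_cohort <- function(spec, seed = 1L) {
  withr::with_seed(seed, {
    montage <- synthetic_montage(spec$n_channels)
    templates <- make_templates(spec, montage)
    K_t <- .smoothing_kernel(montage, spec$template_smoothness)
    subjects <- sprintf("s%02d", seq_len(spec$n_subjects))
    offsets <- matrix(rnorm(spec$n_subjects * spec$k_true, 0,
                            spec$subject_duration_sd),
                      spec$n_subjects, spec$k_true,
                      dimnames = list(subjects, NULL))
    hand <- spec$hand_mean + spec$hand_sd * rnorm(spec$n_subjects) +
      spec$beta_hand * offsets[, 1]
    hand <- pmin(100, pmax(-100, hand))
    names(hand) <- subjects

    epochs <- list(); sequences <- list()
    for (s in seq_along(subjects)) {
      subj_T <- templates
      if (spec$subject_template_jitter > 0) {
        J <- K_t %*% matrix(rnorm(length(templates)), nrow(templates))
        J <- sweep(J, 2, colMeans(J), "-")
        J <- sweep(J, 2, sqrt(colSums(J^2)), "/")
        subj_T <- templates + spec$subject_template_jitter * J
        subj_T <- sweep(subj_T, 2, colMeans(subj_T), "-")
        subj_T <- sweep(subj_T, 2, sqrt(colSums(subj_T^2)), "/")
      }
      for (cc in spec$conditions) {
        lab <- make_sequence(spec, cc, duration_offset_ms = offsets[s, ])
        ep <- render_epoch(subj_T, lab, spec, montage,
                           subject = subjects[s], condition = cc)
        id <- paste(subjects[s], cc, sep = ".")
        epochs[[id]] <- ep
        sequences[[id]] <- as.integer(lab)
      }
    }
    structure(list(epochs = epochs, templates = templates,
                   sequences = sequences, handedness = hand,
                   subject_offsets = offsets, montage = montage,
                   spec = spec, seed = seed),
              class = "ms_cohort")
  })
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat(sprintf("<ms_cohort> %d epochs (%d subjects x %d conditions), seed %s\n",
              length(x$epochs), x$spec$n_subjects,
              length(x$spec$conditions), format(x$seed)))
  invisible(x)
}
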