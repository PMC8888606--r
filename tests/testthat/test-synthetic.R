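test_that("planted templates respect zero mean, unit norm and the |r| bound", {
  spec <- synthetic_spec()
  TT <- make_templates(spec, seed = 3)
  expect_equal(dim(TT), c(128, 4))
  expect_equal(unname(colMeans(TT)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(colSums(TT^2)), rep(1, 4), tolerance = 1e-10)
  R <- abs(crossprod(TT))
  expect_lte(max(R[upper.tri(R)]), 0.5 + 1e-9)

  # bound 0 forces exact orthogonality
  spec0 <- synthetic_spec(n_channels = 32, k_true = 2,
                          template_max_abs_r = 0)
  T0 <- make_templates(spec0, seed = 4)
  expect_equal(abs(sum(T0[, 1] * T0[, 2])), 0, tolerance = 1e-9)

  # rank limit
  specbad <- synthetic_spec(n_channels = 8, k_true = 8)
  expect_error(make_templates(specbad, seed = 1), "channels - 1")
})

test_that("sequence generator respects occupancy and run-length model", {
  # degenerate occupancy: single class
  spec1 <- synthetic_spec(n_channels = 16, k_true = 2,
                          occupancy = matrix(c(1, 0), 8, 2, byrow = TRUE))
  lab <- make_sequence(spec1, "AN-LVF", seed = 5)
  expect_true(all(lab == 1))

  # law of large numbers: completed (untruncated) run lengths center on
  # the planted mean
  spec <- synthetic_spec(null_effects = TRUE)
  lens <- integer(0)
  withr::with_seed(6, {
    for (i in 1:1000) {
      lab <- make_sequence(spec, "AN-AN")
      r <- attr(lab, "runs")
      lens <- c(lens, r$frames[!r$truncated])
    }
  })
  mean_ms <- mean(lens) * 1000 / spec$sfreq
  expect_lt(abs(mean_ms - 100) / 100, 0.10)

  # no immediate self-transitions
  lab <- make_sequence(spec, "HA-HA", seed = 7)
  r <- rle(as.integer(lab))
  expect_true(all(diff(r$values) != 0))

  # conditioning on presence of all classes
  lab4 <- make_sequence(spec, "AN-AN", require_all_classes = TRUE,
                        seed = 8)
  expect_setequal(unique(lab4), 1:4)
})

test_that("rendered epochs hit the requested SNR and are referenced", {
  spec <- synthetic_spec(n_channels = 64)
  TT <- make_templates(spec, montage = synthetic_montage(64), seed = 9)
  snrs <- sapply(1:5, function(i) {
    lab <- make_sequence(spec, "AN-LVF", seed = 10 + i)
    ep <- render_epoch(TT, lab, spec, montage = synthetic_montage(64),
                       seed = 20 + i)
    expect_true(ep$referenced)
    expect_lt(max(abs(colMeans(ep$data))) / max(abs(ep$data)), 1e-10)
    attr(ep, "ground_truth")$realized_snr_db
  })
  expect_true(all(abs(snrs - 5) < 0.5))
})

test_that("noise-free epochs backfit to the planted sequence exactly", {
  spec <- synthetic_spec(n_channels = 32, snr_db = Inf)
  mont <- synthetic_montage(32)
  TT <- make_templates(spec, montage = mont, seed = 11)
  lab <- make_sequence(spec, "HA-LVF", seed = 12)
  ep <- render_epoch(TT, lab, spec, montage = mont, seed = 13)
  sq <- backfit(ep, TT)
  expect_identical(sq$labels, as.integer(lab))
})

test_that("per-run sign flips never leak into labels or metrics", {
  # render the same sequence twice with different RNG (signs/noise off)
  spec <- synthetic_spec(n_channels = 32, snr_db = Inf)
  mont <- synthetic_montage(32)
  TT <- make_templates(spec, montage = mont, seed = 14)
  lab <- make_sequence(spec, "AN-HA", seed = 15)
  ep1 <- render_epoch(TT, lab, spec, montage = mont, seed = 16)
  ep2 <- render_epoch(TT, lab, spec, montage = mont, seed = 17)
  s1 <- backfit(ep1, TT); s2 <- backfit(ep2, TT)
  expect_identical(s1$labels, s2$labels)
  expect_equal(microstate_metrics(s1), microstate_metrics(s2))
})

test_that("cohorts are complete and byte-identical under a fixed seed", {
  spec <- small_spec(snr_db = 10)
  a <- make_cohort(spec, seed = 18)
  b <- make_cohort(spec, seed = 18)
  expect_identical(a, b)
  expect_equal(length(a$epochs), 3 * 3)
  expect_named(a$handedness, sprintf("s%02d", 1:3))
  expect_true(all(a$handedness >= -100 & a$handedness <= 100))
  # a different seed changes the data
  c <- make_cohort(spec, seed = 19)
  expect_false(identical(a$epochs[[1]]$data, c$epochs[[1]]$data))
})

test_that("handedness link plants a recoverable correlation", {
  spec <- synthetic_spec(n_channels = 16, k_true = 2, n_subjects = 12,
                         conditions = c("AN-LVF", "AN-RVF"),
                         subject_duration_sd = 10, hand_sd = 0.01,
                         beta_hand = 1)
  co <- make_cohort(spec, seed = 20)
  # scores reproduce the class-1 duration offsets up to the tiny noise
  r <- cor(co$handedness, co$subject_offsets[, 1])
  expect_gt(r, 0.99)
})

test_that("planted condition effects shape the realized label statistics", {
  # over enough sequences, LVF class-4 planted runs are ~30 ms longer
  # than RVF ones and unilateral class-2 occupancy exceeds bilateral
  spec <- synthetic_spec()
  withr::with_seed(21, {
    mean_run4 <- function(cond) {
      lens <- integer(0)
      for (i in 1:120) {
        r <- attr(make_sequence(spec, cond), "runs")
        lens <- c(lens, r$frames[r$class == 4 & !r$truncated])
      }
      mean(lens) * 1000 / spec$sfreq
    }
    d_lvf <- mean_run4("AN-LVF"); d_rvf <- mean_run4("AN-RVF")
    expect_gt(d_lvf - d_rvf, 15)
    frac2 <- function(cond) {
      mean(sapply(1:100, function(i)
        mean(make_sequence(spec, cond) == 2)))
    }
    expect_gt(frac2("HA-LVF"), frac2("HA-HA"))
  })
})
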