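test_that("one-way rm-ANOVA matches the hand-computed SS oracle", {
  withr::with_seed(101, {
    d <- expand.grid(subject = sprintf("s%d", 1:4),
                     condition = c("A", "B", "C"),
                     stringsAsFactors = FALSE)
    d$duration_ms <- round(rnorm(12, 100, 10), 1)
  })
  got <- rm_anova(d, dv = "duration_ms", within = "condition")
  want <- oracle_oneway_rm(d, "duration_ms", "condition")
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$df_effect, want$df[1])
  expect_equal(got$df_error, want$df[2])
  expect_equal(got$MSE, want$MSE, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$partial_eta_sq, want$pes, tolerance = 1e-10)
})

test_that("two-way rm-ANOVA tests each effect against its own stratum", {
  withr::with_seed(103, {
    d <- expand.grid(subject = sprintf("s%d", 1:8),
                     emotion = c("AN", "HA"), side = c("LVF", "RVF"),
                     stringsAsFactors = FALSE)
    subj_eff <- rnorm(8, 0, 5)
    d$coverage_pct <- 25 + 4 * (d$side == "LVF") +
      subj_eff[match(d$subject, sprintf("s%d", 1:8))] + rnorm(32, 0, 2)
  })
  got <- rm_anova(d, dv = "coverage_pct", within = c("emotion", "side"))
  expect_setequal(got$effect, c("emotion", "side", "emotion:side"))
  expect_true(all(got$df_effect == 1))
  expect_true(all(got$df_error == 7))
  # cross-check the side main effect against a paired t-test: F = t^2
  side_means <- with(d, tapply(coverage_pct, list(subject, side), mean))
  tt <- t.test(side_means[, "LVF"], side_means[, "RVF"], paired = TRUE)
  expect_equal(got$F[got$effect == "side"], unname(tt$statistic)^2,
               tolerance = 1e-9)
  expect_equal(got$p[got$effect == "side"], tt$p.value, tolerance = 1e-9)
})

test_that("constant data give F = 0 and p = 1; missing cells are named", {
  d <- expand.grid(subject = sprintf("s%d", 1:5), condition = c("A", "B"),
                   stringsAsFactors = FALSE)
  d$v <- rep(1:5, 2) # identical across conditions within subject
  got <- rm_anova(d, dv = "v", within = "condition")
  expect_equal(got$F, 0)
  expect_equal(got$p, 1)

  d2 <- d[-3, ]
  expect_error(rm_anova(d2, dv = "v", within = "condition"),
               "incomplete design: subject 's3'")
  d3 <- d; d3$v[4] <- NA
  expect_error(rm_anova(d3, dv = "v", within = "condition"), "missing v")
})

test_that("rm-ANOVA is invariant to row and level ordering", {
  withr::with_seed(107, {
    d <- expand.grid(subject = sprintf("s%d", 1:6),
                     condition = c("A", "B", "C", "D"),
                     stringsAsFactors = FALSE)
    d$v <- rnorm(24, 50, 8)
  })
  a <- rm_anova(d, dv = "v", within = "condition")
  b <- rm_anova(d[rev(seq_len(nrow(d))), ], dv = "v", within = "condition")
  expect_equal(a$F, b$F, tolerance = 1e-12)
  # relabeling the factor levels permutes nothing that matters
  d2 <- d; d2$condition <- chartr("ABCD", "DCBA", d2$condition)
  c2 <- rm_anova(d2, dv = "v", within = "condition")
  expect_equal(a$F, c2$F, tolerance = 1e-12)
})

test_that("Duncan at two levels reduces to the rank-2 studentized range", {
  withr::with_seed(109, {
    d <- expand.grid(subject = sprintf("s%d", 1:10),
                     condition = c("A", "B"), stringsAsFactors = FALSE)
    d$v <- 10 + 3 * (d$condition == "B") + rnorm(20, 0, 2)
  })
  res <- suppressWarnings(duncan_posthoc(d, dv = "v", factor = "condition"))
  expect_equal(nrow(res), 1)
  an <- rm_anova(d, dv = "v", within = "condition")
  means <- tapply(d$v, d$condition, mean)
  q_obs <- abs(diff(means)) / sqrt(an$MSE[1] / 10)
  # closed-form check: protection level (1-alpha)^(2-1) = 1 - alpha
  expect_equal(res$p, unname(1 - ptukey(q_obs, 2, an$df_error[1])),
               tolerance = 1e-10)
  expect_equal(res$significant,
               unname(q_obs > qtukey(0.95, 2, an$df_error[1])))
})

test_that("Duncan flags all pairs for well-separated means and none for ties", {
  withr::with_seed(111, {
    d <- expand.grid(subject = sprintf("s%d", 1:8),
                     condition = c("A", "B", "C", "D"),
                     stringsAsFactors = FALSE)
    d$v <- 10 * match(d$condition, c("A", "B", "C", "D")) +
      rnorm(32, 0, 0.1)
  })
  res <- duncan_posthoc(d, dv = "v", factor = "condition")
  expect_equal(nrow(res), 6)
  expect_true(all(res$significant))

  d$v <- rep(5, 32)
  res0 <- suppressWarnings(duncan_posthoc(d, dv = "v",
                                          factor = "condition"))
  expect_false(any(res0$significant))
})

test_that("Duncan results are invariant to level label permutation", {
  withr::with_seed(113, {
    d <- expand.grid(subject = sprintf("s%d", 1:6),
                     condition = c("A", "B", "C"), stringsAsFactors = FALSE)
    d$v <- rnorm(18, 20, 4)
  })
  r1 <- suppressWarnings(duncan_posthoc(d, dv = "v", factor = "condition"))
  d2 <- d; d2$condition <- chartr("ABC", "CAB", d2$condition)
  r2 <- suppressWarnings(duncan_posthoc(d2, dv = "v",
                                        factor = "condition"))
  key <- function(r) {
    m <- regmatches(r$pair, regexec("(.) - (.)", r$pair))
    vapply(m, function(x) paste(sort(c(x[2], x[3])), collapse = ""), "")
  }
  k1 <- key(r1); k2 <- chartr("CAB", "ABC", key(r2))
  k2 <- vapply(strsplit(k2, ""), function(x)
    paste(sort(x), collapse = ""), "")
  expect_equal(r1$p[order(k1)], r2$p[order(k2)], tolerance = 1e-12)
  expect_error(duncan_posthoc(d[d$condition == "A", ], dv = "v",
                              factor = "condition"), "2 levels")
})

test_that("handedness correlations recover exact linear relations", {
  tab <- expand.grid(subject = sprintf("s%02d", 1:10),
                     condition = c("A", "B"), class = 1:2,
                     stringsAsFactors = FALSE)
  scores <- seq(-90, 90, length.out = 10)
  names(scores) <- sprintf("s%02d", 1:10)
  tab$duration_ms <- 50 + 0.3 * scores[tab$subject]
  tab$occurrence_hz <- 10 - 0.05 * scores[tab$subject]
  tab$coverage_pct <- 25
  res <- metric_handedness_correlation(
    tab, scores, metrics = c("duration_ms", "occurrence_hz"))
  expect_equal(res$r[res$metric == "duration_ms"], c(1, 1),
               tolerance = 1e-12)
  expect_equal(res$r[res$metric == "occurrence_hz"], c(-1, -1),
               tolerance = 1e-12)
  # zero variance errors
  expect_error(metric_handedness_correlation(tab, scores,
                                             metrics = "coverage_pct"),
               "zero variance")
  # independent scores: near-zero correlation on a large sample
  withr::with_seed(115, {
    big <- expand.grid(subject = sprintf("s%03d", 1:100), condition = "A",
                       class = 1, stringsAsFactors = FALSE)
    big$duration_ms <- rnorm(100, 50, 5)
    sc <- rnorm(100, 0, 30); names(sc) <- big$subject
    r <- metric_handedness_correlation(big, sc,
                                       metrics = "duration_ms")$r
    expect_lt(abs(r), 0.25)
  })
})

test_that("the analysis battery replays the condition-level design", {
  withr::with_seed(117, {
    des <- condition_design()
    tab <- expand.grid(subject = sprintf("s%02d", 1:8),
                       condition = des$condition, class = 1:4,
                       stringsAsFactors = FALSE)
    tab$duration_ms <- rnorm(nrow(tab), 100, 10)
    tab$occurrence_hz <- rnorm(nrow(tab), 10, 1)
    tab$coverage_pct <- rnorm(nrow(tab), 25, 3)
    scores <- rnorm(8, 70, 15); names(scores) <- sprintf("s%02d", 1:8)
  })
  out <- run_battery(tab, handedness = scores)
  an <- out$anovas
  expect_true(all(c("omnibus_microstate", "unilateral_emotion_x_side",
                    "bilateral_condition", "valence_negative",
                    "valence_positive") %in% an$family))
  # per class: 3 unilateral effects, 1 bilateral, 2 valence families
  uni <- an[an$family == "unilateral_emotion_x_side" &
              an$dv == "duration_ms", ]
  expect_equal(nrow(uni), 4 * 3)
  expect_equal(nrow(out$correlations), 4 * 3)
  expect_equal(length(out$skipped), 0)
})
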