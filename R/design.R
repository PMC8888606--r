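#' The divided-visual-field condition design
#'
#' Eight conditions of the emotional-faces paradigm: four unilateral (one
#' angry or happy face in the left or right visual field) and four bilateral
#' (two faces, one per hemifield; codes give LVF-RVF content).
#'
#' @return Data frame: `condition`, `presentation`
#'   (unilateral/bilateral), `emotion` (AN/HA, unilateral only), `side`
#'   (LVF/RVF, unilateral only), `lvf`, `rvf` (hemifield contents).
#' @export
condition_design <- function() {
  data.frame(
    condition = c("AN-LVF", "AN-RVF", "HA-LVF", "HA-RVF",
                  "AN-AN", "HA-HA", "AN-HA", "HA-AN"),
    presentation = rep(c("unilateral", "bilateral"), each = 4),
    emotion = c("AN", "AN", "HA", "HA", NA, NA, NA, NA),
    side = c("LVF", "RVF", "LVF", "RVF", NA, NA, NA, NA),
    lvf = c("AN", NA, "HA", NA, "AN", "HA", "AN", "HA"),
    rvf = c(NA, "AN", NA, "HA", "AN", "HA", "HA", "AN"),
    stringsAsFactors = FALSE)
}

#' Condition families for the valence analyses
#'
#' The five-condition families used when each valence is analyzed
#' separately: every condition in which an angry (negative) or happy
#' (positive) face appears in some hemifield. The bilateral mixed conditions
#' belong to both families.
#'
#' @return Named list of two character vectors (`negative`, `positive`).
#' @export
valence_families <- function() {
  list(negative = c("AN-LVF", "AN-RVF", "AN-AN", "AN-HA", "HA-AN"),
       positive = c("HA-LVF", "HA-RVF", "HA-HA", "HA-AN", "AN-HA"))
}

#' The default condition-level analysis battery
#'
#' Declarative description of the group-level tests run on a metrics table:
#' for each metric, (i) a one-way within-subject ANOVA over microstate
#' classes (values averaged over conditions per subject); (ii) per class, a
#' 2x2 Emotion x Side ANOVA on the unilateral conditions and a one-way
#' ANOVA over the bilateral conditions; (iii) per class and valence family,
#' a 5-level one-way ANOVA; plus Pearson correlations with handedness
#' scores when supplied.
#'
#' @param metrics Metric columns to analyze.
#' @param alpha Significance threshold.
#' @return A list describing the battery, consumed by [run_battery()].
#' @export
default_battery <- function(metrics = c("duration_ms", "occurrence_hz",
                                        "coverage_pct"),
                            alpha = 0.05) {
  list(metrics = metrics, alpha = alpha,
       omnibus_classes = TRUE,
       unilateral_emotion_side = TRUE,
       bilateral_oneway = TRUE,
       valence = TRUE,
       handedness = TRUE)
}

#' Run the condition-level analysis battery
#'
#' Replays the battery described by [default_battery()] on a metrics table.
#' Duration is undefined for classes absent from an epoch; analyses
#' involving such missing cells are skipped with a note rather than
#' aborting the battery (occurrence and coverage are always complete).
#'
#' @param table Metrics table ([build_metrics_table()] output).
#' @param handedness Optional named vector of per-subject handedness scores.
#' @param battery Battery description (default [default_battery()]).
#' @param design Condition design table (default [condition_design()]).
#' @return List with `anovas` (one data frame of all effects, with `family`
#'   and `class` context columns), `correlations` (or `NULL`), `skipped`
#'   (character vector of skipped analyses).
#' @export
run_battery <- function(table, handedness = NULL,
                        battery = default_battery(),
                        design = condition_design()) {
  res <- list(); skipped <- character()
  classes <- sort(unique(table$class))
  tab <- merge(table, design, by = "condition", sort = FALSE)

  add <- function(an, family, class, dv) {
    an$family <- family; an$class <- class; an$dv <- dv
    res[[length(res) + 1]] <<- an
  }
  try_anova <- function(d, dv, within, family, class) {
    out <- tryCatch(rm_anova(d, dv = dv, within = within),
                    error = function(e) conditionMessage(e))
    if (is.character(out)) {
      skipped <<- c(skipped, sprintf("%s [%s, class %s]: %s", family, dv,
                                     as.character(class), out))
    } else {
      add(out, family, class, dv)
    }
  }

  for (dv in battery$metrics) {
    if (isTRUE(battery$omnibus_classes)) {
      agg <- aggregate(tab[[dv]],
                       list(subject = tab$subject, class = tab$class),
                       mean, na.rm = TRUE)
      names(agg)[3] <- dv
      try_anova(agg, dv, "class", "omnibus_microstate", NA)
    }
    for (cl in classes) {
      sub <- tab[tab$class == cl, ]
      if (isTRUE(battery$unilateral_emotion_side))
        try_anova(sub[sub$presentation == "unilateral", ], dv,
                  c("emotion", "side"), "unilateral_emotion_x_side", cl)
      if (isTRUE(battery$bilateral_oneway))
        try_anova(sub[sub$presentation == "bilateral", ], dv, "condition",
                  "bilateral_condition", cl)
      if (isTRUE(battery$valence)) {
        fam <- valence_families()
        for (v in names(fam))
          try_anova(sub[sub$condition %in% fam[[v]], ], dv, "condition",
                    paste0("valence_", v), cl)
      }
    }
  }

  correlations <- NULL
  if (isTRUE(battery$handedness) && !is.null(handedness)) {
    correlations <- tryCatch(
      metric_handedness_correlation(table, handedness,
                                    metrics = battery$metrics),
      error = function(e) {
        skipped <<- c(skipped,
                      sprintf("handedness correlations: %s",
                              conditionMessage(e)))
        NULL
      })
  }
  anovas <- if (length(res)) do.call(rbind, res) else NULL
  list(anovas = anovas, correlations = correlations, skipped = skipped)
}
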