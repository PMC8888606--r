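#' Pipeline configuration
#'
#' Validated configuration of the end-to-end analysis. Either a synthetic
#' cohort spec or a directory of ERP epoch files (prefixes readable by
#' [read_erp_epoch()]) provides the input.
#'
#' @param synthetic An `ms_synth_spec` (or `NULL` when reading from disk).
#' @param input_dir Directory of `<prefix>.tsv`/`.yaml` epoch pairs (used
#'   when `synthetic` is `NULL`).
#' @param out_dir Output directory (created if needed); `NULL` disables
#'   artifact writing.
#' @param window_ms Analysis window in ms.
#' @param k_range Contiguous candidate k values starting at 1.
#' @param kl_rule Krzanowski-Lai selection rule, see [kl_criterion()].
#' @param n_restarts,max_iter,tol Clustering parameters.
#' @param seed Integer seed driving every stochastic stage.
#' @param battery Analysis battery (default [default_battery()]).
#' @return A validated list of class `ms_pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input_dir = NULL,
                            out_dir = NULL, window_ms = c(0, 400),
                            k_range = 1:12,
                            kl_rule = c("second_max", "global_max",
                                        "first_max"),
                            n_restarts = 64, max_iter = 300, tol = 1e-7,
                            seed = 1L, battery = default_battery()) {
  kl_rule <- match.arg(kl_rule)
  if (is.null(synthetic) && is.null(input_dir))
    stop("provide either a synthetic spec or an input directory")
  if (length(k_range) < 4)
    stop("k_range must contain at least 4 values (1..4) so the KL ",
         "criterion can form a second maximum; widen k_range")
  if (k_range[1] != 1) stop("k_range must start at 1")
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 out_dir = out_dir, window_ms = window_ms,
                 k_range = k_range, kl_rule = kl_rule,
                 n_restarts = n_restarts, max_iter = max_iter, tol = tol,
                 seed = as.integer(seed), battery = battery),
            class = "ms_pipeline_config")
}

.load_epochs <- function(config) {
  if (!is.null(config$synthetic)) {
    cohort <- make_cohort(config$synthetic, seed = config$seed)
    list(epochs = cohort$epochs, cohort = cohort,
         handedness = cohort$handedness)
  } else {
    prefixes <- sub("\\.yaml$", "",
                    list.files(config$input_dir, pattern = "\\.yaml$",
                               full.names = TRUE))
    prefixes <- prefixes[file.exists(paste0(prefixes, ".tsv"))]
    if (length(prefixes) == 0)
      stop("no epoch files (<prefix>.tsv + .yaml) in ", config$input_dir)
    eps <- lapply(prefixes, read_erp_epoch)
    names(eps) <- vapply(eps, function(e)
      paste(e$subject, e$condition, sep = "."), "")
    list(epochs = eps, cohort = NULL, handedness = NULL)
  }
}

#' Run the full microstate pipeline
#'
#' Stage order: load or simulate the cohort; average-reference and crop
#' every epoch; per-epoch k selection (modified k-means over `k_range`,
#' Krzanowski-Lai rule); pool subject templates; group-level clustering;
#' canonical ordering of global templates by cohort coverage; backfitting;
#' metrics table; condition-level statistics. Artifacts (effective config
#' with hash, templates, sequences, metrics, ANOVA tables) are written to
#' `out_dir` when set. Rerunning with an identical config reproduces the
#' outputs bit for bit.
#'
#' @param config An [pipeline_config()] object.
#' @param handedness Optional named per-subject handedness scores
#'   (overrides cohort-generated ones).
#' @param progress Emit per-stage messages.
#' @return List: `global_templates`, `selections` (per-epoch k-selection
#'   results), `sequences`, `metrics`, `stats`, `handedness`, `cohort`
#'   (when synthetic), `config`, `config_hash`.
#' @export
run_pipeline <- function(config, handedness = NULL, progress = TRUE) {
  stopifnot(inherits(config, "ms_pipeline_config"))
  hash <- rlang::hash(config)
  say <- function(...) if (progress) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  say("stage load: preparing epochs (config %s)", hash)
  inp <- stage("load", .load_epochs(config))
  epochs <- inp$epochs
  if (is.null(handedness)) handedness <- inp$handedness
  say("stage load: %d epochs", length(epochs))

  withr::with_seed(config$seed + 1L, {
    say("stage select-k: per-epoch clustering over k = %d..%d",
        min(config$k_range), max(config$k_range))
    selections <- stage("select-k", {
      out <- vector("list", length(epochs))
      names(out) <- names(epochs)
      for (i in seq_along(epochs)) {
        out[[i]] <- select_k_for_erp(
          epochs[[i]], k_range = config$k_range, rule = config$kl_rule,
          window_ms = config$window_ms, n_restarts = config$n_restarts,
          max_iter = config$max_iter, tol = config$tol)
        if (i %% 25 == 0) say("  select-k: %d / %d epochs", i,
                              length(epochs))
      }
      out
    })

    say("stage group: pooling %d subject-level template sets",
        length(selections))
    pooled <- stage("pool", pool_subject_templates(
      lapply(selections, `[[`, "clustering")))
    global <- stage("group", cluster_group(
      pooled$maps, k_range = config$k_range, rule = config$kl_rule,
      n_restarts = config$n_restarts, max_iter = config$max_iter,
      tol = config$tol))
    say("stage group: k_global = %d (GEV %.3f)", global$k_global,
        global$clustering$gev)

    say("stage backfit: %d epochs x %d templates", length(epochs),
        global$k_global)
    sequences <- stage("backfit", lapply(epochs, backfit,
                                         templates = global,
                                         window_ms = config$window_ms))
    global <- order_templates_by_coverage(global, sequences)
    # re-backfit so labels follow the canonical template order
    sequences <- lapply(epochs, backfit, templates = global,
                        window_ms = config$window_ms)

    say("stage metrics: building table")
    metrics <- stage("metrics", build_metrics_table(sequences))

    say("stage stats: condition-level battery")
    stats_out <- stage("stats", run_battery(metrics,
                                            handedness = handedness,
                                            battery = config$battery))
  })

  bundle <- list(global_templates = global, selections = selections,
                 sequences = sequences, metrics = metrics,
                 stats = stats_out, handedness = handedness,
                 cohort = inp$cohort, config = config, config_hash = hash)
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  cfg_list <- unclass(cfg)
  cfg_list$synthetic <- if (is.null(cfg$synthetic)) NULL
    else lapply(unclass(cfg$synthetic), function(x)
      if (is.matrix(x)) as.data.frame(x) else x)
  yaml::write_yaml(list(config = cfg_list, hash = bundle$config_hash),
                   file.path(out_dir, "config.yaml"))
  write_templates(bundle$global_templates,
                  file.path(out_dir, "global_templates"))
  seq_dir <- file.path(out_dir, "sequences")
  dir.create(seq_dir, showWarnings = FALSE)
  for (nm in names(bundle$sequences))
    write_sequence(bundle$sequences[[nm]], file.path(seq_dir, nm))
  write.csv(bundle$metrics, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  if (!is.null(bundle$stats$anovas))
    write.csv(bundle$stats$anovas, file.path(out_dir, "anovas.csv"),
              row.names = FALSE)
  if (!is.null(bundle$stats$correlations))
    write.csv(bundle$stats$correlations,
              file.path(out_dir, "handedness_correlations.csv"),
              row.names = FALSE)
  ksel <- data.frame(
    epoch = names(bundle$selections),
    chosen_k = vapply(bundle$selections, function(s) s$kl$chosen_k,
                      integer(1)),
    gev = vapply(bundle$selections, function(s) s$clustering$gev,
                 numeric(1)))
  write.csv(ksel, file.path(out_dir, "k_selection.csv"), row.names = FALSE)
  invisible(out_dir)
}
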