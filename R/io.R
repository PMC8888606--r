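#' @importFrom utils read.delim write.table read.csv write.csv
NULL

#' Write / read an ERP epoch as delimited text
#'
#' The normative on-disk form: a tab-delimited channels x frames matrix
#' (`<prefix>.tsv`, row names = channel labels) plus a YAML sidecar
#' (`<prefix>.yaml`) holding `sfreq`, `t0`, `subject`, `condition`,
#' `referenced` and the channel labels.
#'
#' @param epoch An [erp_epoch()].
#' @param prefix Path prefix (without extension).
#' @return `write_erp_epoch` returns the prefix invisibly;
#'   `read_erp_epoch` returns an [erp_epoch()].
#' @export
write_erp_epoch <- function(epoch, prefix) {
  m <- epoch$data
  rownames(m) <- epoch$montage$labels
  write.table(m, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              col.names = FALSE)
  meta <- list(sfreq = epoch$sfreq, t0 = epoch$t0, subject = epoch$subject,
               condition = epoch$condition, referenced = epoch$referenced,
               channels = epoch$montage$labels)
  yaml::write_yaml(meta, paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_erp_epoch
#' @param montage Optional [channel_montage()] overriding the sidecar
#'   labels (e.g. to attach positions).
#' @export
read_erp_epoch <- function(prefix, montage = NULL) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  m <- as.matrix(read.delim(paste0(prefix, ".tsv"), header = FALSE,
                            row.names = 1))
  colnames(m) <- NULL
  if (is.null(montage)) montage <- channel_montage(rownames(m))
  erp_epoch(unname(m), sfreq = meta$sfreq, t0 = meta$t0,
            subject = meta$subject, condition = meta$condition,
            montage = montage, referenced = isTRUE(meta$referenced))
}

#' Write / read a montage table
#'
#' Delimited table `label[, x, y, z]`.
#'
#' @param montage A [channel_montage()].
#' @param path File path.
#' @export
write_montage <- function(montage, path) {
  d <- data.frame(label = montage$labels)
  if (!is.null(montage$positions)) d <- cbind(d, montage$positions)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  pos <- if (all(c("x", "y", "z") %in% names(d)))
    as.matrix(d[, c("x", "y", "z")]) else NULL
  channel_montage(d$label, pos)
}

#' Write / read a template set
#'
#' Channels x k tab-delimited matrix plus YAML metadata (k, rule, seed,
#' provenance count, GEV when available).
#'
#' @param templates An `ms_templates` object.
#' @param prefix Path prefix.
#' @export
write_templates <- function(templates, prefix) {
  write.table(templates$templates, paste0(prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  meta <- list(k_global = templates$k_global, rule = templates$rule,
               seed = templates$seed, provenance_n = templates$provenance_n,
               gev = if (!is.null(templates$clustering))
                 templates$clustering$gev else NA)
  yaml::write_yaml(meta, paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_templates
#' @export
read_templates <- function(prefix) {
  m <- as.matrix(read.delim(paste0(prefix, ".tsv"), header = FALSE))
  colnames(m) <- NULL
  out <- as_ms_templates(unname(m))
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  out$rule <- meta$rule
  out$provenance_n <- meta$provenance_n
  out
}

#' Write a microstate sequence
#'
#' Tab-delimited `frame`, `label`, `fit_r` (label 0 = unassigned) plus a
#' YAML sidecar with sfreq / subject / condition / k.
#'
#' @param seq An `ms_sequence`.
#' @param prefix Path prefix.
#' @export
write_sequence <- function(seq, prefix) {
  d <- data.frame(frame = seq_along(seq$labels),
                  label = ifelse(is.na(seq$labels), 0L, seq$labels),
                  fit_r = seq$fit_r)
  write.table(d, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  yaml::write_yaml(list(sfreq = seq$sfreq, subject = seq$subject,
                        condition = seq$condition, k = seq$k),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  d <- read.delim(paste0(prefix, ".tsv"))
  lab <- d$label
  lab[lab == 0] <- NA_integer_
  s <- ms_sequence(lab, sfreq = meta$sfreq, subject = meta$subject,
                   condition = meta$condition, k = meta$k)
  s$fit_r <- d$fit_r
  s
}

#' Write the KL curve table
#' @param kl A `kl_curve`.
#' @param path File path.
#' @export
write_kl_curve <- function(kl, path) {
  write.table(kl$curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
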