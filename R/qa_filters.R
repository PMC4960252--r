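#' Quality-assurance filtration of feature tables
#'
#' The standard pooled-QC quality-assurance cascade for untargeted LC-MS
#' data: (1) keep features detected in at least a fraction of the QC
#' injections, (2) keep features whose QC coefficient of variation is below
#' a repeatability bound, (3) keep features detected in a large enough
#' fraction of at least one study group.  "Detected" means non-missing
#' after sentinel handling (vendor exports write 0/blank for non-detects).
#' Each stage returns a log record; [apply_qa_pipeline()] chains all three.
#'
#' @name qa_filters
NULL

qa_log <- function(stage, before_ids, after_ids) {
  removed <- setdiff(before_ids, after_ids)
  structure(
    list(stage_name = stage,
         n_features_before = length(before_ids),
         n_features_after = length(after_ids),
         removed_feature_ids = removed),
    class = "qa_filter_log")
}

#' @export
print.qa_filter_log <- function(x, ...) {
  cat(sprintf("[%s] %d -> %d features (%d removed)\n", x$stage_name,
              x$n_features_before, x$n_features_after,
              length(x$removed_feature_ids)))
  invisible(x)
}

#' Serialize QA filter logs as JSON lines
#'
#' One JSON record per stage, in pipeline order.
#'
#' @param logs a list of filter logs as returned by [apply_qa_pipeline()].
#' @param path output file.
#' @export
write_qa_log <- function(logs, path) {
  lines <- vapply(logs, function(l) {
    jsonlite::toJSON(unclass(l), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @describeIn qa_filters Keep features present in at least
#'   `min_qc_fraction` of the QC injections (inclusive threshold).
#' @param t a [feature_table()].
#' @param min_qc_fraction minimum fraction of QC injections in which a
#'   feature must be detected (default 0.5).
#' @return A list with elements `table` and `log`.
#' @export
qc_presence_filter <- function(t, min_qc_fraction = 0.5) {
  stopifnot(min_qc_fraction > 0, min_qc_fraction <= 1)
  qi <- qc_idx(t)
  if (length(qi) == 0L)
    stop("no QC samples in table: skip the QC-based filters explicitly ",
         "rather than calling qc_presence_filter")
  pres <- colMeans(!is.na(t$intensities[qi, , drop = FALSE]))
  keep <- pres >= min_qc_fraction
  out <- subset_features(t, which(keep))
  list(table = out,
       log = qa_log("qc_presence", t$feature_meta$feature_id,
                    out$feature_meta$feature_id))
}

#' @describeIn qa_filters Keep features whose coefficient of variation
#'   (sd/mean, n-1 denominator, raw intensity scale) across non-missing QC
#'   injections is strictly below `max_cv`.  Features with fewer than two
#'   non-missing QC values have an undefined CV and are removed.
#' @param max_cv upper bound on the QC coefficient of variation, strict
#'   (default 0.20).
#' @export
qc_cv_filter <- function(t, max_cv = 0.20) {
  stopifnot(max_cv > 0)
  qi <- qc_idx(t)
  if (length(qi) < 2L)
    stop("qc_cv_filter needs at least 2 QC samples")
  Q <- t$intensities[qi, , drop = FALSE]
  cv <- apply(Q, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    stats::sd(v) / mean(v)
  })
  keep <- !is.na(cv) & cv < max_cv
  out <- subset_features(t, which(keep))
  list(table = out,
       log = qa_log("qc_cv", t$feature_meta$feature_id,
                    out$feature_meta$feature_id))
}

#' @describeIn qa_filters Keep features detected in at least
#'   `min_group_fraction` of the samples of at least one study group
#'   (inclusive threshold); QC injections do not enter the computation.
#' @param min_group_fraction minimum detected fraction within a group
#'   (default 0.8).
#' @export
group_presence_filter <- function(t, min_group_fraction = 0.8) {
  stopifnot(min_group_fraction > 0, min_group_fraction <= 1)
  si <- study_idx(t)
  g <- t$sample_meta$group[si]
  lev <- group_levels(t)
  X <- t$intensities[si, , drop = FALSE]
  frac_a <- colMeans(!is.na(X[g == lev[1L], , drop = FALSE]))
  frac_b <- colMeans(!is.na(X[g == lev[2L], , drop = FALSE]))
  keep <- frac_a >= min_group_fraction | frac_b >= min_group_fraction
  out <- subset_features(t, which(keep))
  list(table = out,
       log = qa_log("group_presence", t$feature_meta$feature_id,
                    out$feature_meta$feature_id))
}

#' Run the full QA filtration cascade
#'
#' Applies [qc_presence_filter()], [qc_cv_filter()] and
#' [group_presence_filter()] in that order and concatenates their logs.
#'
#' @param t a [feature_table()].
#' @param min_qc_fraction,max_cv,min_group_fraction stage thresholds.
#' @return A list with the filtered `table` and `logs` (list of 3).
#' @export
apply_qa_pipeline <- function(t, min_qc_fraction = 0.5, max_cv = 0.20,
                              min_group_fraction = 0.8) {
  s1 <- qc_presence_filter(t, min_qc_fraction)
  s2 <- qc_cv_filter(s1$table, max_cv)
  s3 <- group_presence_filter(s2$table, min_group_fraction)
  list(table = s3$table, logs = list(s1$log, s2$log, s3$log))
}
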