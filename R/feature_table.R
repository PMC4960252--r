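#' Construct a metabolomics feature table
#'
#' The central container of the package: a samples-by-features intensity
#' matrix with per-feature metadata (id, neutral monoisotopic mass,
#' retention time) and per-sample metadata (id, study group, QC flag).
#' Pooled-QC injections are ordinary rows of the matrix flagged with
#' `is_qc = TRUE`; their `group` is `NA`.
#'
#' @param intensities numeric matrix, samples in rows, features in columns.
#'   `NA` encodes a non-detected (missing) measurement; all non-missing
#'   values must be >= 0.
#' @param feature_meta data.frame with columns `feature_id` (unique,
#'   character), `neutral_mass` (Da) and `rt` (minutes).
#' @param sample_meta data.frame with columns `sample_id` (unique,
#'   character), `group` (exactly two distinct non-QC levels) and `is_qc`
#'   (logical).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, feature_meta, sample_meta) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  feature_meta <- as.data.frame(feature_meta, stringsAsFactors = FALSE)
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)

  req_f <- c("feature_id", "neutral_mass", "rt")
  if (!all(req_f %in% names(feature_meta)))
    stop("feature_meta must have columns: ", paste(req_f, collapse = ", "))
  req_s <- c("sample_id", "group", "is_qc")
  if (!all(req_s %in% names(sample_meta)))
    stop("sample_meta must have columns: ", paste(req_s, collapse = ", "))

  feature_meta$feature_id <- as.character(feature_meta$feature_id)
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  sample_meta$is_qc <- as.logical(sample_meta$is_qc)
  sample_meta$group <- as.character(sample_meta$group)
  sample_meta$group[sample_meta$is_qc] <- NA_character_

  if (nrow(intensities) != nrow(sample_meta))
    stop("intensity matrix has ", nrow(intensities), " rows but sample_meta has ",
         nrow(sample_meta), " records")
  if (ncol(intensities) != nrow(feature_meta))
    stop("intensity matrix has ", ncol(intensities), " columns but feature_meta has ",
         nrow(feature_meta), " records")
  if (anyDuplicated(feature_meta$feature_id))
    stop("duplicated feature_id: ",
         paste(unique(feature_meta$feature_id[duplicated(feature_meta$feature_id)]),
               collapse = ", "))
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(sample_meta$sample_id[duplicated(sample_meta$sample_id)]),
               collapse = ", "))
  if (any(intensities < 0, na.rm = TRUE))
    stop("negative intensities are not allowed")
  grps <- unique(sample_meta$group[!sample_meta$is_qc])
  grps <- grps[!is.na(grps)]
  if (length(grps) != 2L)
    stop("exactly 2 study groups required, found ", length(grps),
         if (length(grps)) paste0(": ", paste(grps, collapse = ", ")) else "")

  rownames(intensities) <- sample_meta$sample_id
  colnames(intensities) <- feature_meta$feature_id
  structure(
    list(intensities = intensities,
         feature_meta = feature_meta,
         sample_meta = sample_meta),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  sm <- x$sample_meta
  grps <- table(sm$group[!sm$is_qc])
  cat("feature_table: ", nrow(x$intensities), " samples x ",
      ncol(x$intensities), " features\n", sep = "")
  cat("  study samples: ", paste(names(grps), grps, sep = "=", collapse = ", "),
      "; QC injections: ", sum(sm$is_qc), "\n", sep = "")
  cat("  missing cells: ", sum(is.na(x$intensities)), " (",
      round(100 * mean(is.na(x$intensities)), 1), "%)\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

# study (non-QC) sample index
study_idx <- function(t) which(!t$sample_meta$is_qc)
qc_idx <- function(t) which(t$sample_meta$is_qc)

# the two study group labels in lexicographic order
group_levels <- function(t) {
  sort(unique(stats::na.omit(t$sample_meta$group[!t$sample_meta$is_qc])))
}

# subset helper keeping metadata in sync
subset_features <- function(t, keep) {
  if (is.character(keep)) keep <- match(keep, t$feature_meta$feature_id)
  t$intensities <- t$intensities[, keep, drop = FALSE]
  t$feature_meta <- t$feature_meta[keep, , drop = FALSE]
  rownames(t$feature_meta) <- NULL
  t
}

subset_samples <- function(t, keep) {
  if (is.character(keep)) keep <- match(keep, t$sample_meta$sample_id)
  t$intensities <- t$intensities[keep, , drop = FALSE]
  t$sample_meta <- t$sample_meta[keep, , drop = FALSE]
  rownames(t$sample_meta) <- NULL
  t
}

#' Read a feature table from delimited text
#'
#' Reads the intensity table and the sample metadata from two delimited
#' files (the field separator is sniffed from the extension: `.tsv`/`.txt`
#' is tab, anything else comma).  The vendor-export orientation
#' (`features_in_rows`) carries `feature_id`, `neutral_mass`, `rt` columns
#' followed by one column per sample; the modeling orientation
#' (`samples_in_rows`) carries a `sample_id` column followed by one column
#' per feature, with feature mass/RT supplied via `feature_meta_path` (or
#' left `NA`).
#'
#' Empty cells and `"NA"` parse as missing; with `zero_as_missing = TRUE`
#' (default, matching vendor exports that write 0 for non-detects) zeros
#' are converted to missing as well.
#'
#' @param intensity_path path to the intensity table.
#' @param sample_meta_path path to the sample metadata table with columns
#'   `sample_id`, `group`, `is_qc`.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @param feature_meta_path optional path to feature metadata
#'   (`feature_id`, `neutral_mass`, `rt`) for the `samples_in_rows` layout.
#' @param zero_as_missing treat 0 as a non-detect sentinel.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(intensity_path, sample_meta_path,
                               orientation = c("features_in_rows",
                                               "samples_in_rows"),
                               feature_meta_path = NULL,
                               zero_as_missing = TRUE) {
  orientation <- match.arg(orientation)
  sep_of <- function(p) if (grepl("\\.(tsv|txt)$", p, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(intensity_path, header = TRUE, sep = sep_of(intensity_path),
                           na.strings = c("", "NA"), check.names = FALSE,
                           stringsAsFactors = FALSE)
  sm <- utils::read.table(sample_meta_path, header = TRUE, sep = sep_of(sample_meta_path),
                          na.strings = c("", "NA"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group", "is_qc") %in% names(sm)))
    stop("sample metadata must have columns sample_id, group, is_qc")
  sm$sample_id <- as.character(sm$sample_id)
  sm$is_qc <- as.logical(sm$is_qc)

  if (orientation == "features_in_rows") {
    req <- c("feature_id", "neutral_mass", "rt")
    if (!all(req %in% names(raw)))
      stop("intensity file must have columns feature_id, neutral_mass, rt")
    fm <- raw[, req]
    ids_in_matrix <- setdiff(names(raw), req)
    X <- t(as.matrix(raw[, ids_in_matrix, drop = FALSE]))
    colnames(X) <- fm$feature_id
  } else {
    if (!"sample_id" %in% names(raw))
      stop("intensity file must have a sample_id column")
    ids_in_matrix <- as.character(raw$sample_id)
    X <- as.matrix(raw[, setdiff(names(raw), "sample_id"), drop = FALSE])
    rownames(X) <- ids_in_matrix
    if (!is.null(feature_meta_path)) {
      fm <- utils::read.table(feature_meta_path, header = TRUE,
                              sep = sep_of(feature_meta_path),
                              na.strings = c("", "NA"), check.names = FALSE,
                              stringsAsFactors = FALSE)
    } else {
      fm <- data.frame(feature_id = colnames(X),
                       neutral_mass = NA_real_, rt = NA_real_,
                       stringsAsFactors = FALSE)
    }
  }
  storage.mode(X) <- "double"

  missing_in_matrix <- setdiff(sm$sample_id, ids_in_matrix)
  extra_in_matrix <- setdiff(ids_in_matrix, sm$sample_id)
  if (length(missing_in_matrix) || length(extra_in_matrix))
    stop("sample id mismatch between intensity table and sample metadata;",
         if (length(missing_in_matrix))
           paste0(" absent from matrix: ", paste(missing_in_matrix, collapse = ", "), ";"),
         if (length(extra_in_matrix))
           paste0(" absent from metadata: ", paste(extra_in_matrix, collapse = ", ")))
  X <- X[match(sm$sample_id, ids_in_matrix), , drop = FALSE]
  if (zero_as_missing) X[!is.na(X) & X == 0] <- NA_real_
  feature_table(X, fm, sm)
}

#' Write a feature table to delimited text
#'
#' Inverse of [read_feature_table()]: full double precision is kept so a
#' read -> write -> read round trip reproduces finite intensities exactly
#' and preserves the missingness mask (missing cells are written as `NA`).
#'
#' @param t a [feature_table()].
#' @param intensity_path,sample_meta_path output paths (extension picks the
#'   separator as in [read_feature_table()]).
#' @param orientation layout to write, see [read_feature_table()].
#' @return Invisibly, the paths written.
#' @export
write_feature_table <- function(t, intensity_path, sample_meta_path,
                                orientation = c("features_in_rows",
                                                "samples_in_rows")) {
  orientation <- match.arg(orientation)
  sep_of <- function(p) if (grepl("\\.(tsv|txt)$", p, ignore.case = TRUE)) "\t" else ","
  fmt <- function(M) {
    out <- format(M, digits = 17, trim = TRUE, scientific = TRUE)
    out[is.na(M)] <- "NA"
    out
  }
  if (orientation == "features_in_rows") {
    df <- cbind(t$feature_meta[, c("feature_id", "neutral_mass", "rt")],
                as.data.frame(fmt(t(t$intensities)), stringsAsFactors = FALSE))
    names(df) <- c("feature_id", "neutral_mass", "rt", t$sample_meta$sample_id)
  } else {
    df <- cbind(data.frame(sample_id = t$sample_meta$sample_id,
                           stringsAsFactors = FALSE),
                as.data.frame(fmt(t$intensities), stringsAsFactors = FALSE))
  }
  utils::write.table(df, intensity_path, sep = sep_of(intensity_path),
                     row.names = FALSE, quote = FALSE, na = "NA")
  utils::write.table(t$sample_meta, sample_meta_path,
                     sep = sep_of(sample_meta_path),
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(c(intensity_path, sample_meta_path))
}

#' Impute left-censored missing values at half the feature minimum
#'
#' Replaces missing cells by half the smallest observed intensity of that
#' feature — the usual limit-of-detection convention for LC-MS non-detects.
#' The imputation is flagged (attribute `"imputed"` holds the logical mask)
#' and reversible via [unimpute_lod()].
#'
#' @param t a [feature_table()].
#' @return The table with no missing cells and an `"imputed"` mask attribute.
#' @export
impute_lod <- function(t) {
  X <- t$intensities
  mask <- is.na(X)
  if (any(colSums(!mask) == 0L))
    stop("cannot impute features with no observed values: ",
         paste(colnames(X)[colSums(!mask) == 0L], collapse = ", "))
  for (j in which(colSums(mask) > 0L)) {
    X[mask[, j], j] <- min(X[, j], na.rm = TRUE) / 2
  }
  t$intensities <- X
  attr(t, "imputed") <- mask
  t
}

#' Undo limit-of-detection imputation
#'
#' @param t a table previously passed through [impute_lod()].
#' @return The table with imputed cells restored to missing.
#' @export
unimpute_lod <- function(t) {
  mask <- attr(t, "imputed")
  if (is.null(mask)) return(t)
  t$intensities[mask] <- NA_real_
  attr(t, "imputed") <- NULL
  t
}
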