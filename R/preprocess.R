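#' Fit a column scaler (unit-variance or Pareto)
#'
#' Dispersion-based data pretreatment for multivariate modeling.  Both
#' methods centre each feature at its mean and divide by a per-feature
#' scaling factor: the standard deviation for unit-variance (UV,
#' autoscaling) or the square root of the standard deviation for Pareto.
#' UV gives every feature unit variance so the analysis runs on
#' correlations; Pareto compresses high-variance features less, keeping
#' large fold changes partially dominant.  Standard deviations use the
#' n-1 denominator.
#'
#' @param X numeric matrix (samples x features), no missing values.
#' @param method `"uv"`, `"pareto"` or `"none"`.
#' @param center subtract column means (default `TRUE`).
#' @return A `scaling_spec` with the fitted means and factors.
#' @export
fit_scaler <- function(X, method = c("uv", "pareto", "none"), center = TRUE) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (anyNA(X)) stop("fit_scaler requires a complete matrix (impute first)")
  if (nrow(X) < 2L) stop("fit_scaler needs at least 2 samples")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  if (method != "none" && any(sdv == 0)) {
    bad <- colnames(X)[sdv == 0]
    if (is.null(bad)) bad <- which(sdv == 0)
    stop("zero-variance features cannot be scaled: ",
         paste(bad, collapse = ", "))
  }
  fac <- switch(method,
                uv = sdv,
                pareto = sqrt(sdv),
                none = rep(1, ncol(X)))
  structure(
    list(method = method, center = center,
         per_feature_means = if (center) mu else rep(0, ncol(X)),
         per_feature_factors = fac,
         feature_ids = colnames(X)),
    class = "scaling_spec")
}

#' Apply (or invert) a fitted scaler
#'
#' Columnwise `(X - means) / factors`.  `invert_scaler()` is the exact
#' inverse, so `invert_scaler(apply_scaler(X, s), s)` reproduces `X`.
#'
#' @param X matrix with the same columns the spec was fitted on.
#' @param s a `scaling_spec` from [fit_scaler()].
#' @return The transformed matrix.
#' @export
apply_scaler <- function(X, s) {
  X <- as.matrix(X)
  if (ncol(X) != length(s$per_feature_factors))
    stop("matrix has ", ncol(X), " columns; scaler was fitted on ",
         length(s$per_feature_factors))
  sweep(sweep(X, 2L, s$per_feature_means, "-"), 2L, s$per_feature_factors, "/")
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(X, s) {
  X <- as.matrix(X)
  if (ncol(X) != length(s$per_feature_factors))
    stop("matrix has ", ncol(X), " columns; scaler was fitted on ",
         length(s$per_feature_factors))
  sweep(sweep(X, 2L, s$per_feature_factors, "*"), 2L, s$per_feature_means, "+")
}

#' Serialize / restore a scaling specification
#'
#' @param s a `scaling_spec`.
#' @param path JSON file path.
#' @export
write_scaling_spec <- function(s, path) {
  jsonlite::write_json(unclass(s), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaling_spec
#' @export
read_scaling_spec <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  s$per_feature_means <- as.numeric(s$per_feature_means)
  s$per_feature_factors <- as.numeric(s$per_feature_factors)
  structure(s, class = "scaling_spec")
}

# Fit the scaler on study samples only (QCs would shrink the dispersion
# estimates since they replicate one pooled sample), return the scaled
# study matrix plus the spec.
scale_study_matrix <- function(t, method) {
  si <- study_idx(t)
  X <- t$intensities[si, , drop = FALSE]
  if (anyNA(X)) stop("missing values present: run impute_lod() first")
  s <- fit_scaler(X, method = method)
  list(X = apply_scaler(X, s), spec = s,
       y = class_codes(t), sample_ids = t$sample_meta$sample_id[si])
}

# +1/-1 class coding, lexicographic group order: first level -> -1,
# second -> +1 (mapping recorded as names).
class_codes <- function(t) {
  lev <- group_levels(t)
  g <- t$sample_meta$group[study_idx(t)]
  y <- ifelse(g == lev[2L], 1, -1)
  attr(y, "mapping") <- stats::setNames(c(-1, 1), lev)
  y
}

#' Log-transform intensities
#'
#' Elementwise logarithm of the intensity matrix, preserving the
#' missingness mask.  A convenience for variance stabilisation; the
#' modeling workflows operate on whatever scale the table carries.
#'
#' @param t a [feature_table()].
#' @param base logarithm base (default natural).
#' @param offset added before taking logs (default 0).
#' @return The transformed table.
#' @export
log_transform <- function(t, base = exp(1), offset = 0) {
  X <- t$intensities + offset
  if (any(X <= 0, na.rm = TRUE))
    stop("log_transform requires all (intensity + offset) > 0")
  t$intensities <- log(X, base = base)
  t
}
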