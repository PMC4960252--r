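#' Principal component analysis by singular value decomposition
#'
#' PCA on an already centred/scaled matrix, used to screen the data before
#' supervised modeling: pooled-QC injections should cluster tightly and
#' gross outliers show up at the edge of the Hotelling T-squared limit.
#' Component signs follow a fixed convention (the largest-magnitude
#' loading element of each component is positive) so results are
#' reproducible across linear-algebra backends.
#'
#' @param X centred (and usually scaled) numeric matrix, samples x features.
#' @param n_components number of components, at most `min(n - 1, p)`.
#' @return A `pca_model` with `scores`, `loadings`, `eigenvalues`
#'   (score variances, n-1 denominator) and `explained_variance`
#'   (proportions of total variance).
#' @export
fit_pca <- function(X, n_components) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n_components > min(n - 1L, p))
    stop("n_components must be <= min(n - 1, p) = ", min(n - 1L, p))
  sv <- svd(X)
  total_var <- sum(sv$d^2)
  keep <- seq_len(n_components)
  loadings <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-|loading| element positive
  for (a in keep) {
    piv <- which.max(abs(loadings[, a]))
    if (loadings[piv, a] < 0) {
      loadings[, a] <- -loadings[, a]
      sv$u[, a] <- -sv$u[, a]
    }
  }
  scores <- X %*% loadings
  structure(
    list(n_components = n_components,
         scores = scores,
         loadings = loadings,
         eigenvalues = sv$d[keep]^2 / (n - 1L),
         explained_variance = sv$d[keep]^2 / total_var,
         n_samples = n),
    class = "pca_model")
}

#' Flag outliers by Hotelling's T-squared in PCA score space
#'
#' For each sample, T2 = sum over components of t_a^2 / lambda_a, with
#' lambda_a the score variance of component a.  The limit is the usual
#' F-based control bound `A (n-1)(n+1) / (n (n-A)) * F_(A, n-A)(confidence)`;
#' samples exceeding it are flagged.
#'
#' @param m a `pca_model` with at least 2 components.
#' @param confidence limit confidence level (default 0.95).
#' @return Logical vector, one flag per sample; attribute `"t2"` carries
#'   the statistics, `"limit"` the bound.
#' @export
hotelling_outliers <- function(m, confidence = 0.95) {
  A <- m$n_components
  n <- m$n_samples
  if (A < 2L) stop("hotelling_outliers needs at least 2 components")
  if (n <= A) stop("need more samples than components")
  t2 <- rowSums(sweep(m$scores^2, 2L, m$eigenvalues, "/"))
  limit <- A * (n - 1) * (n + 1) / (n * (n - A)) *
    stats::qf(confidence, A, n - A)
  flags <- t2 > limit
  attr(flags, "t2") <- t2
  attr(flags, "limit") <- limit
  flags
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures for a binary class code
#' y in \{+1, -1\}: an orthogonal-signal-correction (OSC) filter strips the
#' variation in X that is uncorrelated with y, then a single predictive
#' component is fitted on the filtered matrix.  The recursion:
#' the predictive weight `w` is X'y normalised to unit length; for each of
#' the `n_orth` orthogonal components, `t = X w`, `p = X't/(t't)`,
#' `w_orth` is `p` minus its projection on `w` (normalised),
#' `t_orth = X w_orth`, `p_orth = X't_orth/(t_orth't_orth)`, and X is
#' deflated by `t_orth p_orth'`.  Finally `t = X w`, `c = y't/(t't)`,
#' and `R2Y = 1 - ||y - t c||^2 / ||y - mean(y)||^2`.
#'
#' @param X centred/scaled matrix (samples x features), complete.
#' @param y numeric class codes, both of +1 and -1 present.
#' @param n_orth number of orthogonal components to remove (default 1).
#' @return An `opls_model` holding `w`, `t`, `p_load`, `c`, the orthogonal
#'   `w_orth`/`t_orth`/`p_orth` matrices, `vip`, `r2y` and bookkeeping.
#' @export
fit_opls_da <- function(X, y, n_orth = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("fit_opls_da requires complete data")
  if (length(unique(sign(y))) < 2L) stop("both classes must be present")
  n <- nrow(X)
  p <- ncol(X)
  feature_ids <- colnames(X)
  if (is.null(feature_ids)) feature_ids <- paste0("V", seq_len(p))

  w <- drop(crossprod(X, y))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("no predictive variation: y is orthogonal to every column of X")
  w <- w / nw

  W_o <- matrix(0, p, 0)
  T_o <- matrix(0, n, 0)
  P_o <- matrix(0, p, 0)
  Xd <- X
  k <- 0L
  while (k < n_orth) {
    t_pred <- drop(Xd %*% w)
    p_load <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
    w_o <- p_load - sum(w * p_load) * w
    nw_o <- sqrt(sum(w_o^2))
    if (nw_o < 1e-12) break  # no orthogonal variation left
    w_o <- w_o / nw_o
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    T_o <- cbind(T_o, t_o)
    P_o <- cbind(P_o, p_o)
    k <- k + 1L
  }

  t_pred <- drop(Xd %*% w)
  p_load <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
  cc <- sum(y * t_pred) / sum(t_pred^2)
  ss_res <- sum((y - t_pred * cc)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2y <- 1 - ss_res / ss_tot

  m <- structure(
    list(w = w, t = t_pred, p_load = p_load, c = cc,
         w_orth = W_o, t_orth = T_o, p_orth = P_o, n_orth = k,
         r2y = r2y, q2 = NA_real_, feature_ids = feature_ids,
         n_samples = n, n_features = p),
    class = "opls_model")
  m$vip <- vip(m)
  m
}

#' @export
print.opls_model <- function(x, ...) {
  cat("OPLS-DA model: 1 predictive + ", x$n_orth, " orthogonal component(s), ",
      x$n_features, " features, ", x$n_samples, " samples\n", sep = "")
  cat(sprintf("  R2Y = %.4f", x$r2y))
  if (!is.na(x$q2)) cat(sprintf(", Q2 = %.4f", x$q2))
  cat("\n")
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' VIP over the predictive component(s):
#' `VIP_j = sqrt( p * sum_a SSY_a (w_aj/||w_a||)^2 / sum_a SSY_a )`.
#' With the single post-OSC predictive component used here this reduces to
#' `sqrt(p) * |w_j|` (w has unit norm), and mean(VIP^2) = 1 identically —
#' which is why VIP > 1 ("above-average influence") is the conventional
#' selection rule.
#'
#' @param m a fitted `opls_model`.
#' @return Numeric VIP vector named by feature id.
#' @export
vip <- function(m) {
  stats::setNames(sqrt(m$n_features) * abs(m$w), m$feature_ids)
}

#' Select features with VIP above a threshold
#'
#' @param m a fitted `opls_model`.
#' @param threshold strict lower VIP bound (default 1).
#' @return Character vector of selected feature ids.
#' @export
select_by_vip <- function(m, threshold = 1.0) {
  m$feature_ids[m$vip > threshold]
}

# Project new (already scaled) samples through a fitted model:
# deflate by the training orthogonal components, then score.
predict_opls <- function(m, X_new) {
  X_new <- as.matrix(X_new)
  if (m$n_orth > 0L) {
    for (k in seq_len(m$n_orth)) {
      t_o <- drop(X_new %*% m$w_orth[, k])
      X_new <- X_new - tcrossprod(t_o, m$p_orth[, k])
    }
  }
  drop(X_new %*% m$w) * m$c
}

# Stratified k-fold assignment (per class, seeded by the caller's RNG state)
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated predictive performance (Q2)
#'
#' Stratified k-fold cross-validation of the full scale-then-OPLS pipeline:
#' in each fold the scaler and the OPLS-DA model are refitted on the
#' training samples only (no leakage), held-out samples are projected
#' through the training orthogonal components and scored, and
#' `Q2 = 1 - PRESS / SS` with `SS = sum((y - mean(y_train))^2)` accumulated
#' over folds.
#'
#' @param t a QA-filtered, imputed [feature_table()].
#' @param scaling `"uv"`, `"pareto"` or `"none"`.
#' @param n_orth orthogonal components (default 1).
#' @param k folds (default 7).
#' @param seed integer seed for the fold assignment.
#' @param refit_scaler_per_fold refit scaling inside each training fold
#'   (default `TRUE`); `FALSE` scales once on the full data first,
#'   mimicking software that cross-validates on a pre-scaled matrix.
#' @return Q2 (scalar); attribute `"press"` and `"ss"` carry the parts.
#' @export
q2_cv <- function(t, scaling = "uv", n_orth = 1L, k = 7L, seed = 1L,
                  refit_scaler_per_fold = TRUE) {
  si <- study_idx(t)
  X_raw <- t$intensities[si, , drop = FALSE]
  if (anyNA(X_raw)) stop("missing values present: run impute_lod() first")
  y <- as.numeric(class_codes(t))
  if (min(table(y)) < k) stop("k exceeds the size of the smaller class")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- stratified_folds(y, k)
  if (any(vapply(seq_len(k), function(f) length(unique(y[fold != f])) < 2L,
                 logical(1)))) {
    fold <- stratified_folds(y, k)
    if (any(vapply(seq_len(k), function(f) length(unique(y[fold != f])) < 2L,
                   logical(1))))
      stop("could not build folds with both classes in every training set")
  }
  whole_spec <- if (!refit_scaler_per_fold) fit_scaler(X_raw, method = scaling)
  press <- 0
  ss <- 0
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    if (refit_scaler_per_fold) {
      sp <- fit_scaler(X_raw[tr, , drop = FALSE], method = scaling)
    } else {
      sp <- whole_spec
    }
    X_tr <- apply_scaler(X_raw[tr, , drop = FALSE], sp)
    X_te <- apply_scaler(X_raw[te, , drop = FALSE], sp)
    m <- fit_opls_da(X_tr, y[tr], n_orth = n_orth)
    y_hat <- predict_opls(m, X_te)
    press <- press + sum((y[te] - y_hat)^2)
    ss <- ss + sum((y[te] - mean(y[tr]))^2)
  }
  q2 <- 1 - press / ss
  attr(q2, "press") <- press
  attr(q2, "ss") <- ss
  q2
}

#' Score plot for an OPLS-DA model
#'
#' Predictive score against the first orthogonal score (or sample index
#' when no orthogonal component exists), coloured by class.
#'
#' @param x a fitted `opls_model`.
#' @param y ignored.
#' @param groups optional factor of class labels for the legend.
#' @param ... passed to [graphics::plot()].
#' @export
plot.opls_model <- function(x, y = NULL, groups = NULL, ...) {
  t2 <- if (x$n_orth > 0L) x$t_orth[, 1L] else seq_along(x$t)
  col <- if (is.null(groups)) 1L else as.integer(factor(groups)) + 1L
  graphics::plot(x$t, t2, col = col, pch = 19,
                 xlab = "t (predictive)",
                 ylab = if (x$n_orth > 0L) "t_orth 1" else "sample index", ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_len(nlevels(factor(groups))) + 1L, pch = 19)
  invisible(x)
}

# RNG-state helpers: seeded internals must not clobber the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
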