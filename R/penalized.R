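#' Build a penalized logistic regression problem
#'
#' Extracts the study samples of a QA-filtered, imputed table, standardizes
#' every feature column to mean 0 / sd 1 (n-1 denominator) and codes the
#' response 0/1 by lexicographic group order (first level -> 0).  The
#' centring/scaling constants are stored so coefficients can be
#' back-transformed to the raw intensity scale.
#'
#' @param t a [feature_table()] with two study groups and no missing values.
#' @return A `lasso_problem` with elements `X` (standardized), `X_raw`,
#'   `y`, `n`, `p`, `feature_ids`, `center`, `scale`, `y_mapping`.
#' @export
make_problem <- function(t) {
  si <- study_idx(t)
  X_raw <- t$intensities[si, , drop = FALSE]
  if (anyNA(X_raw)) stop("missing values present: run impute_lod() first")
  lev <- group_levels(t)
  y <- as.integer(t$sample_meta$group[si] == lev[2L])
  prob <- make_problem_matrix(X_raw, y, t$feature_meta$feature_id)
  prob$y_mapping <- stats::setNames(c(0L, 1L), lev)
  prob
}

# matrix-level constructor shared with the bootstrap loop
make_problem_matrix <- function(X_raw, y, feature_ids) {
  X_raw <- as.matrix(X_raw)
  ctr <- colMeans(X_raw)
  scl <- apply(X_raw, 2L, stats::sd)
  if (any(scl == 0))
    stop("zero-variance features cannot be standardized: ",
         paste(feature_ids[scl == 0], collapse = ", "))
  X <- sweep(sweep(X_raw, 2L, ctr, "-"), 2L, scl, "/")
  colnames(X) <- feature_ids
  structure(
    list(X = X, X_raw = X_raw, y = as.numeric(y),
         n = nrow(X), p = ncol(X), feature_ids = feature_ids,
         center = ctr, scale = scl),
    class = "lasso_problem")
}

#' Smallest penalty that zeroes every coefficient
#'
#' With the intercept profiled out at the null model, the
#' Karush-Kuhn-Tucker condition at beta = 0 gives
#' `lambda_max = max_j | x_j' (y - mean(y)) |`; any `lambda >=` this value
#' yields an empty active set.
#'
#' @param prob a `lasso_problem`.
#' @return The scalar lambda_max.
#' @export
lambda_max <- function(prob) {
  max(abs(drop(crossprod(prob$X, prob$y - mean(prob$y)))))
}

#' Log-spaced penalty grid
#'
#' 100 points (by default) from `lambda_max` down to
#' `grid_ratio * lambda_max`, strictly decreasing — the conventional path
#' layout for warm-started coordinate descent.
#'
#' @param prob a `lasso_problem`.
#' @param n_lambda grid size (default 100).
#' @param grid_ratio ratio of smallest to largest lambda (default 1e-3).
#' @export
lambda_grid <- function(prob, n_lambda = 100L, grid_ratio = 1e-3) {
  lmax <- lambda_max(prob)
  exp(seq(log(lmax), log(grid_ratio * lmax), length.out = n_lambda))
}

#' Fit the penalized logistic model at one penalty value
#'
#' Minimizes `-lnL + lambda * sum_j |beta_j|` (intercept unpenalized) by
#' cyclic coordinate descent on the iteratively reweighted quadratic
#' approximation of the negative log-likelihood, with soft-thresholding
#' updates and a step-halving safeguard that keeps the exact objective
#' non-increasing across outer iterations.
#'
#' @param prob a `lasso_problem`.
#' @param lambda penalty, >= 0.
#' @param init optional warm-start list with `beta` and `intercept`.
#' @param tol convergence tolerance on the maximum coefficient change
#'   (default 1e-8).
#' @param max_iter maximum outer iterations (default 10000).
#' @return A `lasso_fit` with the standardized-scale coefficients `beta`,
#'   raw-scale `beta_raw`/`intercept_raw`, `log_likelihood`, `aic`,
#'   `active_set` (feature ids), `converged` and `n_iter`.
#' @export
fit_lasso_logistic <- function(prob, lambda, init = NULL, tol = 1e-8,
                               max_iter = 10000L) {
  stopifnot(lambda >= 0)
  if (is.null(init)) init <- list(beta = rep(0, prob$p), intercept = 0)
  res <- cd_lasso_logistic_cpp(prob$X, prob$y, lambda,
                               init$beta, init$intercept,
                               tol, as.integer(max_iter))
  if (!res$converged)
    warning("coordinate descent did not converge at lambda = ",
            signif(lambda, 4), " (possible complete separation at small lambda)")
  beta <- drop(res$beta)
  # clamp sub-ulp boundary noise (a coordinate sitting exactly on its KKT
  # knot, e.g. at lambda_max, can pick up an O(1e-15) coefficient)
  beta[abs(beta) < 1e-12] <- 0
  names(beta) <- prob$feature_ids
  active <- prob$feature_ids[beta != 0]
  k <- length(active) + 1L  # + intercept
  ll <- res$log_likelihood
  structure(
    list(lambda = lambda,
         intercept = res$intercept,
         beta = beta,
         beta_raw = beta / prob$scale,
         intercept_raw = res$intercept - sum(beta * prob$center / prob$scale),
         log_likelihood = ll,
         aic = -2 * ll + 2 * k,
         active_set = active,
         objective = res$objective,
         objective_trace = res$objective_trace,
         converged = res$converged,
         n_iter = res$n_iter),
    class = "lasso_fit")
}

#' Akaike information criterion of a penalized fit
#'
#' `AIC = -2 lnL + 2 k` with `k` = number of nonzero coefficients plus one
#' for the intercept (the standard LASSO degrees-of-freedom estimator).
#'
#' @param fit a `lasso_fit`.
#' @export
aic <- function(fit) {
  -2 * fit$log_likelihood + 2 * (length(fit$active_set) + 1L)
}

#' Fit the penalty path and select the tuning parameter
#'
#' Fits the model at every grid point with warm starts in decreasing-lambda
#' order.  Rule `"aic"` (default) picks the full-data minimum-AIC fit; rule
#' `"cv_deviance"` picks the lambda minimizing the mean held-out binomial
#' deviance over stratified k-fold cross-validation with per-fold
#' re-standardization.  Ties are broken toward the larger lambda (the
#' sparser model).
#'
#' @param prob a `lasso_problem`.
#' @param grid decreasing lambda vector (default [lambda_grid()]).
#' @param rule `"aic"` or `"cv_deviance"`.
#' @param k folds for `"cv_deviance"` (default 5).
#' @param seed integer seed for the fold assignment.
#' @param tol,max_iter passed to [fit_lasso_logistic()].
#' @return A `lasso_path` with `lambda_grid`, `fits`, per-lambda `aic`
#'   (and `cv_deviance` if used), `lambda_selected`, `fit_selected`,
#'   `selection_rule`.
#' @export
select_lambda <- function(prob, grid = NULL, rule = c("aic", "cv_deviance"),
                          k = 5L, seed = 1L, tol = 1e-8, max_iter = 10000L) {
  rule <- match.arg(rule)
  if (is.null(grid)) grid <- lambda_grid(prob)
  if (any(diff(grid) >= 0)) stop("lambda grid must be strictly decreasing")

  fit_path <- function(p_obj, g) {
    fits <- vector("list", length(g))
    init <- NULL
    for (i in seq_along(g)) {
      fits[[i]] <- suppressWarnings(
        fit_lasso_logistic(p_obj, g[i], init = init, tol = tol,
                           max_iter = max_iter))
      init <- list(beta = unname(fits[[i]]$beta),
                   intercept = fits[[i]]$intercept)
    }
    fits
  }

  fits <- fit_path(prob, grid)
  aics <- vapply(fits, aic, numeric(1))
  cvdev <- NULL

  if (rule == "aic") {
    sel <- which.min(aics)  # first minimum = largest lambda on ties
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    fold <- stratified_folds(prob$y, k)
    bad <- function(fd) any(vapply(seq_len(k), function(f)
      length(unique(prob$y[fd != f])) < 2L, logical(1)))
    if (bad(fold)) {
      fold <- stratified_folds(prob$y, k)
      if (bad(fold)) stop("could not build folds with both classes in every training set")
    }
    dev <- matrix(NA_real_, k, length(grid))
    for (f in seq_len(k)) {
      tr <- fold != f
      pf <- make_problem_matrix(prob$X_raw[tr, , drop = FALSE], prob$y[tr],
                                prob$feature_ids)
      fits_f <- fit_path(pf, grid)
      X_te <- sweep(sweep(prob$X_raw[!tr, , drop = FALSE], 2L, pf$center, "-"),
                    2L, pf$scale, "/")
      y_te <- prob$y[!tr]
      dev[f, ] <- vapply(fits_f, function(ft) {
        eta <- drop(X_te %*% ft$beta) + ft$intercept
        ll <- sum(y_te * eta - vapply(eta, function(e)
          if (e > 35) e else log1p(exp(e)), numeric(1)))
        -2 * ll
      }, numeric(1))
    }
    cvdev <- colMeans(dev)
    sel <- which.min(cvdev)
  }

  structure(
    list(lambda_grid = grid, fits = fits, aic = aics, cv_deviance = cvdev,
         lambda_selected = grid[sel], selected_index = sel,
         fit_selected = fits[[sel]], selection_rule = rule),
    class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat("LASSO path: ", length(x$lambda_grid), " lambda values, rule = ",
      x$selection_rule, "\n", sep = "")
  cat(sprintf("  selected lambda = %.6g, %d active features, AIC = %.3f\n",
              x$lambda_selected, length(x$fit_selected$active_set),
              x$fit_selected$aic))
  invisible(x)
}

#' Export the penalty path as a per-lambda table
#'
#' @param path a `lasso_path`.
#' @param file output TSV path.
#' @export
write_lasso_path <- function(path, file) {
  df <- data.frame(lambda = path$lambda_grid,
                   df = vapply(path$fits, function(f)
                     length(f$active_set), integer(1)),
                   log_likelihood = vapply(path$fits, function(f)
                     f$log_likelihood, numeric(1)),
                   aic = path$aic)
  if (!is.null(path$cv_deviance)) df$cv_deviance <- path$cv_deviance
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Bootstrap stability of the penalized selection
#'
#' Repeats the whole model-development procedure on bootstrap resamples:
#' samples are drawn with replacement stratified by study group, the
#' problem is rebuilt (re-standardized) on each resample, the penalty is
#' re-selected, and the active set recorded.  A feature that is constant
#' within a resample is excluded from that resample's model and counted as
#' not selected.  Reproducibility is the percentage of resamples in which
#' a feature entered the model.
#'
#' @param t a QA-filtered, imputed [feature_table()].
#' @param n_boot number of resamples (default 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param rule,k,grid_size,grid_ratio,tol,max_iter passed to the per-resample
#'   [select_lambda()] / [lambda_grid()].
#' @return A `stability_result` with per-feature `inclusion_count` and
#'   `reproducibility` (percent), plus the per-resample active sets.
#' @export
bootstrap_stability <- function(t, n_boot = 1000L, seed = 1L,
                                rule = c("aic", "cv_deviance"), k = 5L,
                                grid_size = 100L, grid_ratio = 1e-3,
                                tol = 1e-8, max_iter = 10000L) {
  rule <- match.arg(rule)
  si <- study_idx(t)
  X_raw <- t$intensities[si, , drop = FALSE]
  if (anyNA(X_raw)) stop("missing values present: run impute_lod() first")
  lev <- group_levels(t)
  g <- t$sample_meta$group[si]
  y <- as.integer(g == lev[2L])
  ids <- t$feature_meta$feature_id
  idx_a <- which(g == lev[1L])
  idx_b <- which(g == lev[2L])

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  count <- stats::setNames(integer(length(ids)), ids)
  active_sets <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    take <- c(sample(idx_a, length(idx_a), replace = TRUE),
              sample(idx_b, length(idx_b), replace = TRUE))
    Xb <- X_raw[take, , drop = FALSE]
    yb <- y[take]
    ok <- apply(Xb, 2L, stats::sd) > 0
    pb <- make_problem_matrix(Xb[, ok, drop = FALSE], yb, ids[ok])
    pathb <- select_lambda(pb, grid = lambda_grid(pb, grid_size, grid_ratio),
                           rule = rule, k = k, seed = seed + b,
                           tol = tol, max_iter = max_iter)
    act <- pathb$fit_selected$active_set
    count[act] <- count[act] + 1L
    active_sets[[b]] <- act
  }
  structure(
    list(n_boot = n_boot,
         inclusion_count = count,
         reproducibility = 100 * count / n_boot,
         active_sets = active_sets,
         seed = seed, rule = rule),
    class = "stability_result")
}

#' Report the selected features with their bootstrap reproducibility
#'
#' The reported set is the active set of the full-data selected fit; each
#' member is annotated with its bootstrap reproducibility.  Members below
#' `min_reproducibility` are flagged, not removed — the reproducibility is
#' reported alongside the selection, it does not filter it.
#'
#' @param s a `stability_result`.
#' @param base_path the full-data `lasso_path`.
#' @param min_reproducibility flagging threshold in percent (default 90).
#' @return data.frame with `feature_id`, `inclusion_count`,
#'   `reproducibility`, `flagged`.
#' @export
select_by_stability <- function(s, base_path, min_reproducibility = 90) {
  act <- base_path$fit_selected$active_set
  data.frame(feature_id = act,
             inclusion_count = unname(s$inclusion_count[act]),
             reproducibility = unname(s$reproducibility[act]),
             flagged = unname(s$reproducibility[act]) < min_reproducibility,
             stringsAsFactors = FALSE)
}

#' Export stability results as TSV
#'
#' @param s a `stability_result`.
#' @param file output path.
#' @export
write_stability <- function(s, file) {
  df <- data.frame(feature_id = names(s$inclusion_count),
                   inclusion_count = unname(s$inclusion_count),
                   reproducibility_pct = unname(s$reproducibility),
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
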