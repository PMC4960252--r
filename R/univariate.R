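#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classic FDR step-up adjustment: sort the m raw p-values ascending,
#' set q_(i) = min over j >= i of p_(j) * m / j, cap at 1, and return the
#' values in the original input order.  The rejection set `{q < alpha}`
#' coincides with the classical "largest k with p_(k) <= k*alpha/m"
#' step-up rule at every threshold.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  q_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  # guard the q >= p identity against one-ulp rounding in p * m / j
  pmax(q, p)
}

# Brown-Forsythe (median-centred) Levene test for two groups: a plain
# pooled-variance t-test on absolute deviations from the group medians.
levene_bf <- function(x_a, x_b) {
  z_a <- abs(x_a - stats::median(x_a))
  z_b <- abs(x_b - stats::median(x_b))
  if (stats::sd(z_a) == 0 && stats::sd(z_b) == 0) return(1)
  stats::t.test(z_a, z_b, var.equal = TRUE)$p.value
}

shapiro_p <- function(x) {
  # constant (or effectively constant) vectors cannot be tested for
  # normality; route them to the distribution-free branch
  if (length(unique(x)) < 3L || stats::sd(x) == 0) return(0)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
}

#' Choose the two-group test for one feature
#'
#' The gatekeeper logic used before each per-feature comparison: if the
#' Shapiro-Wilk test accepts normality in both groups (p > alpha), the
#' homogeneity of variances is checked with the median-centred
#' (Brown-Forsythe) Levene test, choosing the pooled-variance Student t
#' when it passes and Welch's t otherwise; if either group fails the
#' normality check, the Mann-Whitney U test is used.  Groups too small for
#' the Shapiro-Wilk test (< 3 values) fall back to Mann-Whitney with a
#' warning.
#'
#' @param x_a,x_b non-missing intensity vectors for the two groups.
#' @param alpha significance level for the normality/variance gates
#'   (default 0.05).
#' @return One of `"student_t"`, `"welch_t"`, `"mann_whitney"`.
#' @export
choose_test <- function(x_a, x_b, alpha = 0.05) {
  if (length(x_a) < 3L || length(x_b) < 3L) {
    warning("group too small for the Shapiro-Wilk test; using Mann-Whitney")
    return("mann_whitney")
  }
  if (shapiro_p(x_a) > alpha && shapiro_p(x_b) > alpha) {
    if (levene_bf(x_a, x_b) > alpha) "student_t" else "welch_t"
  } else {
    "mann_whitney"
  }
}

#' Per-feature two-group testing with FDR correction
#'
#' Runs the [choose_test()] logic on every feature of a QA-filtered,
#' imputed table (raw intensity scale: the three tests are invariant under
#' the per-feature linear maps that UV/Pareto scaling apply, so the order
#' relative to scaling is immaterial), collects two-sided p-values, and
#' adjusts them across all features with [bh_adjust()].  The Mann-Whitney
#' p-value is exact for small samples without ties and uses the
#' tie-corrected normal approximation otherwise.
#'
#' @param t a [feature_table()] with two study groups and no missing values.
#' @param alpha significance level used both for the test-choice gates and
#'   for the FDR significance call `q < alpha` (default 0.05).
#' @return A `univariate_result`: data.frame with columns `feature_id`,
#'   `normal_a`, `normal_b`, `equal_var`, `test_used`, `p_value`,
#'   `q_value`, `significant`.
#' @export
run_univariate <- function(t, alpha = 0.05) {
  si <- study_idx(t)
  X <- t$intensities[si, , drop = FALSE]
  if (anyNA(X)) stop("missing values present: run impute_lod() first")
  lev <- group_levels(t)
  g <- t$sample_meta$group[si]
  ia <- g == lev[1L]
  ib <- g == lev[2L]
  p <- ncol(X)
  res <- data.frame(feature_id = t$feature_meta$feature_id,
                    normal_a = NA, normal_b = NA, equal_var = NA,
                    test_used = NA_character_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    x_a <- X[ia, j]
    x_b <- X[ib, j]
    if (stats::sd(c(x_a, x_b)) == 0) {
      warning("feature ", res$feature_id[j],
              " is constant across both groups; p set to 1")
      res$test_used[j] <- "student_t"
      res$p_value[j] <- 1
      next
    }
    na_ok <- shapiro_p(x_a) > alpha
    nb_ok <- shapiro_p(x_b) > alpha
    res$normal_a[j] <- na_ok
    res$normal_b[j] <- nb_ok
    if (na_ok && nb_ok) {
      ev <- levene_bf(x_a, x_b) > alpha
      res$equal_var[j] <- ev
      res$test_used[j] <- if (ev) "student_t" else "welch_t"
      res$p_value[j] <- stats::t.test(x_a, x_b, var.equal = ev)$p.value
    } else {
      res$test_used[j] <- "mann_whitney"
      res$p_value[j] <- suppressWarnings(
        stats::wilcox.test(x_a, x_b, exact = NULL)$p.value)
    }
  }
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < alpha
  class(res) <- c("univariate_result", "data.frame")
  res
}

#' Select FDR-significant features
#'
#' @param r a `univariate_result` from [run_univariate()].
#' @param q_threshold significance threshold on the adjusted q-value,
#'   strict `<` (default 0.05).
#' @return Character vector of significant feature ids.
#' @export
fdr_select <- function(r, q_threshold = 0.05) {
  r$feature_id[r$q_value < q_threshold]
}

#' Export univariate results as TSV
#'
#' @param r a `univariate_result`.
#' @param path output file.
#' @export
write_univariate <- function(r, path) {
  out <- r[, c("feature_id", "test_used", "p_value", "q_value", "significant")]
  names(out) <- c("feature_id", "test_used", "p", "q", "significant")
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
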