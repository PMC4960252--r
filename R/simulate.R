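#' Design of a synthetic untargeted LC-MS study
#'
#' Parameters of the generator in [simulate_study()].  Defaults describe a
#' balanced two-class plasma-fingerprinting study of realistic desk scale:
#' 50 + 50 study samples, 8 pooled-QC injections, 500 features of which 10
#' discriminate between groups at a 2-fold change, 15% analytical
#' (QC-level) coefficient of variation, 30% median biological CV,
#' correlated blocks of 10 features sharing a within-block correlation of
#' 0.6, and left-censoring (detection-limit missingness) at the 5th
#' intensity percentile per feature.
#'
#' @param n_per_group integer pair: study samples per group.
#' @param n_qc pooled-QC injections.
#' @param p number of features.
#' @param n_true number of discriminating features.
#' @param log2_fold_change between-group effect on the log2 scale (per
#'   true feature, random sign).
#' @param qc_cv target analytical coefficient of variation.
#' @param biological_cv median biological coefficient of variation across
#'   features (per-feature values are drawn lognormal around it).
#' @param block_size width of the correlated feature blocks.
#' @param within_block_corr within-block correlation of the biological
#'   variation, in \[0, 1).
#' @param lod_quantile per-feature detection-limit quantile driving
#'   missingness.
#' @param seed integer seed; the generated table is bit-reproducible.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_per_group = c(50L, 50L), n_qc = 8L, p = 500L,
                              n_true = 10L, log2_fold_change = 1.0,
                              qc_cv = 0.15, biological_cv = 0.30,
                              block_size = 10L, within_block_corr = 0.6,
                              lod_quantile = 0.05, seed = 1L) {
  d <- list(n_per_group = as.integer(n_per_group), n_qc = as.integer(n_qc),
            p = as.integer(p), n_true = as.integer(n_true),
            log2_fold_change = log2_fold_change, qc_cv = qc_cv,
            biological_cv = biological_cv, block_size = as.integer(block_size),
            within_block_corr = within_block_corr,
            lod_quantile = lod_quantile, seed = as.integer(seed))
  if (length(d$n_per_group) != 2L || any(d$n_per_group < 1L))
    stop("n_per_group must be two positive counts")
  if (d$n_true > d$p) stop("n_true cannot exceed p")
  if (d$n_true < 0L || d$p < 1L || d$n_qc < 0L) stop("counts must be non-negative")
  if (d$within_block_corr < 0 || d$within_block_corr >= 1)
    stop("within_block_corr must lie in [0, 1)")
  if (d$qc_cv < 0 || d$biological_cv < 0) stop("CVs must be non-negative")
  if (d$lod_quantile < 0 || d$lod_quantile >= 1)
    stop("lod_quantile must lie in [0, 1)")
  structure(d, class = "simulation_design")
}

# lognormal sd (log2 scale) giving a raw-scale coefficient of variation cv
sigma_log2_for_cv <- function(cv) sqrt(log(1 + cv^2)) / log(2)

#' Simulate a two-class untargeted LC-MS feature table
#'
#' Generates a [feature_table()] with known ground truth.  On the log2
#' scale, each feature has a baseline abundance drawn from a wide
#' distribution; study samples add (i) a group effect of
#' `+/- log2_fold_change` for the `n_true` planted discriminating features,
#' (ii) block-structured biological variation (a per-sample block factor
#' shared by `block_size` consecutive features induces the within-block
#' correlation — the multicollinearity typical of adduct/fragment groups),
#' and (iii) analytical noise at `qc_cv`.  QC injections replicate the
#' pooled sample: the per-feature mean of all study samples' expected
#' intensities, plus analytical noise only.  Intensities are exponentiated
#' to the raw scale and left-censored at the per-feature `lod_quantile`
#' detection threshold (censored cells become missing).
#'
#' @param d a [simulation_design()].
#' @return list with `table` (a [feature_table()]) and `truth`
#'   (`true_feature_ids`, per-feature `effect_log2` signed effects).
#' @export
simulate_study <- function(d) {
  stopifnot(inherits(d, "simulation_design"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(d$seed)

  n_a <- d$n_per_group[1L]
  n_b <- d$n_per_group[2L]
  n <- n_a + n_b
  p <- d$p

  feature_ids <- sprintf("M%04d", seq_len(p))
  baseline <- stats::rnorm(p, mean = log2(1e5), sd = 2)      # wide abundance range
  neutral_mass <- stats::runif(p, 80, 1000)
  rt <- stats::runif(p, 0.5, 20)

  true_idx <- sort(sample.int(p, d$n_true))
  effect_sign <- sample(c(-1, 1), d$n_true, replace = TRUE)
  effect <- numeric(p)
  effect[true_idx] <- effect_sign * d$log2_fold_change

  # heterogeneous biological dispersion across features (lognormal around
  # the design median) so that feature variances differ — the regime in
  # which UV and Pareto scaling genuinely disagree
  sigma_bio <- sigma_log2_for_cv(d$biological_cv) * exp(stats::rnorm(p, 0, 0.4))
  sigma_tech <- sigma_log2_for_cv(d$qc_cv)

  block <- ((seq_len(p) - 1L) %/% d$block_size) + 1L
  n_block <- max(block)
  rho <- d$within_block_corr

  grp <- rep(c(0, 1), c(n_a, n_b))                            # 0 = group A
  mu <- outer(rep(1, n), baseline) +
    outer(grp - 0.5, effect)                                  # +/- half effect per group
  U <- matrix(stats::rnorm(n * n_block), n, n_block)          # block factors
  E <- matrix(stats::rnorm(n * p), n, p)
  bio <- (sqrt(rho) * U[, block, drop = FALSE] + sqrt(1 - rho) * E) *
    matrix(sigma_bio, n, p, byrow = TRUE)
  tech <- matrix(stats::rnorm(n * p, sd = sigma_tech), n, p)
  Z_study <- mu + bio + tech

  # QC = pooled sample: per-feature mean of the study samples' expected
  # raw-scale intensities, analytical noise only
  qc_base <- log2(colMeans(2^mu))
  Z_qc <- outer(rep(1, d$n_qc), qc_base) +
    if (sigma_tech > 0) matrix(stats::rnorm(d$n_qc * p, sd = sigma_tech),
                               d$n_qc, p) else 0

  X <- 2^rbind(Z_study, Z_qc)

  # detection limit: left-censor below the per-feature lod_quantile of the
  # study-sample intensities
  if (d$lod_quantile > 0) {
    lod <- apply(X[seq_len(n), , drop = FALSE], 2L, stats::quantile,
                 probs = d$lod_quantile)
    X[sweep(X, 2L, lod, "<")] <- NA_real_
  }

  sample_meta <- data.frame(
    sample_id = c(sprintf("A%03d", seq_len(n_a)),
                  sprintf("B%03d", seq_len(n_b)),
                  sprintf("QC%02d", seq_len(d$n_qc))),
    group = c(rep("groupA", n_a), rep("groupB", n_b), rep(NA, d$n_qc)),
    is_qc = c(rep(FALSE, n), rep(TRUE, d$n_qc)),
    stringsAsFactors = FALSE)
  feature_meta <- data.frame(feature_id = feature_ids,
                             neutral_mass = neutral_mass, rt = rt,
                             stringsAsFactors = FALSE)
  tab <- feature_table(X, feature_meta, sample_meta)

  truth <- list(true_feature_ids = feature_ids[true_idx],
                effect_log2 = stats::setNames(effect, feature_ids))
  list(table = tab, truth = truth)
}

#' Recovery metrics of a selection against the planted truth
#'
#' @param selected character vector of selected feature ids.
#' @param truth the `truth` element of [simulate_study()].
#' @return list with `recall`, `precision` (NA for an empty selection) and
#'   `fdp` (false discovery proportion, NA for an empty selection).
#' @export
truth_metrics <- function(selected, truth) {
  tru <- truth$true_feature_ids
  tp <- length(intersect(selected, tru))
  list(recall = if (length(tru)) tp / length(tru) else NA_real_,
       precision = if (length(selected)) tp / length(selected) else NA_real_,
       fdp = if (length(selected)) 1 - tp / length(selected) else NA_real_)
}
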