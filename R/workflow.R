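#' Approach 1: OPLS-DA with VIP selection on all filtered features
#'
#' Scales the study samples, fits the OPLS-DA model, and selects features
#' with VIP above the threshold.  R2Y is attached from the fit and Q2 from
#' stratified k-fold cross-validation of the whole scale-and-fit pipeline.
#'
#' @param t a QA-filtered, imputed [feature_table()].
#' @param scaling `"uv"` or `"pareto"`.
#' @param n_orth orthogonal components (default 1).
#' @param vip_threshold strict VIP cutoff (default 1).
#' @param cv_folds folds for Q2 (default 7).
#' @param seed seed for the cross-validation folds.
#' @return list with `selected` (feature ids), `model` (the `opls_model`
#'   with `q2` filled in) and `scaling`.
#' @export
run_approach_opls <- function(t, scaling = "uv", n_orth = 1L,
                              vip_threshold = 1.0, cv_folds = 7L, seed = 1L) {
  sm <- scale_study_matrix(t, scaling)
  m <- fit_opls_da(sm$X, sm$y, n_orth = n_orth)
  m$q2 <- as.numeric(q2_cv(t, scaling = scaling, n_orth = n_orth,
                           k = cv_folds, seed = seed))
  m$scaling <- sm$spec
  list(selected = select_by_vip(m, vip_threshold), model = m,
       scaling = scaling)
}

#' Approach 2: FDR pre-filtered OPLS-DA
#'
#' Runs the per-feature univariate tests with Benjamini-Hochberg
#' correction, keeps the features significant at `q_threshold`, and fits
#' the OPLS-DA/VIP selection on that subset only.  The final selection is
#' by construction a subset of the FDR-significant set.  An empty
#' pre-selection returns an empty selection; a singleton pre-selection is
#' returned as-is (no multivariate model can be built on one feature),
#' each with a warning.
#'
#' @inheritParams run_approach_opls
#' @param q_threshold FDR significance threshold (default 0.05).
#' @return list with `selected`, `fdr_selected` (the pre-selection),
#'   `univariate` (the full test table), `model` (or `NULL`), `scaling`.
#' @export
run_approach_fdr_opls <- function(t, scaling = "uv", q_threshold = 0.05,
                                  n_orth = 1L, vip_threshold = 1.0,
                                  cv_folds = 7L, seed = 1L) {
  uni <- run_univariate(t, alpha = q_threshold)
  pre <- fdr_select(uni, q_threshold)
  if (length(pre) == 0L) {
    warning("no FDR-significant features; skipping OPLS-DA")
    return(list(selected = character(0), fdr_selected = pre,
                univariate = uni, model = NULL, scaling = scaling))
  }
  if (length(pre) == 1L) {
    warning("a single FDR-significant feature; skipping OPLS-DA")
    return(list(selected = pre, fdr_selected = pre,
                univariate = uni, model = NULL, scaling = scaling))
  }
  sub <- subset_features(t, pre)
  res <- run_approach_opls(sub, scaling = scaling, n_orth = n_orth,
                           vip_threshold = vip_threshold,
                           cv_folds = min(cv_folds, min(table(class_codes(sub)))),
                           seed = seed)
  list(selected = res$selected, fdr_selected = pre, univariate = uni,
       model = res$model, scaling = scaling)
}

#' Approach 3: LASSO penalized logistic regression with bootstrap stability
#'
#' Builds the standardized problem, selects the penalty along the path,
#' and evaluates per-feature bootstrap reproducibility by re-running the
#' whole selection on stratified resamples.
#'
#' @param t a QA-filtered, imputed [feature_table()].
#' @param rule penalty-selection rule, `"aic"` (default) or `"cv_deviance"`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param grid_size,grid_ratio penalty-grid layout.
#' @param cv_folds folds for the `"cv_deviance"` rule.
#' @return list with `selected` (active set of the selected full-data
#'   fit), `report` (selection annotated with reproducibility), `path`,
#'   `stability`.
#' @export
run_approach_lasso <- function(t, rule = "aic", n_boot = 1000L, seed = 1L,
                               grid_size = 100L, grid_ratio = 1e-3,
                               cv_folds = 5L) {
  prob <- make_problem(t)
  path <- select_lambda(prob, grid = lambda_grid(prob, grid_size, grid_ratio),
                        rule = rule, k = cv_folds, seed = seed)
  stab <- bootstrap_stability(t, n_boot = n_boot, seed = seed, rule = rule,
                              k = cv_folds, grid_size = grid_size,
                              grid_ratio = grid_ratio)
  rep <- select_by_stability(stab, path)
  list(selected = path$fit_selected$active_set, report = rep,
       path = path, stability = stab)
}

#' Three-way comparison of selected feature sets
#'
#' Counts all seven Venn regions of the three selections and the consensus
#' (triple intersection).
#'
#' @param a,b,c character vectors of feature ids (same universe).
#' @param names labels for the three sets.
#' @return A `selection_report` list with `sets`, `venn` (named counts:
#'   `a_only`, `b_only`, `c_only`, `ab_only`, `ac_only`, `bc_only`, `abc`),
#'   `consensus`, `union_size`.
#' @export
compare_selections <- function(a, b, c,
                               names = c("opls_vip", "fdr_opls_vip", "lasso")) {
  u <- union(union(a, b), c)
  in_a <- u %in% a
  in_b <- u %in% b
  in_c <- u %in% c
  venn <- c(
    a_only = sum(in_a & !in_b & !in_c),
    b_only = sum(!in_a & in_b & !in_c),
    c_only = sum(!in_a & !in_b & in_c),
    ab_only = sum(in_a & in_b & !in_c),
    ac_only = sum(in_a & !in_b & in_c),
    bc_only = sum(!in_a & in_b & in_c),
    abc = sum(in_a & in_b & in_c))
  structure(
    list(sets = stats::setNames(list(a, b, c), names),
         venn = venn,
         consensus = u[in_a & in_b & in_c],
         union_size = length(u)),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection comparison (", paste(names(x$sets), collapse = " / "), ")\n",
      sep = "")
  cat("  set sizes: ", paste(vapply(x$sets, length, integer(1)),
                             collapse = " / "), "\n", sep = "")
  cat("  Venn regions:",
      paste(names(x$venn), x$venn, sep = "=", collapse = ", "), "\n")
  cat("  consensus (all three): ", length(x$consensus), " feature(s)\n",
      sep = "")
  invisible(x)
}

#' Default workflow configuration
#'
#' Returns the configuration list consumed by [run_all()], optionally
#' merged with overrides read from a YAML file.  Blocks: `simulate`
#' (generator design; set `input$intensity_path`/`input$sample_meta_path`
#' instead to read real data), `qa` (filter thresholds), `pca`
#' (`outlier_removal`, `confidence`), `opls` (`n_orth`, `vip_threshold`,
#' `cv_folds`), `fdr` (`q_threshold`), `lasso` (`rule`, `n_boot`,
#' `grid_size`, `grid_ratio`, `cv_folds`).
#'
#' @param config_path optional YAML file with overriding blocks.
#' @export
default_config <- function(config_path = NULL) {
  cfg <- list(
    input = NULL,
    simulate = list(n_per_group = c(50L, 50L), n_qc = 8L, p = 500L,
                    n_true = 10L, log2_fold_change = 1.0, qc_cv = 0.15,
                    biological_cv = 0.30, block_size = 10L,
                    within_block_corr = 0.6, lod_quantile = 0.05),
    qa = list(min_qc_fraction = 0.5, max_cv = 0.20, min_group_fraction = 0.8),
    pca = list(outlier_removal = FALSE, confidence = 0.95, n_components = 2L),
    opls = list(n_orth = 1L, vip_threshold = 1.0, cv_folds = 7L),
    fdr = list(q_threshold = 0.05),
    lasso = list(rule = "aic", n_boot = 1000L, grid_size = 100L,
                 grid_ratio = 1e-3, cv_folds = 5L))
  if (!is.null(config_path)) {
    user <- yaml::read_yaml(config_path)
    for (blk in names(user)) {
      if (is.list(user[[blk]]) && is.list(cfg[[blk]])) {
        cfg[[blk]][names(user[[blk]])] <- user[[blk]]
      } else {
        cfg[[blk]] <- user[[blk]]
      }
    }
  }
  cfg
}

#' Run the full three-approach comparison
#'
#' End-to-end pipeline: obtain the feature table (simulate per config, or
#' read the files named in `config$input`), apply the QA filtration chain,
#' optionally remove PCA/Hotelling outliers, impute non-detects, run the
#' three selection approaches (OPLS-DA/VIP under both UV and Pareto
#' scaling, FDR-prefiltered OPLS-DA under both scalings, LASSO once — it
#' standardizes internally), and compare the UV-scaled selections in a
#' three-way Venn summary.  All randomness derives from `seed`; a fixed
#' config + seed reproduces every output file byte-identically.
#'
#' @param config configuration list from [default_config()].
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @param seed integer master seed.
#' @return Invisibly, a list with the filtered table, per-approach results,
#'   the `selection_report`, and the QA logs.
#' @export
run_all <- function(config = default_config(), out_dir = NULL, seed = 1L) {
  seed <- as.integer(seed)
  if (!is.null(config$input)) {
    tab <- read_feature_table(config$input$intensity_path,
                              config$input$sample_meta_path)
    truth <- NULL
  } else {
    dsn <- do.call(simulation_design, c(config$simulate, list(seed = seed)))
    sim <- simulate_study(dsn)
    tab <- sim$table
    truth <- sim$truth
  }

  qa <- apply_qa_pipeline(tab,
                          min_qc_fraction = config$qa$min_qc_fraction,
                          max_cv = config$qa$max_cv,
                          min_group_fraction = config$qa$min_group_fraction)
  t_f <- qa$table
  if (ncol(t_f$intensities) == 0L)
    stop("all features removed by QA filtration")

  outliers <- NULL
  if (isTRUE(config$pca$outlier_removal)) {
    ti <- impute_lod(t_f)
    sm <- scale_study_matrix(ti, "uv")
    pca <- fit_pca(sm$X, n_components = config$pca$n_components)
    flags <- hotelling_outliers(pca, confidence = config$pca$confidence)
    outliers <- sm$sample_ids[flags]
    if (length(outliers))
      t_f <- subset_samples(t_f, setdiff(t_f$sample_meta$sample_id, outliers))
  }

  ti <- impute_lod(t_f)

  opls_uv <- run_approach_opls(ti, "uv", n_orth = config$opls$n_orth,
                               vip_threshold = config$opls$vip_threshold,
                               cv_folds = config$opls$cv_folds, seed = seed)
  opls_par <- run_approach_opls(ti, "pareto", n_orth = config$opls$n_orth,
                                vip_threshold = config$opls$vip_threshold,
                                cv_folds = config$opls$cv_folds, seed = seed)
  fdr_uv <- suppressWarnings(
    run_approach_fdr_opls(ti, "uv", q_threshold = config$fdr$q_threshold,
                          n_orth = config$opls$n_orth,
                          vip_threshold = config$opls$vip_threshold,
                          cv_folds = config$opls$cv_folds, seed = seed))
  fdr_par <- suppressWarnings(
    run_approach_fdr_opls(ti, "pareto", q_threshold = config$fdr$q_threshold,
                          n_orth = config$opls$n_orth,
                          vip_threshold = config$opls$vip_threshold,
                          cv_folds = config$opls$cv_folds, seed = seed))
  lasso <- run_approach_lasso(ti, rule = config$lasso$rule,
                              n_boot = config$lasso$n_boot, seed = seed,
                              grid_size = config$lasso$grid_size,
                              grid_ratio = config$lasso$grid_ratio,
                              cv_folds = config$lasso$cv_folds)

  report <- compare_selections(opls_uv$selected, fdr_uv$selected,
                               lasso$selected)

  out <- list(table = t_f, truth = truth, qa_logs = qa$logs,
              outliers_removed = outliers,
              opls_uv = opls_uv, opls_pareto = opls_par,
              fdr_opls_uv = fdr_uv, fdr_opls_pareto = fdr_par,
              lasso = lasso, report = report, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_qa_log(qa$logs, file.path(out_dir, "qa_log.jsonl"))
    write_univariate(fdr_uv$univariate, file.path(out_dir, "univariate.tsv"))
    write_stability(lasso$stability, file.path(out_dir, "stability.tsv"))
    write_lasso_path(lasso$path, file.path(out_dir, "lasso_path.tsv"))
    sel_tab <- function(ids) data.frame(feature_id = ids,
                                        stringsAsFactors = FALSE)
    sets <- list(selection_opls_uv = opls_uv$selected,
                 selection_opls_pareto = opls_par$selected,
                 selection_fdr_opls_uv = fdr_uv$selected,
                 selection_fdr_opls_pareto = fdr_par$selected,
                 selection_lasso = lasso$selected)
    for (nm in names(sets))
      utils::write.table(sel_tab(sets[[nm]]),
                         file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    jr <- list(
      seed = seed,
      n_features_after_qa = ncol(t_f$intensities),
      outliers_removed = as.list(outliers),
      approaches = list(
        opls_vip = list(scaling = "uv",
                        n_selected = length(opls_uv$selected),
                        r2y = opls_uv$model$r2y, q2 = opls_uv$model$q2),
        opls_vip_pareto = list(scaling = "pareto",
                               n_selected = length(opls_par$selected),
                               r2y = opls_par$model$r2y,
                               q2 = opls_par$model$q2),
        fdr_opls_vip = list(scaling = "uv",
                            n_fdr_significant = length(fdr_uv$fdr_selected),
                            n_selected = length(fdr_uv$selected),
                            r2y = if (!is.null(fdr_uv$model)) fdr_uv$model$r2y,
                            q2 = if (!is.null(fdr_uv$model)) fdr_uv$model$q2),
        fdr_opls_vip_pareto = list(scaling = "pareto",
                                   n_fdr_significant = length(fdr_par$fdr_selected),
                                   n_selected = length(fdr_par$selected)),
        lasso = list(n_selected = length(lasso$selected),
                     lambda = lasso$path$lambda_selected,
                     reproducibility_min = if (nrow(lasso$report))
                       min(lasso$report$reproducibility),
                     reproducibility_max = if (nrow(lasso$report))
                       max(lasso$report$reproducibility))),
      venn = as.list(report$venn),
      consensus = as.list(report$consensus))
    jsonlite::write_json(jr, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
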