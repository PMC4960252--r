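test_that("the problem is standardized with a reversible coding", {
  t <- random_table(n_a = 8, n_b = 8, p = 6, seed = 14)
  ti <- impute_lod(t)
  prob <- make_problem(ti)
  expect_lt(max(abs(colMeans(prob$X))), 1e-10)
  expect_lt(max(abs(apply(prob$X, 2, sd) - 1)), 1e-10)
  expect_equal(unname(prob$y_mapping), c(0L, 1L))
  expect_equal(names(prob$y_mapping), c("A", "B"))
  # back-transform identity: beta on the raw scale times sd recovers beta
  f <- fit_lasso_logistic(prob, lambda_max(prob) / 4)
  expect_equal(f$beta_raw * prob$scale, f$beta, ignore_attr = TRUE)

  X <- cbind(rnorm(10), rep(1, 10))
  expect_error(metabselect:::make_problem_matrix(X, rep(0:1, 5), c("a", "b")),
               "zero-variance.*b")
})

test_that("lambda_max is the exact knot where the active set empties", {
  set.seed(33)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- rbinom(40, 1, 0.5)
  prob <- metabselect:::make_problem_matrix(X, y, paste0("f", 1:10))
  lmax <- lambda_max(prob)
  expect_equal(lmax, max(abs(crossprod(prob$X, prob$y - mean(prob$y)))),
               ignore_attr = TRUE)
  expect_length(fit_lasso_logistic(prob, lmax)$active_set, 0L)
  expect_length(fit_lasso_logistic(prob, 1.01 * lmax)$active_set, 0L)
  expect_gt(length(fit_lasso_logistic(prob, 0.99 * lmax)$active_set), 0L)
})

test_that("the null fit recovers the closed-form intercept and likelihood", {
  set.seed(40)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- rbinom(60, 1, 0.3)
  prob <- metabselect:::make_problem_matrix(X, y, paste0("f", 1:5))
  f <- fit_lasso_logistic(prob, 2 * lambda_max(prob))
  yb <- mean(y)
  expect_equal(f$intercept, qlogis(yb), tolerance = 1e-7)
  ll0 <- length(y) * (yb * log(yb) + (1 - yb) * log(1 - yb))
  expect_equal(f$log_likelihood, ll0, tolerance = 1e-7)
  expect_equal(f$aic, -2 * ll0 + 2, tolerance = 1e-6)  # k = 1, intercept only
  expect_equal(aic(f), f$aic)
})

test_that("unpenalized coefficients match the Newton logistic MLE", {
  set.seed(50)
  for (rep in 1:20) {
    X <- matrix(rnorm(90), 30, 3)
    y <- rbinom(30, 1, plogis(0.8 * X[, 1] - 0.5 * X[, 3]))
    if (length(unique(y)) < 2) next
    prob <- metabselect:::make_problem_matrix(X, y, paste0("f", 1:3))
    f <- fit_lasso_logistic(prob, 0)
    g <- suppressWarnings(glm.fit(cbind(1, prob$X), y,
                                  family = binomial()))
    expect_lt(max(abs(c(f$intercept, unname(f$beta)) - g$coefficients)), 1e-5)
  }
})

test_that("solutions satisfy the KKT conditions along the whole path", {
  set.seed(60)
  for (rep in 1:5) {
    n <- sample(30:50, 1); p <- sample(5:50, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, plogis(X[, 1] - X[, 2]))
    if (length(unique(y)) < 2) next
    prob <- metabselect:::make_problem_matrix(X, y, paste0("f", seq_len(p)))
    path <- select_lambda(prob, grid = lambda_grid(prob, 40L))
    for (i in seq_along(path$fits)) {
      f <- path$fits[[i]]
      lam <- path$lambda_grid[i]
      pi_hat <- plogis(drop(prob$X %*% f$beta) + f$intercept)
      gr <- drop(crossprod(prob$X, prob$y - pi_hat))
      act <- f$beta != 0
      if (any(act)) {
        expect_lt(max(abs(abs(gr[act]) - lam)), 1e-6)
        expect_true(all(sign(gr[act]) == sign(f$beta[act])))
      }
      if (any(!act)) expect_lt(max(abs(gr[!act])) - lam, 1e-6)
    }
    # L1 norm non-increasing in lambda (tolerance for numerical wiggle)
    l1 <- vapply(path$fits, function(f) sum(abs(f$beta)), numeric(1))
    expect_true(all(diff(l1) > -1e-6))
  }
})

test_that("the exact objective never increases across outer iterations", {
  set.seed(70)
  X <- matrix(rnorm(50 * 20), 50, 20)
  y <- rbinom(50, 1, plogis(2 * X[, 1]))
  prob <- metabselect:::make_problem_matrix(X, y, paste0("f", 1:20))
  for (lam in c(0.1, 1, 5) * lambda_max(prob) / 10) {
    f <- fit_lasso_logistic(prob, lam)
    expect_true(all(diff(f$objective_trace) <= 1e-12))
  }
})

test_that("lambda selection is deterministic and recovers a planted signal", {
  set.seed(80)
  X <- matrix(rnorm(100 * 50), 100, 50)
  eta <- 1.5 * X[, 1] - 1.5 * X[, 2] + 1.5 * X[, 3]
  y <- rbinom(100, 1, plogis(eta))
  prob <- metabselect:::make_problem_matrix(X, y, paste0("f", 1:50))

  # degenerate grid: the null model is selected
  p0 <- select_lambda(prob, grid = lambda_max(prob))
  expect_length(p0$fit_selected$active_set, 0L)

  path <- select_lambda(prob)
  expect_true(all(c("f1", "f2", "f3") %in% path$fit_selected$active_set))
  # interior AIC minimum exists on this signal
  expect_gt(path$selected_index, 1L)
  expect_lt(path$selected_index, length(path$lambda_grid))

  path2 <- select_lambda(prob)
  expect_identical(path$lambda_selected, path2$lambda_selected)
  expect_identical(path$fit_selected$beta, path2$fit_selected$beta)

  cv1 <- select_lambda(prob, rule = "cv_deviance", seed = 5)
  cv2 <- select_lambda(prob, rule = "cv_deviance", seed = 5)
  expect_identical(cv1$lambda_selected, cv2$lambda_selected)
  expect_true(all(c("f1", "f2", "f3") %in% cv1$fit_selected$active_set))
})

test_that("active sets agree with an independent penalized solver", {
  skip_if_not_installed("glmnet")
  set.seed(90)
  X <- matrix(rnorm(80 * 30), 80, 30)
  y <- rbinom(80, 1, plogis(X[, 1] - X[, 2]))
  prob <- metabselect:::make_problem_matrix(X, y, paste0("f", 1:30))
  # glmnet minimizes -ll/n + lambda ||beta||_1 -> its lambda is ours / n
  for (lam in lambda_max(prob) * c(0.5, 0.2, 0.05)) {
    f <- fit_lasso_logistic(prob, lam)
    g <- glmnet::glmnet(prob$X, prob$y, family = "binomial",
                        lambda = lam / prob$n, standardize = FALSE,
                        thresh = 1e-12)
    gb <- as.numeric(g$beta)
    expect_lt(max(abs(unname(f$beta) - gb)), 1e-4)
  }
})

test_that("bootstrap stability is seeded bookkeeping over real refits", {
  st <- filtered_study(seed = 6, n_per_group = c(15L, 15L), p = 40L,
                       n_true = 3L, log2_fold_change = 2)
  s1 <- bootstrap_stability(st$table, n_boot = 15L, seed = 9L)
  s2 <- bootstrap_stability(st$table, n_boot = 15L, seed = 9L)
  expect_identical(s1$inclusion_count, s2$inclusion_count)
  expect_true(all(s1$reproducibility >= 0 & s1$reproducibility <= 100))
  # counts equal recomputation from the stored per-resample active sets
  recount <- table(unlist(s1$active_sets))
  for (id in names(s1$inclusion_count)) {
    expect_equal(unname(s1$inclusion_count[id]),
                 if (id %in% names(recount)) unname(as.integer(recount[id])) else 0L)
  }
})

test_that("an overwhelming discriminator is always selected", {
  # one feature separates the classes by 20 biological sds
  set.seed(17)
  n <- 30
  X <- exp(matrix(rnorm(n * 8, 8, 0.2), n, 8))
  X[, 1] <- X[, 1] * rep(c(1, 50), each = n / 2)
  t <- make_table(X, rep(c("A", "B"), each = n / 2))
  ti <- impute_lod(t)
  s <- bootstrap_stability(ti, n_boot = 30L, seed = 4L)
  expect_gte(s$reproducibility["F1"], 99)
  # pure-noise features stay near zero
  expect_lte(median(s$reproducibility[-1]), 10)
})

test_that("the stability report annotates, flags, and never filters", {
  st <- filtered_study(seed = 16, n_per_group = c(15L, 15L), p = 40L,
                       n_true = 3L, log2_fold_change = 2)
  prob <- make_problem(st$table)
  path <- select_lambda(prob)
  s <- bootstrap_stability(st$table, n_boot = 15L, seed = 2L)
  rep <- select_by_stability(s, path, min_reproducibility = 90)
  expect_setequal(rep$feature_id, path$fit_selected$active_set)
  expect_equal(rep$reproducibility, unname(s$reproducibility[rep$feature_id]))
  expect_equal(rep$flagged, rep$reproducibility < 90)

  # empty active set -> empty report
  p0 <- select_lambda(prob, grid = lambda_max(prob))
  expect_equal(nrow(select_by_stability(s, p0)), 0L)
})
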