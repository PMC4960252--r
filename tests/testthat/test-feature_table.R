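test_that("constructor enforces shape, uniqueness, sign and group invariants", {
  X <- matrix(1:6, 3, 2)
  t <- make_table(X, c("A", "B", "A"))
  expect_s3_class(t, "feature_table")
  expect_equal(dim(t), c(3L, 2L))

  expect_error(make_table(X, c("A", "B")), "rows")
  expect_error(make_table(X, c("A", "B", "A"), feature_ids = c("F1", "F1")),
               "duplicated feature_id")
  expect_error(make_table(-X, c("A", "B", "A")), "negative")
  expect_error(make_table(X, c("A", "A", "A")), "2 study groups")
  expect_error(make_table(X, c("A", "B", "C")), "2 study groups")
})

test_that("read/write round trip is exact and preserves missingness", {
  set.seed(42)
  X <- matrix(exp(rnorm(40, 10, 1)), 8, 5)
  X[2, 3] <- NA
  X[5, 1] <- NA
  t0 <- make_table(X, c(rep("A", 3), rep("B", 3), NA, NA))
  for (orient in c("features_in_rows", "samples_in_rows")) {
    ip <- tempfile(fileext = ".csv")
    sp <- tempfile(fileext = ".csv")
    write_feature_table(t0, ip, sp, orientation = orient)
    t1 <- read_feature_table(ip, sp, orientation = orient,
                             zero_as_missing = FALSE)
    expect_identical(t1$intensities, t0$intensities)
    expect_identical(is.na(t1$intensities), is.na(t0$intensities))
    expect_identical(t1$sample_meta$group, t0$sample_meta$group)
  }
})

test_that("zero cells parse as missing when the sentinel is enabled", {
  ip <- tempfile(fileext = ".csv")
  sp <- tempfile(fileext = ".csv")
  writeLines(c("feature_id,neutral_mass,rt,S1,S2,S3",
               "F1,100,1.0,0,5,7",
               "F2,200,2.0,3,4,5"), ip)
  writeLines(c("sample_id,group,is_qc",
               "S1,A,FALSE", "S2,A,FALSE", "S3,B,FALSE"), sp)
  t1 <- read_feature_table(ip, sp)
  expect_true(is.na(t1$intensities["S1", "F1"]))
  t2 <- read_feature_table(ip, sp, zero_as_missing = FALSE)
  expect_equal(t2$intensities["S1", "F1"], 0)
})

test_that("sample id mismatch between files is a hard error naming offenders", {
  ip <- tempfile(fileext = ".csv")
  sp <- tempfile(fileext = ".csv")
  writeLines(c("feature_id,neutral_mass,rt,S1,S2",
               "F1,100,1.0,2,5"), ip)
  writeLines(c("sample_id,group,is_qc",
               "S1,A,FALSE", "S2,B,FALSE", "S9,B,FALSE"), sp)
  expect_error(read_feature_table(ip, sp), "S9")
})

test_that("QC presence filter uses an inclusive threshold and needs QCs", {
  # feature 1 present in 1/4 QCs (removed at 0.5), feature 2 in 2/4 (kept),
  # feature 3 in all (kept)
  X <- matrix(10, 8, 3)
  X[5:7, 1] <- NA         # QCs are rows 5:8
  X[5:6, 2] <- NA
  t <- make_table(X, c("A", "A", "B", "B", NA, NA, NA, NA))
  out <- qc_presence_filter(t, 0.5)
  expect_equal(out$table$feature_meta$feature_id, c("F2", "F3"))
  expect_equal(out$log$removed_feature_ids, "F1")
  expect_equal(out$log$n_features_before - length(out$log$removed_feature_ids),
               out$log$n_features_after)

  no_qc <- make_table(X[1:4, ], c("A", "A", "B", "B"))
  expect_error(qc_presence_filter(no_qc), "no QC samples")

  all_there <- make_table(matrix(5, 6, 2), c("A", "A", "B", "B", NA, NA))
  expect_equal(qc_presence_filter(all_there)$table$intensities,
               all_there$intensities)
})

test_that("QC CV filter is strictly below the bound, on the raw scale", {
  # F1: QC [100,100,100] -> CV 0, kept
  # F2: QC [100,150] (one QC missing) -> CV = sd/mean = 35.36/125 > 0.2, removed
  # F3: QC [80,100,120] -> CV exactly 0.20, removed (strict <)
  # F4: only 1 non-missing QC -> undefined CV, removed
  # F5: all QCs missing -> removed, not an error
  X <- matrix(100, 7, 5)
  X[5:7, 2] <- c(100, 150, NA)
  X[5:7, 3] <- c(80, 100, 120)
  X[5:7, 4] <- c(90, NA, NA)
  X[5:7, 5] <- NA
  t <- make_table(X, c("A", "A", "B", "B", NA, NA, NA))
  out <- qc_cv_filter(t, 0.20)
  expect_equal(out$table$feature_meta$feature_id, "F1")
  expect_setequal(out$log$removed_feature_ids, c("F2", "F3", "F4", "F5"))
  # the hand-computed F2 CV
  expect_equal(sd(c(100, 150)) / mean(c(100, 150)), 0.2828427, tolerance = 1e-6)
})

test_that("group presence keeps a feature detected well in either group", {
  # 10 per group; F1: 9/10 A, 0/10 B -> kept; F2: 7/10 both -> removed;
  # F3: exactly 8/10 in A -> kept (inclusive)
  X <- matrix(5, 22, 3)
  a_rows <- 1:10; b_rows <- 11:20
  X[a_rows[1], 1] <- NA; X[b_rows, 1] <- NA              # F1: 9/10 vs 0/10
  X[a_rows[1:3], 2] <- NA; X[b_rows[1:3], 2] <- NA       # F2: 7/10 vs 7/10
  X[a_rows[1:2], 3] <- NA; X[b_rows, 3] <- NA            # F3: 8/10 vs 0/10
  t <- make_table(X, c(rep("A", 10), rep("B", 10), NA, NA))
  out <- group_presence_filter(t, 0.8)
  expect_setequal(out$table$feature_meta$feature_id, c("F1", "F3"))
  expect_equal(out$log$removed_feature_ids, "F2")
})

test_that("QA pipeline equals an independent rule evaluator and is idempotent", {
  set.seed(77)
  n_a <- 10; n_b <- 10; n_qc <- 6; p <- 60
  X <- matrix(exp(rnorm((n_a + n_b + n_qc) * p, 8, 0.1)),
              n_a + n_b + n_qc, p)
  qc_rows <- (n_a + n_b + 1):(n_a + n_b + n_qc)
  # plant violators of each rule
  X[qc_rows[1:4], 1:5] <- NA                      # fail QC presence
  X[qc_rows, 6:10] <- X[qc_rows, 6:10] * exp(matrix(rnorm(n_qc * 5, 0, 0.6),
                                                    n_qc, 5))  # high CV
  X[1:8, 11:15] <- NA; X[(n_a + 1):(n_a + 8), 11:15] <- NA  # fail group presence
  t <- make_table(X, c(rep("A", n_a), rep("B", n_b), rep(NA, n_qc)))

  res <- apply_qa_pipeline(t)
  expect_setequal(res$table$feature_meta$feature_id, qa_rules_brute(t))
  expect_length(res$logs, 3L)

  # idempotence: a second pass removes nothing
  res2 <- apply_qa_pipeline(res$table)
  expect_identical(res2$table$intensities, res$table$intensities)
  expect_true(all(vapply(res2$logs, function(l)
    length(l$removed_feature_ids) == 0L, logical(1))))

  # order independence of the surviving set (CV values are untouched by
  # the presence filters)
  alt <- qc_cv_filter(group_presence_filter(qc_presence_filter(t)$table)$table)
  expect_setequal(alt$table$feature_meta$feature_id,
                  res$table$feature_meta$feature_id)
})

test_that("a table where every feature fails filters to zero features", {
  X <- matrix(10, 6, 2)
  X[5:6, ] <- NA  # QCs all missing
  t <- make_table(X, c("A", "A", "B", "B", NA, NA))
  res <- apply_qa_pipeline(t)
  expect_equal(ncol(res$table$intensities), 0L)
})

test_that("LOD imputation fills half the feature minimum and reverses", {
  X <- matrix(c(4, 8, NA, 6,
                10, NA, 20, 40), 4, 2)
  t <- make_table(X, c("A", "A", "B", "B"))
  ti <- impute_lod(t)
  expect_equal(ti$intensities[3, 1], 2)   # min(4,8,6)/2
  expect_equal(ti$intensities[2, 2], 5)   # min(10,20,40)/2
  back <- unimpute_lod(ti)
  expect_identical(is.na(back$intensities), is.na(t$intensities))
})

test_that("QA logs serialize as JSON lines", {
  t <- random_table()
  res <- apply_qa_pipeline(t)
  f <- tempfile(fileext = ".jsonl")
  write_qa_log(res$logs, f)
  lines <- readLines(f)
  expect_length(lines, 3L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$stage_name, "qc_presence")
  expect_equal(rec$n_features_before, 10)
})
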