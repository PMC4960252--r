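# Fixture builders and independent oracles used across the suite.

# Minimal feature table from an intensity matrix.  groups: character vector
# per sample, NA for QC injections.
make_table <- function(X, groups, is_qc = is.na(groups),
                       feature_ids = paste0("F", seq_len(ncol(X)))) {
  feature_table(
    X,
    feature_meta = data.frame(feature_id = feature_ids,
                              neutral_mass = 100 + seq_len(ncol(X)),
                              rt = seq_len(ncol(X)) / 10,
                              stringsAsFactors = FALSE),
    sample_meta = data.frame(sample_id = sprintf("S%02d", seq_len(nrow(X))),
                             group = groups, is_qc = is_qc,
                             stringsAsFactors = FALSE))
}

# A two-group table with QCs from iid lognormal noise (no signal).
random_table <- function(n_a = 6, n_b = 6, n_qc = 4, p = 10, seed = 1) {
  set.seed(seed)
  n <- n_a + n_b + n_qc
  X <- matrix(exp(rnorm(n * p, 10, 0.3)), n, p)
  make_table(X, c(rep("A", n_a), rep("B", n_b), rep(NA, n_qc)))
}

# Brute-force Benjamini-Hochberg step-up adjusted values, written directly
# from the definition with explicit loops.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (pos in seq_len(m)) {
    i <- o[pos]
    best <- Inf
    for (pos2 in pos:m) {
      j <- o[pos2]
      best <- min(best, p[j] * m / pos2)
    }
    q[i] <- min(best, 1)
  }
  q
}

# Classical BH step-up rejection set: largest k with p_(k) <= k*alpha/m.
bh_reject_brute <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * alpha / m) k <- i
  if (k == 0) integer(0) else sort(o[seq_len(k)])
}

# Independent per-feature QA rule evaluator: returns the ids a feature
# table should retain, judging every feature against all three rules
# directly (presence fractions and QC CV computed from scratch).
qa_rules_brute <- function(t, min_qc_fraction = 0.5, max_cv = 0.20,
                           min_group_fraction = 0.8) {
  X <- t$intensities
  qc <- t$sample_meta$is_qc
  g <- t$sample_meta$group
  lev <- sort(unique(na.omit(g[!qc])))
  keep <- character(0)
  for (j in seq_len(ncol(X))) {
    v_qc <- X[qc, j]
    ok1 <- mean(!is.na(v_qc)) >= min_qc_fraction
    v_obs <- v_qc[!is.na(v_qc)]
    ok2 <- length(v_obs) >= 2 && sd(v_obs) / mean(v_obs) < max_cv
    fa <- mean(!is.na(X[!qc & g %in% lev[1], j]))
    fb <- mean(!is.na(X[!qc & g %in% lev[2], j]))
    ok3 <- fa >= min_group_fraction || fb >= min_group_fraction
    if (ok1 && ok2 && ok3) keep <- c(keep, t$feature_meta$feature_id[j])
  }
  keep
}

# Step-by-step OPLS recursion oracle, written as plain scalar loops.
opls_oracle <- function(X, y, n_orth) {
  w <- as.numeric(t(X) %*% y)
  w <- w / sqrt(sum(w^2))
  W_o <- NULL; T_o <- NULL; P_o <- NULL
  Xd <- X
  for (k in seq_len(n_orth)) {
    t_p <- as.numeric(Xd %*% w)
    p_l <- as.numeric(t(Xd) %*% t_p) / sum(t_p * t_p)
    w_o <- p_l - sum(w * p_l) * w
    w_o <- w_o / sqrt(sum(w_o^2))
    t_o <- as.numeric(Xd %*% w_o)
    p_o <- as.numeric(t(Xd) %*% t_o) / sum(t_o * t_o)
    Xd <- Xd - outer(t_o, p_o)
    W_o <- cbind(W_o, w_o); T_o <- cbind(T_o, t_o); P_o <- cbind(P_o, p_o)
  }
  t_p <- as.numeric(Xd %*% w)
  cc <- sum(y * t_p) / sum(t_p * t_p)
  r2y <- 1 - sum((y - t_p * cc)^2) / sum((y - mean(y))^2)
  list(w = w, w_orth = W_o, t_orth = T_o, p_orth = P_o,
       t = t_p, c = cc, r2y = r2y)
}

# Imputed, QA-filtered synthetic study used by several modeling tests.
filtered_study <- function(seed, ...) {
  sim <- simulate_study(simulation_design(seed = seed, ...))
  qa <- apply_qa_pipeline(sim$table)
  list(table = impute_lod(qa$table), truth = sim$truth)
}
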