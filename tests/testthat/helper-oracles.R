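# Independent oracles and small fixture generators shared across tests.

# Closed-form single-kernel REML via the eigendecomposition of G: one record
# per line, intercept only. Profiles the variance ratio delta = sig_e / sig_g
# and optimizes it on the log scale.
single_kernel_reml <- function(y_line, G) {
  e <- eigen(G, symmetric = TRUE)
  yt <- drop(crossprod(e$vectors, y_line))
  xt <- drop(crossprod(e$vectors, rep(1, length(y_line))))
  d <- e$values
  nl <- length(y_line)
  obj <- function(ldelta) {
    delta <- exp(ldelta)
    w <- 1 / (d + delta)
    beta <- sum(w * xt * yt) / sum(w * xt^2)
    r <- yt - xt * beta
    s2g <- sum(w * r^2) / (nl - 1)
    0.5 * (sum(log(d + delta)) + (nl - 1) * log(s2g) + log(sum(w * xt^2)) + (nl - 1))
  }
  op <- stats::optimize(obj, c(-15, 15), tol = 1e-13)
  delta <- exp(op$minimum)
  w <- 1 / (d + delta)
  beta <- sum(w * xt * yt) / sum(w * xt^2)
  r <- yt - xt * beta
  s2g <- sum(w * r^2) / (nl - 1)
  c(sig_g = s2g, sig_e = s2g * delta, mu = beta)
}

# Literal transcription of the contrast-reliability formula with dense
# inversions and an explicit per-column loop.
naive_cd <- function(G, calib, K, lambda, fixed = "none") {
  n <- nrow(G)
  nc <- length(calib)
  Z <- matrix(0, nc, n)
  for (r in seq_len(nc)) Z[r, calib[r]] <- 1
  D <- if (fixed == "intercept") {
    X <- matrix(1, nc, 1)
    diag(nc) - X %*% solve(t(X) %*% X) %*% t(X)
  } else diag(nc)
  M <- G - lambda * solve(t(Z) %*% D %*% Z + lambda * solve(G))
  out <- numeric(ncol(K))
  for (j in seq_len(ncol(K)))
    out[j] <- (t(K[, j]) %*% M %*% K[, j]) / (t(K[, j]) %*% G %*% K[, j])
  out
}

# Per-individual CDmean by looping the literal formula.
naive_cdmean <- function(G, lambda, fixed = "none") {
  n <- nrow(G)
  vapply(seq_len(n), function(g) {
    others <- setdiff(seq_len(n), g)
    mean(naive_cd(G, g, contrast_matrix(n, others), lambda, fixed))
  }, numeric(1))
}

# A compact simulated dataset for model-level tests.
small_dataset <- function(seed = 1, n_families = 4, family_size = 14,
                          h2 = 0.3, ...) {
  cfg <- sim_config(n_families = n_families, family_size = family_size,
                    n_chromosomes = 4, markers_per_chromosome = 30,
                    n_trials = 2, blocks_per_rep = 3, h2 = h2,
                    seed = seed, ...)
  simulate_trial_data(cfg)
}

# Random positive-definite family relationship matrix (DH-like scale).
random_family_grm <- function(n, seed) {
  with_seed <- function(s, expr) { set.seed(s); expr }
  with_seed(seed, {
    A <- matrix(rnorm(n * 2 * n), n, 2 * n) / sqrt(2 * n)
    G <- tcrossprod(A) + diag(0.3, n) + 0.8
    rownames(G) <- colnames(G) <- sprintf("L%03d", seq_len(n))
    G
  })
}
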