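# Shared fixtures and independent oracles used across test files.

# small lipid panel for fast phantoms
tiny_panel <- function(n_per_tissue = 2, n_flat = 1, n_matrix = 1,
                       n_ko_up = 0, seed = 99) {
  make_lipid_panel(n_per_tissue = n_per_tissue, n_flat = n_flat,
                   n_matrix = n_matrix, n_ko_up = n_ko_up, seed = seed)
}

# brute-force Benjamini-Hochberg step-up: q_i = min over j with p_j >= p_i
# of m * p_j / rank_j, capped at 1 (computed literally from the definition)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  adj <- m * p[ord] / seq_len(m)
  # step-up: running minimum from the largest p downwards
  for (i in m:1) {
    q[ord[i]] <- min(1, if (i == m) adj[i] else min(adj[i], q[ord[i + 1]]))
  }
  q
}

# one-component NIPALS PLS1 oracle: iterative algorithm written directly
# from the textbook recipe, independent of the package implementation
nipals_pls1_oracle <- function(X, y, n_comp = 1, tol = 1e-12,
                               max_iter = 500) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  scores <- NULL; yhat <- 0
  for (k in seq_len(n_comp)) {
    w <- rep(1 / sqrt(ncol(Xc)), ncol(Xc))
    t_old <- rep(Inf, nrow(Xc))
    for (it in seq_len(max_iter)) {
      w <- drop(t(Xc) %*% yc)
      w <- w / sqrt(sum(w^2))
      t_ <- drop(Xc %*% w)
      if (sum((t_ - t_old)^2) < tol) break
      t_old <- t_
    }
    p_ <- drop(t(Xc) %*% t_) / sum(t_^2)
    c_ <- sum(yc * t_) / sum(t_^2)
    Xc <- Xc - outer(t_, p_)
    yhat <- yhat + c_ * t_
    scores <- cbind(scores, t_)
  }
  list(scores = scores, yhat = yhat,
       r2y = 1 - sum((yc - yhat)^2) / sum(yc^2))
}

# population-sd column scaler used to evaluate the matrix-filter inequality
# independently of the package code
pop_sd_cols <- function(m) {
  apply(m, 2, function(v) sqrt(mean((v - mean(v))^2)))
}
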