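# Shared fixture builders. Panels for replicated experiments use a small
# intercross census and genome so many replicates fit in a test run; the
# full-scale defaults are exercised in the acceptance suite.

tiny_arms <- function(n_arm = 2, len_kb = 1000, len_cM = 20) {
  data.frame(arm = c("2L", "2R", "3L", "3R", "X")[seq_len(n_arm)],
             len_kb = len_kb, len_cM = len_cM, stringsAsFactors = FALSE)
}

tiny_grid <- function(n_arm = 2, len_kb = 1000, len_cM = 20, step_kb = 10) {
  genome_grid(tiny_arms(n_arm, len_kb, len_cM), step_kb)
}

quick_config <- function(n_ril = 100, grid = tiny_grid(), qtl = list(),
                         n_pairs = 200, seed = 1, ...) {
  sim_config(n_ril = n_ril, grid = grid, qtl = qtl, n_pairs = n_pairs,
             seed = seed, ...)
}

# 5v3 founder split (founders 6..8 resistant), the DCV major-QTL pattern
split_5v3 <- c(rep("susceptible", 5), rep("resistant", 3))

# Random founder-probability rows over k active founders, embedded in the
# 8-founder layout (remaining columns zero).
random_prob_rows <- function(n, k_founders = 4, ril_ids = sprintf("R%03d", 1:n)) {
  P <- matrix(0, n, 8, dimnames = list(ril_ids, NULL))
  raw <- matrix(runif(n * k_founders), n, k_founders)
  P[, seq_len(k_founders)] <- raw / rowSums(raw)
  P
}

# Independent least-squares oracle: RSS from the normal equations on an
# explicitly full-rank design built from the active founder columns.
oracle_lod <- function(y, P) {
  n <- length(y)
  active <- which(colSums(P) > 0)
  X1 <- cbind(1, P[, active[-1], drop = FALSE])
  b1 <- solve(crossprod(X1), crossprod(X1, y))
  rss1 <- sum((y - X1 %*% b1)^2)
  rss0 <- sum((y - mean(y))^2)
  (n / 2) * log10(rss0 / rss1)
}

# Brute-force best two-class split over every bipartition of the represented
# founders (not only ranked cuts).
oracle_best_bipartition_F <- function(y, f) {
  founders <- sort(unique(f))
  k <- length(founders)
  bestF <- -Inf
  for (code in 1:(2^k - 2)) {
    res <- founders[bitwAnd(code, 2^(seq_len(k) - 1)) > 0]
    g <- as.integer(f %in% res)
    Fv <- mprqtl:::one_way_F(y, g)
    if (Fv > bestF) bestF <- Fv
  }
  bestF
}

# Brute-force best ranked-cut split (direction "high")
oracle_best_ranked_F <- function(y, f, means) {
  founders <- sort(unique(f))
  ord <- founders[order(means[founders])]
  k <- length(ord)
  vapply(seq_len(k - 1), function(j) {
    mprqtl:::one_way_F(y, as.integer(f %in% ord[(j + 1):k]))
  }, numeric(1))
}
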