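# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# A small PBM training set with one planted 6-mer (CACGTG, palindromic),
# baseline 100, scale 1000, noise 5% of the per-occurrence signal.
fixture_sim <- function() {
  if (is.null(.fixtures$sim)) {
    truth <- list(features = c(CACGTG = 1), a = 100, c = 1000)
    .fixtures$sim <- simulate_pbm(truth, n_probes = 2000, noise_sd = 50,
                                  seed = 11)
  }
  .fixtures$sim
}

fixture_model <- function() {
  if (is.null(.fixtures$model))
    .fixtures$model <- train_pbm_model(fixture_sim()$probes, seed = 11)
  .fixtures$model
}

fixture_bmax <- function() {
  if (is.null(.fixtures$bmax))
    .fixtures$bmax <- estimate_bmax(fixture_model(), n = 20000, seed = 5)
  .fixtures$bmax
}

random_seqs <- function(n, L, seed) {
  withr::with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
}

# brute-force AUC oracle: count positive/negative pairs, ties as 1/2
auc_pair_oracle <- function(pos, neg) {
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# exhaustive two-stage grid search for the positive lasso (2 features):
# minimises ||y - a - X b||^2 + alpha * sum(b) over a non-negative grid,
# refining around the coarse optimum.
positive_lasso_grid_oracle <- function(X, y, alpha, upper = 5) {
  obj <- function(b1, b2) {
    r <- y - X[, 1] * b1 - X[, 2] * b2
    a <- mean(r)
    sum((r - a)^2) + alpha * (b1 + b2)
  }
  search <- function(g1, g2) {
    grid <- expand.grid(b1 = g1, b2 = g2)
    vals <- mapply(obj, grid$b1, grid$b2)
    grid[which.min(vals), ]
  }
  best <- search(seq(0, upper, by = 0.05), seq(0, upper, by = 0.05))
  for (h in c(0.05, 0.002, 1e-4)) {
    best <- search(pmax(seq(best$b1 - h, best$b1 + h, by = h / 25), 0),
                   pmax(seq(best$b2 - h, best$b2 + h, by = h / 25), 0))
  }
  b <- c(best$b1, best$b2)
  list(beta = b, intercept = mean(y - X %*% b))
}
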