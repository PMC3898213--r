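test_that("design matrix with uniform position effects equals occurrence counts", {
  seqs <- random_seqs(25, 36, 2)
  feats <- c("AAAA", "CACGTG", "CANNG")
  X <- as.matrix(build_design_matrix(seqs, feats))
  for (j in seq_along(feats))
    expect_equal(X[, j], as.numeric(count_occurrences(seqs, feats[j])))
})

test_that("design matrix weights occurrences by their start position", {
  lam <- c(2, rep(1, 35))
  # AAAA occurs once, at start position 1
  X <- as.matrix(build_design_matrix(paste0("AAAA", strrep("C", 32)),
                                     "AAAA", lam))
  expect_equal(X[1, 1], 2.0)
  # probe with no feature occurrence gives an all-zero row
  X0 <- build_design_matrix(strrep("G", 36), "AATA")
  expect_equal(sum(X0), 0)
  expect_error(build_design_matrix("ACGT", "ACGTA"), "longer than")
})

test_that("positive lasso handles degenerate inputs per contract", {
  X <- matrix(rpois(30, 2), 10, 3)
  fit <- fit_positive_lasso(X, rep(7, 10), alpha = 1)
  expect_equal(fit$beta, rep(0, 3))
  expect_equal(fit$intercept, 7)
  y <- X %*% c(1, 2, 0) + 5
  big <- fit_positive_lasso(X, as.numeric(y), alpha = 1e9)
  expect_equal(big$beta, rep(0, 3))
  expect_error(fit_positive_lasso(X, c(rep(1, 9), NaN), 1), "non-finite")
})

test_that("unpenalised single-feature fit matches the least-squares oracle", {
  x <- c(0, 1, 2)
  y <- 3 + 2 * x
  fit <- fit_positive_lasso(matrix(x, ncol = 1), y, alpha = 0)
  # closed form: slope cov(x,y)/var(x) = 2, intercept 3
  expect_equal(fit$beta, 2, tolerance = 1e-8)
  expect_equal(fit$intercept, 3, tolerance = 1e-8)
})

test_that("positive lasso matches a brute-force grid search", {
  withr::with_seed(9, {
    X <- matrix(rpois(50, 2), 25, 2)
    y <- as.numeric(4 + X %*% c(1.5, 0.7) + rnorm(25, 0, 0.3))
  })
  for (alpha in c(0.5, 4, 20)) {
    fit <- fit_positive_lasso(X, y, alpha)
    oracle <- positive_lasso_grid_oracle(X, y, alpha)
    expect_equal(fit$beta, oracle$beta, tolerance = 1e-4)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-3)
  }
})

test_that("sparsity is non-increasing in the penalty", {
  sim <- fixture_sim()
  seqs <- sim$probes$sequence[1:400]
  y <- sim$probes$intensity[1:400]
  X <- build_design_matrix(seqs, enumerate_features(4, 5))
  nnz <- vapply(c(10, 100, 1000, 10000, 1e5),
                function(a) sum(fit_positive_lasso(X, y, a)$beta > 0),
                numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("position effects are recovered from simulated data", {
  # a 4-mer occurs often enough (~0.26 per probe) to resolve per-position
  # structure at a few thousand probes
  truth_u <- list(features = c(ACGG = 1), a = 0, c = 100, lambda = NULL)
  sim_u <- simulate_pbm(truth_u, 3000, noise_sd = 1, seed = 21)
  lam_u <- estimate_position_effects(sim_u$probes$sequence,
                                     sim_u$probes$intensity,
                                     "ACGG", 100, 0)[["4"]]
  expect_length(lam_u, 33)
  expect_equal(mean(lam_u), 1, tolerance = 1e-8)
  expect_true(all(abs(lam_u - 1) < 0.1))

  lam_true <- seq(1.5, 0.5, length.out = 33)
  truth_d <- list(features = c(ACGG = 1), a = 0, c = 100,
                  lambda = lam_true)
  sim_d <- simulate_pbm(truth_d, 5000, noise_sd = 1, seed = 22)
  lam_d <- estimate_position_effects(sim_d$probes$sequence,
                                     sim_d$probes$intensity,
                                     "ACGG", 100, 0)[["4"]]
  expect_gt(cor(lam_d, lam_true, method = "spearman"), 0.9)
})

test_that("position effects fall back to uniform for degenerate inputs", {
  seqs <- random_seqs(150, 36, 5)
  y <- rnorm(150)
  uniform <- list(`4` = rep(1, 33))
  expect_equal(estimate_position_effects(seqs, y, "AAAA", 0, 0), uniform)
  expect_warning(
    lam <- estimate_position_effects(seqs[1:50], y[1:50], "AAAA", 1, 0),
    "fewer than 100")
  expect_equal(lam, uniform)
})

test_that("training recovers a planted motif with the top normalised coefficient", {
  m <- fixture_model()
  expect_identical(m$features[which.max(m$beta_norm)], "CACGTG")
  expect_equal(max(m$beta_norm), 1)
  expect_true(all(m$beta >= 0))
})

test_that("training is deterministic: identical serialization for identical inputs", {
  sim <- fixture_sim()
  probes <- sim$probes[1:500, ]
  m1 <- train_pbm_model(probes, seed = 4)
  m2 <- train_pbm_model(probes, seed = 4)
  f1 <- tempfile(); f2 <- tempfile()
  write_kmer_model(m1, f1); write_kmer_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(paste0(f1, ".json")),
                   readLines(paste0(f2, ".json")))
})

test_that("model serialization round-trips", {
  m <- fixture_model()
  f <- tempfile()
  write_kmer_model(m, f)
  back <- read_kmer_model(f)
  keep <- m$beta > 0
  expect_equal(sort(back$features), sort(m$features[keep]))
  expect_equal(back$beta[match(m$features[keep], back$features)],
               m$beta[keep], tolerance = 1e-9)
  expect_equal(back$lambda, m$lambda, tolerance = 1e-12)
})

test_that("training on reverse-complemented probes yields the same canonical model", {
  sim <- fixture_sim()
  probes <- sim$probes[1:500, ]
  flipped <- probes
  flipped$sequence <- revcomp(probes$sequence)
  m1 <- train_pbm_model(probes, seed = 4)
  m2 <- train_pbm_model(flipped, seed = 4)
  expect_identical(m1$features, m2$features)
  expect_equal(m1$beta, m2$beta, tolerance = 1e-6)
})

test_that("identical intensities give an empty model with a warning", {
  sim <- fixture_sim()
  probes <- sim$probes[1:200, ]
  probes$intensity <- 5
  expect_warning(m <- train_pbm_model(probes), "identical")
  expect_true(all(m$beta == 0))
  expect_error(train_pbm_model(sim$probes[1:50, ]), "100 probes")
})
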