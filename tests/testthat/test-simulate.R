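test_that("noiseless probes without the motif read exactly the baseline", {
  truth <- list(features = c(CACGTG = 1), a = 100, c = 1000)
  sim <- simulate_pbm(truth, 500, noise_sd = 0, seed = 2)
  no_motif <- count_occurrences(sim$probes$sequence, "CACGTG") == 0
  expect_gt(sum(no_motif), 0)
  expect_true(all(sim$probes$intensity[no_motif] == 100))
  expect_error(simulate_pbm(truth, 10, noise_sd = -1), "non-negative")
})

test_that("generators are pure functions of parameters and seed", {
  truth <- list(features = c(CACGTG = 1), a = 100, c = 1000)
  s1 <- simulate_pbm(truth, 200, 25, seed = 9)
  s2 <- simulate_pbm(truth, 200, 25, seed = 9)
  expect_identical(s1$probes, s2$probes)
  g1 <- simulate_genome(truth, 20000, 10, seed = 3)
  g2 <- simulate_genome(truth, 20000, 10, seed = 3)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$sites, g2$sites)
  p1 <- simulate_peaks(g1$sites, 20, 20000, seed = 4)
  p2 <- simulate_peaks(g1$sites, 20, 20000, seed = 4)
  expect_identical(p1, p2)
})

test_that("mean intensity matches the analytic expectation of the linear model", {
  # non-palindromic 6-mer: 2 of 4^6 window strings match per position
  truth <- list(features = setNames(1, canonicalize("ACGTAC")), a = 50,
                c = 1000)
  sim <- simulate_pbm(truth, 10000, noise_sd = 20, seed = 31)
  e_f <- 31 * 2 / 4^6
  expected <- 50 + 1000 * e_f
  se <- sd(sim$probes$intensity) / sqrt(10000)
  expect_lt(abs(mean(sim$probes$intensity) - expected), 3 * se)
})

test_that("planted genome sites are spaced, recorded, and high-scoring", {
  m <- fixture_model()
  bm <- fixture_bmax()
  truth <- list(features = c(CACGTG = 1))
  gen <- simulate_genome(truth, 30000, 40, seed = 8)
  expect_identical(nrow(gen$sites), 40L)
  # non-overlapping by construction
  expect_true(all(diff(gen$sites$start) >= 36))
  cutoff <- high_score_threshold(m, bm, n_samples = 20000, seed = 2)
  win <- substring(gen$genome, gen$sites$start + 1, gen$sites$end)
  B <- pmin(tfpipes:::score_raw(m, win) / bm$value, 1)
  expect_true(all(B > cutoff))
  empty <- simulate_genome(truth, 20000, 0, seed = 8)
  expect_identical(nrow(empty$sites), 0L)
})

test_that("tissue tracks draw counts from the assigned mixture component", {
  sites <- data.frame(chrom = "chrS", start = seq(0, by = 36,
                                                  length.out = 2000))
  sites$end <- sites$start + 36
  closed_only <- simulate_tissue_tracks(sites, n_tissues = 1, open_prob = 0,
                                        seed = 5)
  cc <- site_tag_density(closed_only$tracks[[1]], sites)
  expect_lt(mean(cc), 3)
  sim <- simulate_tissue_tracks(sites, n_tissues = 2, open_prob = 0.3,
                                seed = 6)
  counts <- site_tag_density(sim$tracks[[1]], sites)
  open <- sim$labels[, 1]
  expect_lt(abs(mean(counts[open]) - 40) / 40, 0.1)
  expect_lt(mean(counts[!open]), 3)
  expect_identical(dim(sim$labels), c(2000L, 2L))
})

test_that("conservation tracks are elevated at true sites", {
  sites <- data.frame(chrom = "chrS", start = seq(0, by = 36,
                                                  length.out = 1000))
  sites$end <- sites$start + 36
  truth_flag <- seq_len(1000) <= 100
  sim <- simulate_tissue_tracks(sites, true_sites = truth_flag, seed = 7)
  s <- vapply(seq_len(1000), function(i)
    track_mean(sim$conservation, "chrS", sites$start[i], sites$end[i]),
    numeric(1))
  expect_gt(mean(s[truth_flag]), 0.6)   # Beta(5,2), mean 5/7
  expect_lt(mean(s[!truth_flag]), 0.4)  # Beta(2,5), mean 2/7
  expect_true(all(s >= 0 & s <= 1))
})

test_that("peak simulation ranks planted sites above decoys", {
  truth <- list(features = c(CACGTG = 1))
  gen <- simulate_genome(truth, 50000, 25, seed = 10)
  pk0 <- simulate_peaks(gen$sites, 0, 50000, seed = 11)
  expect_identical(pk0$start, gen$sites$start)
  pk <- simulate_peaks(gen$sites, 100, 50000, seed = 11)
  ord <- order(-pk$score)
  expect_true(all(pk$is_true[ord[1:25]]))
})

test_that("the full pipeline separates true sites from background", {
  m <- fixture_model()
  bm <- fixture_bmax()
  truth <- list(features = c(CACGTG = 1))
  gen <- simulate_genome(truth, 80000, 60, seed = 21)
  sites <- tfpipes:::tile_sites(data.frame(chrom = "chrS", start = 0,
                                           end = 80000))
  is_true <- sites$start %in% gen$sites$start
  sim <- simulate_tissue_tracks(sites, n_tissues = 1,
                                open_prob = ifelse(is_true, 0.9, 0.08),
                                true_sites = is_true, seed = 22)
  win <- substring(gen$genome, sites$start + 1, sites$end)
  B <- pmin(tfpipes:::score_raw(m, win) / bm$value, 1)
  counts <- site_tag_density(sim$tracks[[1]], sites)
  mix <- fit_chromatin_mixture(counts, seed = 23)
  X <- occupancy(B, prob_open(mix, counts))
  S <- vapply(seq_len(nrow(sites)), function(i)
    track_mean(sim$conservation, "chrS", sites$start[i], sites$end[i]),
    numeric(1))
  pm <- fit_pipes(X, S, seed = 24)
  post <- posterior_binding(pm, X, S)
  expect_gt(compute_auc(post[is_true], post[!is_true]), 0.9)
})
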