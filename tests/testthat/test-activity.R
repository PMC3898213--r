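test_that("the high-score cutoff is the order-statistic at the top 0.1%", {
  expect_equal(tfpipes:::score_cutoff((1:1000) / 1000, 0.001), 0.999)
  expect_warning(cut1 <- tfpipes:::score_cutoff(rep(0.4, 100)), "identical")
  expect_equal(cut1, 0.4)
  m <- fixture_model()
  bm <- fixture_bmax()
  c1 <- high_score_threshold(m, bm, n_samples = 5000, seed = 2)
  c2 <- high_score_threshold(m, bm, n_samples = 5000, seed = 2)
  expect_identical(c1, c2)
  degen <- tfpipes:::new_kmer_model("AAAA", 0, rep(1, 33), 0, 1, 4, 6, 0, 1)
  expect_error(high_score_threshold(degen, 1), "degenerate")
})

test_that("open sites use a strict density cutoff", {
  sites <- data.frame(chrom = "chr1", start = c(0, 36, 72),
                      end = c(36, 72, 108))
  tr <- function(vals) coverage_track(
    data.frame(chrom = "chr1", start = sites$start, end = sites$end,
               value = vals))
  open <- open_sites_per_tissue(list(a = tr(c(15, 16, 0)),
                                     b = tr(c(0, 0, 0))), sites)
  expect_identical(open$a, 2L)     # 15 is closed, 16 is open
  expect_length(open$b, 0)
  expect_error(open_sites_per_tissue(list(tr(c(1, 2, 3))), sites), "named")
})

test_that("ubiquitously open sites are excluded with a strict 1/3 rule", {
  mk_map <- function(n_open_tissues, n_tissues) {
    m <- c(lapply(seq_len(n_open_tissues), function(i) 1L),
           lapply(seq_len(n_tissues - n_open_tissues), function(i) integer(0)))
    names(m) <- paste0("t", seq_len(n_tissues))
    m
  }
  # open in 19 of 55 (> 1/3) -> removed everywhere
  f19 <- filter_ubiquitous(mk_map(19, 55))
  expect_true(all(lengths(f19) == 0))
  # open in 18 of 55 (<= 1/3) -> kept
  f18 <- filter_ubiquitous(mk_map(18, 55))
  expect_identical(f18$t1, 1L)
  # 1 of 3 is exactly 1/3, not more -> kept
  f13 <- filter_ubiquitous(mk_map(1, 3))
  expect_identical(f13$t1, 1L)
  expect_error(filter_ubiquitous(mk_map(1, 1)), "2 tissues")
})

test_that("activity scores follow the pseudocounted ratio", {
  # equal fractions in and out -> score ~ 1 (exactly 1 without pseudocounts)
  same <- activity_score(200, 1000, 2000, 10000)
  expect_equal(same$score, 1, tolerance = 1e-2)
  small <- activity_score(20, 100, 200, 1000)
  expect_equal(small$score, (21 / 102) / (201 / 1002), tolerance = 1e-12)
  only_in <- activity_score(20, 100, 0, 1000)
  expect_equal(only_in$score, (21 / 102) / (1 / 1002), tolerance = 1e-12)
  expect_gt(only_in$score, 100)
  none <- activity_score(0, 500, 0, 500)
  expect_equal(none$score, 1)
  expect_error(activity_score(0, 0, 0, 0), "undefined")
})

test_that("the binomial activity p-value is an exact upper tail", {
  expect_equal(activity_pvalue(10, 10, 0.5), 0.5^10)
  expect_equal(activity_pvalue(0, 17, 0.3), 1.0)
  # direct summation oracle for P(X >= 3), X ~ Bin(5, 0.2)
  direct <- sum(choose(5, 3:5) * 0.2^(3:5) * 0.8^(5 - (3:5)))
  expect_equal(activity_pvalue(3, 5, 0.2), direct, tolerance = 1e-12)
  expect_equal(round(direct, 5), 0.05792)
  expect_error(activity_pvalue(6, 5, 0.2), "x <= n")
  expect_error(activity_pvalue(1, 5, 0), "\\(0, 1\\)")
  # coherence: non-increasing in x
  pv <- vapply(0:20, function(x) activity_pvalue(x, 20, 0.3), numeric(1))
  expect_true(all(diff(pv) <= 0))
})

test_that("the activity matrix flags the enriched tissue and is symmetric under the null", {
  model <- fixture_model()
  truth <- list(features = c(CACGTG = 1))
  gen <- simulate_genome(truth, 60000, 120, seed = 3)
  sites <- tfpipes:::tile_sites(data.frame(chrom = "chrS", start = 0,
                                           end = 60000))
  planted <- sites$start %in% gen$sites$start
  # tissue A: planted sites preferentially open; B and C: random openness
  open_A <- ifelse(planted, 0.9, 0.05)
  sim <- simulate_tissue_tracks(sites, n_tissues = 3,
                                open_assignment = cbind(
                                  A = withr::with_seed(1, runif(nrow(sites)) < open_A),
                                  B = withr::with_seed(2, runif(nrow(sites)) < 0.1),
                                  C = withr::with_seed(3, runif(nrow(sites)) < 0.1)),
                                seed = 4)
  act <- activity_matrix(list(tf1 = model), sim$tracks,
                         data.frame(chrom = "chrS", start = 0, end = 60000),
                         gen$genome, bmax_samples = 5000, seed = 6)
  expect_identical(nrow(act), 3L)
  best <- act$tissue[act$is_max]
  expect_identical(best, "A")
  expect_gt(act$score[act$tissue == "A"],
            max(act$score[act$tissue != "A"]) * 2)
  expect_true(all(act$p_value >= 0 & act$p_value <= 1))
  expect_lt(act$p_value[act$tissue == "A"], 0.01)
})

test_that("an empty TF list yields an empty activity table", {
  act <- activity_matrix(list(), list(), data.frame(), c())
  expect_identical(nrow(act), 0L)
  expect_true(all(c("tf", "tissue", "score", "p_value") %in% names(act)))
})

test_that("two statistically identical tissues both score near 1", {
  model <- fixture_model()
  truth <- list(features = c(CACGTG = 1))
  gen <- simulate_genome(truth, 40000, 80, seed = 13)
  sim <- simulate_tissue_tracks(
    tfpipes:::tile_sites(data.frame(chrom = "chrS", start = 0, end = 40000)),
    n_tissues = 2, open_prob = 0.25, seed = 14)
  # with only 2 tissues the strict 1/3 ubiquity rule would discard every
  # open site, so the filter is disabled for this symmetry check
  act <- activity_matrix(list(tf1 = model), sim$tracks,
                         data.frame(chrom = "chrS", start = 0, end = 40000),
                         gen$genome, max_fraction = 1,
                         bmax_samples = 5000, seed = 15)
  expect_true(all(act$score > 0.4 & act$score < 2.5))
})
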