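#' High-score cutoff for a TF
#'
#' A site is called high-scoring for a TF when its binding probability
#' exceeds the top 0.1% of binding probabilities over all possible sites,
#' estimated from a large sample of random 36bp sequences.
#'
#' @param model a `kmer_binding_model` with nonzero coefficients.
#' @param bmax a `bmax_estimate` (or positive scalar).
#' @param n_samples number of random sites sampled (default 100000).
#' @param seed integer seed.
#' @param top_fraction upper tail mass defining "high-scoring"
#'   (default 0.001).
#' @return the binding-probability cutoff (99.9th percentile of sampled B).
#' @export
high_score_threshold <- function(model, bmax, n_samples = 100000L, seed = 1L,
                                 top_fraction = 0.001) {
  if (all(model$beta_norm == 0))
    stop("degenerate model: no nonzero coefficients")
  width <- if (inherits(bmax, "bmax_estimate")) bmax$width else 36L
  raw <- withr::with_seed(seed, score_raw(model, random_dna(n_samples, width)))
  score_cutoff(pmin(raw / bmax_value(bmax), 1), top_fraction)
}

## upper-tail cutoff: the (1 - top_fraction) quantile as an order statistic
score_cutoff <- function(B, top_fraction = 0.001) {
  cutoff <- stats::quantile(B, 1 - top_fraction, type = 1, names = FALSE)
  if (all(B == B[1L]))
    warning("all sampled scores identical; every site is high-scoring")
  cutoff
}

#' Open sites per tissue
#'
#' For each tissue, the subset of sites whose DNase tag density is
#' strictly greater than the cutoff (default 15, a density at which the
#' open-chromatin probability is close to 1).
#'
#' @param tracks named list of `coverage_track`, one per tissue.
#' @param sites `data.frame` with columns `chrom`, `start`, `end`.
#' @param density_cutoff strict lower bound on density (default 15).
#' @return named list of integer site indices, one per tissue.
#' @export
open_sites_per_tissue <- function(tracks, sites, density_cutoff = 15) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("tracks must be a named list, one coverage track per tissue")
  lapply(tracks, function(tr) {
    if (!inherits(tr, "coverage_track")) stop("missing track for a tissue")
    dens <- site_tag_density(tr, sites)
    which(dens > density_cutoff)
  })
}

#' Remove ubiquitously open sites
#'
#' Sites open in more than 1/3 of all tissues are not tissue specific and
#' are excluded from every tissue's open set before activity scoring.
#'
#' @param open_map named list of open-site index vectors per tissue.
#' @param n_tissues total number of tissues (default `length(open_map)`).
#' @param max_fraction exclusion bound (default 1/3; strict inequality).
#' @return filtered `open_map`.
#' @export
filter_ubiquitous <- function(open_map, n_tissues = length(open_map),
                              max_fraction = 1 / 3) {
  if (n_tissues < 2L) stop("need at least 2 tissues")
  counts <- table(unlist(open_map))
  ubiquitous <- as.integer(names(counts)[counts > n_tissues * max_fraction])
  lapply(open_map, function(idx) setdiff(idx, ubiquitous))
}

#' Tissue-activity score of a TF
#'
#' `Activity(f, T) = R(f, T) / R(f, T-bar)` where `R(f, T)` is the
#' fraction of tissue `T`'s DNase-open sites that contain a high-scoring
#' binding site of `f`, and `T-bar` pools all other tissues.  Laplace
#' pseudocounts `(x + 1) / (n + 2)` are applied to both fractions so the
#' ratio is always finite; the expected score is 1 for a TF with no
#' tissue preference.
#'
#' @param hits_in number of open sites in `T` containing a high-scoring
#'   site.
#' @param open_in number of open sites in `T`.
#' @param hits_out,open_out the same counts pooled over all other tissues.
#' @return list with `r_in`, `r_out` (pseudocounted fractions) and
#'   `score`.
#' @export
activity_score <- function(hits_in, open_in, hits_out, open_out) {
  stopifnot(hits_in >= 0, hits_out >= 0, open_in >= hits_in,
            open_out >= hits_out)
  if (open_in == 0 && open_out == 0)
    stop("no open sites in any tissue; activity score undefined")
  r_in <- (hits_in + 1) / (open_in + 2)
  r_out <- (hits_out + 1) / (open_out + 2)
  list(r_in = r_in, r_out = r_out, score = r_in / r_out)
}

#' One-sided binomial test for activity significance
#'
#' Upper-tail probability `P(X >= x)` for `X ~ Binomial(n, p)`: the chance
#' of observing at least `x` of the TF's `n` high-scoring sites in the
#' tissue's open regions when each falls there with the background rate
#' `p = R(f, T-bar)`.
#'
#' @param x observed successes (0..n).
#' @param n number of trials.
#' @param p null success probability in (0, 1).
#' @return the p-value.
#' @export
activity_pvalue <- function(x, n, p) {
  if (x < 0 || x > n || n < 0) stop("need 0 <= x <= n")
  if (p <= 0 || p >= 1) stop("null probability must lie in (0, 1)")
  stats::pbinom(x - 1, n, p, lower.tail = FALSE)
}

## non-overlapping 36bp tiling of regions
tile_sites <- function(regions, width = 36L) {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    starts <- seq.int(regions$start[i], by = width,
                      length.out = max(0L, (regions$end[i] - regions$start[i]) %/% width))
    if (length(starts) == 0L) return(NULL)
    data.frame(chrom = regions$chrom[i], start = starts,
               end = starts + width, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' TF-by-tissue activity matrix
#'
#' Tiles the analysed regions into non-overlapping 36bp sites, determines
#' each tissue's open (and non-ubiquitous) sites from its DNase track,
#' calls each TF's high-scoring sites from sequence, and computes the
#' activity score and binomial p-value for every (TF, tissue) pair.
#'
#' @param tf_models named list of `kmer_binding_model` objects.
#' @param tracks named list of `coverage_track`, one per tissue.
#' @param regions `data.frame` of regions to scan (`chrom`, `start`,
#'   `end`), e.g. promoter windows.
#' @param genome named character vector of chromosome sequences.
#' @param density_cutoff DNase openness cutoff (default 15).
#' @param top_fraction high-score tail (default 0.001).
#' @param max_fraction ubiquity bound (default 1/3).
#' @param bmax_samples sites sampled for `B_max` and the score cutoff.
#' @param seed integer seed.
#' @return `data.frame` with one row per (TF, tissue): `tf`, `tissue`,
#'   `score`, `r_in`, `r_out`, `x`, `n`, `p_null`, `p_value`, `is_max`
#'   (whether the tissue attains the TF's maximum score).
#' @export
activity_matrix <- function(tf_models, tracks, regions, genome,
                            density_cutoff = 15, top_fraction = 0.001,
                            max_fraction = 1 / 3, bmax_samples = 20000L,
                            seed = 1L) {
  if (length(tf_models) == 0L)
    return(data.frame(tf = character(0), tissue = character(0),
                      score = numeric(0), r_in = numeric(0),
                      r_out = numeric(0), x = integer(0), n = integer(0),
                      p_null = numeric(0), p_value = numeric(0),
                      is_max = logical(0)))
  sites <- tile_sites(regions)
  seqs <- substring(genome[sites$chrom], sites$start + 1L, sites$end)
  open_map <- filter_ubiquitous(
    open_sites_per_tissue(tracks, sites, density_cutoff),
    n_tissues = length(tracks), max_fraction = max_fraction)
  tissues <- names(tracks)
  rows <- list()
  for (tf in names(tf_models)) {
    model <- tf_models[[tf]]
    bmax <- estimate_bmax(model, n = bmax_samples, seed = seed)
    cutoff <- high_score_threshold(model, bmax, n_samples = bmax_samples,
                                   seed = seed + 1L,
                                   top_fraction = top_fraction)
    B <- pmin(score_raw(model, seqs) / bmax_value(bmax), 1)
    high <- which(B > cutoff)
    for (tis in tissues) {
      open_in <- open_map[[tis]]
      open_out <- unlist(open_map[setdiff(tissues, tis)], use.names = FALSE)
      x_in <- length(intersect(high, open_in))
      hits_out <- sum(open_out %in% high)   # pooled over other tissues
      sc <- activity_score(x_in, length(open_in), hits_out, length(open_out))
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, tissue = tis, score = sc$score, r_in = sc$r_in,
        r_out = sc$r_out, x = x_in, n = length(high), p_null = sc$r_out,
        p_value = activity_pvalue(x_in, length(high), sc$r_out),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$is_max <- stats::ave(out$score, out$tf, FUN = max) == out$score
  rownames(out) <- NULL
  out
}
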