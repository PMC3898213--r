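#' Simulate a PBM probe array from a planted k-mer model
#'
#' Generates uniform-random 36bp probe sequences and intensities from the
#' linear binding model: `Y = a + c * F + noise`, where `F` is the
#' position-weighted sum of the planted k-mer binding coefficients over
#' all probe windows.
#'
#' @param truth list describing the ground truth: `features` (named
#'   numeric vector of planted canonical k-mers and their true beta),
#'   optional `lambda` (position effects, default uniform), `a`
#'   (baseline intensity, default 100), `c` (intensity scale, default
#'   1000).
#' @param n_probes number of probes.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   intensity units (>= 0).
#' @param seed integer seed.
#' @param width probe variable-region length (default 36).
#' @return list with `probes` (a `data.frame` usable by
#'   [train_pbm_model()]) and `truth` (the generating parameters plus the
#'   seed).
#' @export
simulate_pbm <- function(truth, n_probes, noise_sd, seed = 1L, width = 36L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(!is.null(names(truth$features)))
  feats <- canonicalize(names(truth$features))
  beta <- as.numeric(truth$features)
  a <- truth$a %||% 100
  cc <- truth$c %||% 1000
  lambda <- truth$lambda
  withr::with_seed(seed, {
    seqs <- random_dna(n_probes, width)
    X <- build_design_matrix(seqs, feats, lambda)
    F_i <- as.numeric(X %*% beta)
    y <- a + cc * F_i + stats::rnorm(n_probes, 0, noise_sd)
    list(probes = data.frame(probe_id = sprintf("probe_%05d", seq_len(n_probes)),
                             sequence = seqs, intensity = y,
                             stringsAsFactors = FALSE),
         truth = list(features = stats::setNames(beta, feats),
                      lambda = lambda, a = a, c = cc,
                      noise_sd = noise_sd, seed = seed, F = F_i))
  })
}

#' Simulate a genome with planted binding sites
#'
#' Uniform-random background sequence with copies of the model's top
#' k-mer embedded at recorded, non-overlapping 36bp site windows.  Each
#' planted window carries `site_copies` occurrences of the motif so that
#' it scores well above the random-background score distribution.
#'
#' @param truth truth list as in [simulate_pbm()] (the feature with the
#'   largest beta is planted).
#' @param length genome length in bp (>= 10000).
#' @param n_planted_sites number of planted 36bp sites.
#' @param seed integer seed.
#' @param site_copies motif copies per planted window (default 3).
#' @param spacing minimum distance between slot starts in bp (default 72,
#'   guaranteeing non-overlapping 36bp windows).
#' @param chrom chromosome name (default "chrS").
#' @return list with `genome` (named character vector of length 1) and
#'   `sites` (truth `data.frame`: `chrom`, `start`, `end` of each planted
#'   36bp window).
#' @export
simulate_genome <- function(truth, length, n_planted_sites, seed = 1L,
                            site_copies = 3L, spacing = 72L, chrom = "chrS") {
  if (length < 10000L) stop("genome length must be >= 10000")
  if (spacing < 72L) stop("spacing below 72 would allow overlapping sites")
  motif <- names(truth$features)[which.max(truth$features)]
  k <- nchar(motif)
  if (site_copies * k > 36L) stop("too many motif copies for a 36bp site")
  withr::with_seed(seed, {
    n_slots <- length %/% spacing  # candidate non-overlapping 36bp slots
    if (n_planted_sites > n_slots)
      stop("too many planted sites for the genome length")
    seq_chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    slot <- sort(sample.int(n_slots, n_planted_sites))
    starts0 <- (slot - 1L) * spacing      # 0-based window starts
    offsets <- seq(1L, by = k + 2L, length.out = site_copies)
    motif_chars <- strsplit(motif, "")[[1L]]
    for (s in starts0) {
      for (o in offsets) {
        idx <- s + o + seq_len(k) - 1L    # 1-based positions in seq_chars
        seq_chars[idx] <- motif_chars
      }
    }
    genome <- stats::setNames(paste(seq_chars, collapse = ""), chrom)
    sites <- data.frame(chrom = rep(chrom, length(starts0)),
                        start = starts0, end = starts0 + 36L,
                        stringsAsFactors = FALSE)
    list(genome = genome, sites = sites, motif = motif, seed = seed)
  })
}

#' Simulate per-tissue DNase tracks and a conservation track
#'
#' For each tissue, tag counts over the given 36bp sites are drawn from
#' the open negative-binomial component at sites assigned open and from
#' the closed component elsewhere.  A conservation track is drawn
#' Beta(5, 2) at true binding sites and Beta(2, 5) elsewhere.
#'
#' @param sites `data.frame` of 36bp site windows (`chrom`, `start`,
#'   `end`).
#' @param n_tissues number of tissues.
#' @param open_assignment logical matrix `n_sites x n_tissues`, or `NULL`
#'   to draw assignments from `open_prob`.
#' @param open_prob per-site probability of being open in a tissue; a
#'   scalar, or a vector of length `n_sites` (e.g. higher at true sites).
#' @param mixture_params list with `mean_closed`, `mean_open`, `size`
#'   (shared NB dispersion); defaults 1, 40, 5.
#' @param true_sites logical vector marking true binding sites (for the
#'   conservation track); default all `FALSE`.
#' @param cons_true,cons_bg Beta parameters of the conservation score at
#'   true sites and background (defaults `c(5, 2)` and `c(2, 5)`).
#' @param seed integer seed.
#' @return list with `tracks` (named list of `coverage_track`), `labels`
#'   (the open-assignment matrix), `conservation` (a `coverage_track`)
#'   and `truth` (generating parameters).
#' @export
simulate_tissue_tracks <- function(sites, n_tissues = 1L,
                                   open_assignment = NULL, open_prob = 0.1,
                                   mixture_params = list(mean_closed = 1,
                                                         mean_open = 40,
                                                         size = 5),
                                   true_sites = NULL,
                                   cons_true = c(5, 2), cons_bg = c(2, 5),
                                   seed = 1L) {
  n <- nrow(sites)
  if (is.null(true_sites)) true_sites <- rep(FALSE, n)
  withr::with_seed(seed, {
    if (is.null(open_assignment)) {
      p <- rep_len(open_prob, n)
      open_assignment <- matrix(stats::runif(n * n_tissues) <
                                  rep(p, n_tissues), n, n_tissues)
    }
    if (is.null(colnames(open_assignment)))
      colnames(open_assignment) <- sprintf("tissue_%02d", seq_len(n_tissues))
    tracks <- lapply(seq_len(n_tissues), function(t) {
      open <- open_assignment[, t]
      counts <- ifelse(open,
                       stats::rnbinom(n, mu = mixture_params$mean_open,
                                      size = mixture_params$size),
                       stats::rnbinom(n, mu = mixture_params$mean_closed,
                                      size = mixture_params$size))
      coverage_track(data.frame(chrom = sites$chrom, start = sites$start,
                                end = sites$end, value = counts,
                                stringsAsFactors = FALSE))
    })
    names(tracks) <- colnames(open_assignment)
    cons_val <- ifelse(true_sites,
                       stats::rbeta(n, cons_true[1], cons_true[2]),
                       stats::rbeta(n, cons_bg[1], cons_bg[2]))
    conservation <- coverage_track(
      data.frame(chrom = sites$chrom, start = sites$start, end = sites$end,
                 value = cons_val, stringsAsFactors = FALSE))
    list(tracks = tracks, labels = open_assignment,
         conservation = conservation,
         truth = list(mixture_params = mixture_params,
                      open_prob = open_prob, seed = seed))
  })
}

#' Simulate a ChIP-seq peak list
#'
#' Peaks at the planted site windows receive high enrichment scores;
#' `n_decoys` decoy peaks at random non-overlapping coordinates receive
#' strictly lower scores.
#'
#' @param sites truth site `data.frame` (`chrom`, `start`, `end`).
#' @param n_decoys number of decoy peaks.
#' @param genome_length chromosome length (for decoy placement).
#' @param seed integer seed.
#' @return `data.frame` with `chrom`, `start`, `end`, `score`, `is_true`.
#' @export
simulate_peaks <- function(sites, n_decoys, genome_length, seed = 1L) {
  withr::with_seed(seed, {
    n <- nrow(sites)
    true_peaks <- data.frame(chrom = sites$chrom, start = sites$start,
                             end = sites$end,
                             score = stats::runif(n, 10, 20),
                             is_true = TRUE, stringsAsFactors = FALSE)
    if (n_decoys > 0L) {
      pos <- sample.int(genome_length - 36L, n_decoys)
      decoys <- data.frame(chrom = sites$chrom[1L], start = pos,
                           end = pos + 36L,
                           score = stats::runif(n_decoys, 1, 5),
                           is_true = FALSE, stringsAsFactors = FALSE)
      out <- rbind(true_peaks, decoys)
    } else out <- true_peaks
    rownames(out) <- NULL
    out
  })
}

#' Null calibration of the tissue-activity score
#'
#' Simulates a TF with no tissue preference: each of its high-scoring
#' sites falls into each tissue's DNase-open set independently with the
#' same probability, landing on a uniformly chosen open site.  For each
#' replicate the activity score of one tissue (open sites containing a
#' hit, versus the pool of all other tissues) is computed with the
#' Laplace pseudocount rule.  The expected score is 1.
#'
#' @param n_tissues number of tissues (default 10).
#' @param n_open open sites per tissue (default 1000).
#' @param n_sites high-scoring TF sites (default 500).
#' @param p probability that a site falls into a given tissue's open set
#'   (default 0.2), identical across tissues (the null).
#' @param reps number of replicates (default 1000).
#' @param seed integer seed.
#' @return numeric vector of `reps` activity scores.
#' @export
simulate_null_activity <- function(n_tissues = 10L, n_open = 1000L,
                                   n_sites = 500L, p = 0.2, reps = 1000L,
                                   seed = 1L) {
  withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      # per tissue: number of distinct open sites containing >= 1 TF site
      occupied <- vapply(seq_len(n_tissues), function(t) {
        hits <- stats::rbinom(1L, n_sites, p)
        length(unique(sample.int(n_open, hits, replace = TRUE)))
      }, integer(1))
      sc <- activity_score(occupied[1L], n_open,
                           sum(occupied[-1L]), n_open * (n_tissues - 1L))
      sc$score
    }, numeric(1))
  })
}
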