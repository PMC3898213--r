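## Raw (unscaled) binding scores of 36bp sites: sum over nonzero-beta'
## features of beta'_s * count of s in the site.  Vectorised over sites.
score_raw <- function(model, seqs, chunk = 20000L) {
  stopifnot(inherits(model, "kmer_binding_model"))
  act <- which(model$beta_norm > 0)
  if (length(act) == 0L) return(numeric(length(seqs)))
  out <- numeric(length(seqs))
  for (lo in seq(1L, length(seqs), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(seqs))
    X <- build_design_matrix(seqs[lo:hi], model$features[act])
    out[lo:hi] <- as.numeric(X %*% model$beta_norm[act])
  }
  out
}

## Uniform random DNA sequences of a given length.
random_dna <- function(n, width) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Estimate the binding-score normaliser B_max
#'
#' Samples `n` random 36bp sites and records the highest unscaled binding
#' score; every site score is later divided by this constant so that
#' binding probabilities lie in `[0, 1]`.
#'
#' @param model a fitted `kmer_binding_model` with at least one nonzero
#'   coefficient (a degenerate model yields `B_max = 1` with a warning).
#' @param n number of sampled sites (default 100000).
#' @param seed integer seed.
#' @param width site width (default 36, the PBM variable-region length).
#' @return object of class `bmax_estimate` with elements `value`,
#'   `n_samples`, `seed`, `width`.
#' @export
estimate_bmax <- function(model, n = 100000L, seed = 1L, width = 36L) {
  if (all(model$beta_norm == 0)) {
    warning("model has no nonzero coefficients; B_max set to 1")
    return(structure(list(value = 1, n_samples = n, seed = seed,
                          width = width), class = "bmax_estimate"))
  }
  raw <- withr::with_seed(seed, score_raw(model, random_dna(n, width)))
  structure(list(value = max(raw), n_samples = n, seed = seed,
                 width = width), class = "bmax_estimate")
}

#' @export
print.bmax_estimate <- function(x, ...) {
  cat(sprintf("B_max = %.6g (max unscaled score over %d random %dbp sites, seed %d)\n",
              x$value, x$n_samples, x$width, x$seed))
  invisible(x)
}

#' Score a single 36bp site
#'
#' The binding probability of a site is its unscaled k-mer score divided
#' by `B_max`, clipped at 1 (sampling can underestimate the true maximum).
#'
#' @param model a `kmer_binding_model`.
#' @param bmax a `bmax_estimate` (or a positive number).
#' @param site_seq DNA string whose length equals the model site width.
#' @return list with `raw` and `B` (in `[0, 1]`).
#' @export
score_site <- function(model, bmax, site_seq) {
  width <- if (inherits(bmax, "bmax_estimate")) bmax$width else 36L
  if (nchar(site_seq) != width)
    stop("site sequence must have length ", width)
  raw <- score_raw(model, site_seq)
  list(raw = raw, B = min(raw / bmax_value(bmax), 1))
}

bmax_value <- function(bmax) {
  if (inherits(bmax, "bmax_estimate")) bmax$value else as.numeric(bmax)
}

#' Score a sequence by its best 36bp window
#'
#' Slides a 36bp window (step 1 by default) over the sequence, scores each
#' window, and reports the maximum binding probability together with the
#' per-window profile.
#'
#' @param model a `kmer_binding_model`.
#' @param bmax a `bmax_estimate`.
#' @param seq DNA string of length >= the site width.
#' @param step window step in bp (default 1: every overlapping window).
#' @return list with `B` (max over windows) and `profile`, a `data.frame`
#'   with columns `offset` (0-based window start), `raw`, `B`.
#' @export
score_sequence <- function(model, bmax, seq, step = 1L) {
  width <- if (inherits(bmax, "bmax_estimate")) bmax$width else 36L
  L <- nchar(seq)
  if (L < width) stop("sequence shorter than site width ", width)
  starts <- seq.int(1L, L - width + 1L, by = step)
  wins <- substring(seq, starts, starts + width - 1L)
  raw <- score_raw(model, wins)
  B <- pmin(raw / bmax_value(bmax), 1)
  list(B = max(B),
       profile = data.frame(offset = starts - 1L, raw = raw, B = B))
}

#' Max-window binding probability for many sequences
#'
#' Vectorised form of [score_sequence()] returning only the maximum
#' window binding probability per sequence (the evaluation-harness hot
#' path).  Sequences may differ in length.
#'
#' @param model a `kmer_binding_model`.
#' @param bmax a `bmax_estimate` (or positive scalar).
#' @param seqs character vector of DNA sequences.
#' @param step window step in bp.
#' @return numeric vector of binding probabilities in `[0, 1]`.
#' @export
score_sequences_max <- function(model, bmax, seqs, step = 1L) {
  width <- if (inherits(bmax, "bmax_estimate")) bmax$width else 36L
  out <- numeric(length(seqs))
  for (L in unique(nchar(seqs))) {
    if (L < width) stop("sequence shorter than site width ", width)
    idx <- which(nchar(seqs) == L)
    starts <- seq.int(1L, L - width + 1L, by = step)
    wins <- unlist(lapply(starts, function(s)
      substr(seqs[idx], s, s + width - 1L)))
    raw <- matrix(score_raw(model, wins), nrow = length(idx))
    out[idx] <- pmin(apply(raw, 1L, max) / bmax_value(bmax), 1)
  }
  out
}
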