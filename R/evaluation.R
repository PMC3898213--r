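#' Build the bound (positive) sequence set from ChIP-seq peaks
#'
#' Takes the `n_top` peaks with the highest enrichment score (ties broken
#' by coordinate) and replaces each by the `width`-bp window centred on
#' the peak midpoint (or on `start + summit` when a `summit` column is
#' present).  Windows extending past a chromosome end are discarded with
#' a warning.
#'
#' @param peaks `data.frame` with `chrom`, `start`, `end`, `score`
#'   (enrichment) and optional `summit` (offset from `start`).
#' @param genome named character vector of chromosome sequences.
#' @param n_top number of peaks used (default 3000).
#' @param width positive-sequence width (default 600).
#' @return `data.frame` with `chrom`, `start`, `end`, `sequence`.
#' @export
build_positive_set <- function(peaks, genome, n_top = 3000L, width = 600L) {
  if (!"score" %in% names(peaks))
    stop("peaks must carry an enrichment score column")
  if (nrow(peaks) < n_top)
    warning("fewer peaks (", nrow(peaks), ") than n_top (", n_top,
            "); using all")
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  top <- peaks[ord[seq_len(min(n_top, nrow(peaks)))], , drop = FALSE]
  center <- if ("summit" %in% names(top)) top$start + top$summit else
    (top$start + top$end) %/% 2
  start <- center - width %/% 2
  end <- start + width
  chrom_len <- nchar(genome)[top$chrom]
  keep <- start >= 0 & end <= chrom_len & top$chrom %in% names(genome)
  if (any(!keep))
    warning(sum(!keep), " peak(s) too close to a chromosome end; discarded")
  out <- data.frame(chrom = top$chrom[keep], start = start[keep],
                    end = end[keep], stringsAsFactors = FALSE)
  out$sequence <- substring(genome[out$chrom], out$start + 1L, out$end)
  rownames(out) <- NULL
  out
}

#' Build the unbound (negative) sequence set
#'
#' For each positive window `[s, s + width)` the candidate negative is the
#' same-width window upstream of it, separated by a `gap`:
#' `[s - gap - width, s - gap)`.  Candidates extending past the chromosome
#' start or overlapping any positive window are dropped.
#'
#' @param positives output of [build_positive_set()].
#' @param genome named character vector of chromosome sequences.
#' @param gap separation from the positive window (default 300).
#' @return `data.frame` with `chrom`, `start`, `end`, `sequence`.
#' @export
build_negative_set <- function(positives, genome, gap = 300L) {
  width <- positives$end[1L] - positives$start[1L]
  start <- positives$start - gap - width
  end <- positives$start - gap
  keep <- start >= 0
  # drop candidates overlapping any positive window
  for (i in which(keep)) {
    same <- positives$chrom == positives$chrom[i]
    if (any(start[i] < positives$end[same] & end[i] > positives$start[same]))
      keep[i] <- FALSE
  }
  out <- data.frame(chrom = positives$chrom[keep], start = start[keep],
                    end = end[keep], stringsAsFactors = FALSE)
  out$sequence <- substring(genome[out$chrom], out$start + 1L, out$end)
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a random positive outscores a
#' random negative, ties counted 1/2 (equivalently, the Mann-Whitney U
#' statistic divided by `n_pos * n_neg`).
#'
#' @param pos_scores,neg_scores numeric score vectors (non-empty).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L)
    stop("both score sets must be non-empty")
  if (any(is.na(c(pos_scores, neg_scores))))
    stop("NA scores are not allowed")
  r <- rank(c(pos_scores, neg_scores))
  np <- length(pos_scores); nn <- length(neg_scores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate scoring methods on a bound/unbound sequence set
#'
#' Applies each scorer to the positive and negative sequences and reports
#' one AUC per method.  A scorer is a function taking a `data.frame` of
#' sequences (columns `chrom`, `start`, `end`, `sequence`) and returning
#' one numeric score per row.  A scorer that fails is recorded as `NA`
#' and the run continues.
#'
#' @param positives,negatives sequence sets from [build_positive_set()]
#'   and [build_negative_set()].
#' @param scorers named list of scoring functions.
#' @return `data.frame` with columns `method`, `auc`, `n_pos`, `n_neg`.
#' @export
evaluate_methods <- function(positives, negatives, scorers) {
  stopifnot(length(scorers) > 0L, !is.null(names(scorers)))
  rows <- lapply(names(scorers), function(m) {
    auc <- tryCatch({
      ps <- scorers[[m]](positives)
      ns <- scorers[[m]](negatives)
      compute_auc(ps, ns)
    }, error = function(e) {
      warning("scorer '", m, "' failed: ", conditionMessage(e))
      NA_real_
    })
    data.frame(method = m, auc = auc, n_pos = nrow(positives),
               n_neg = nrow(negatives), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
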