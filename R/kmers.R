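#' Reverse complement of DNA patterns
#'
#' Vectorised reverse complement over the extended alphabet `{A,C,G,T,N}`,
#' where `N` (a gap/wildcard position in gapped k-mers) is its own complement.
#'
#' @param x character vector of patterns over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTTG", "ANT"))
revcomp <- function(x) {
  stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' Canonical form of a k-mer pattern
#'
#' Transcription-factor binding is strand symmetric, so a k-mer and its
#' reverse complement share one binding coefficient.  The canonical
#' representative is the lexicographically smaller of the pattern and its
#' reverse complement (`N` complements to `N`).  Idempotent.
#'
#' @param pattern character vector over `{A,C,G,T,N}`.
#' @return character vector of canonical patterns.
#' @export
#' @examples
#' canonicalize("TTTG")   # "CAAA"
#' canonicalize("ACGT")   # palindromic, unchanged
canonicalize <- function(pattern) {
  if (length(pattern) == 0L) return(character(0))
  if (any(is.na(pattern) | !nzchar(pattern)))
    stop("empty pattern cannot be canonicalized")
  bad <- grepl("[^ACGTN]", pattern)
  if (any(bad))
    stop("pattern contains characters outside {A,C,G,T,N}: ",
         pattern[which(bad)[1L]])
  if (any(!grepl("[ACGT]", pattern)))
    stop("pattern consisting only of N cannot be canonicalized")
  rc <- revcomp(pattern)
  ifelse(rc < pattern, rc, pattern)
}

#' Validate a k-mer feature pattern
#'
#' A feature must be canonical, have length between 1 and 8, and must not
#' begin or end with the wildcard `N` (a gap is only meaningful between two
#' anchored bases).
#'
#' @param pattern character vector of candidate feature patterns.
#' @return invisibly, the validated patterns.
#' @keywords internal
validate_features <- function(pattern) {
  k <- nchar(pattern)
  if (any(k < 1L | k > 8L))
    stop("feature length must be between 1 and 8")
  if (any(substr(pattern, 1L, 1L) == "N" | substr(pattern, k, k) == "N"))
    stop("feature patterns must not start or end with N")
  canon <- canonicalize(pattern)
  if (any(canon != pattern))
    stop("feature pattern is not in canonical form: ",
         pattern[which(canon != pattern)[1L]])
  invisible(pattern)
}

#' Enumerate all canonical ungapped k-mers
#'
#' @param k_min,k_max integer k range (1--8).  The initial model round uses
#'   4--6; longer k-mers enter only through [extend_features()].
#' @return character vector of canonical patterns, sorted within each k.
#' @export
#' @examples
#' length(enumerate_features(4, 4))  # 136 canonical 4-mers
enumerate_features <- function(k_min, k_max) {
  if (k_max > 8L) stop("k-mers longer than 8 are not supported (model cap)")
  if (k_min < 1L || k_min > k_max) stop("need 1 <= k_min <= k_max")
  out <- character(0)
  for (k in seq(k_min, k_max)) {
    mers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                        stringsAsFactors = FALSE))
    out <- c(out, sort(unique(canonicalize(mers))))
  }
  out
}

## Extract all k-length windows of a set of equal-length sequences as an
## n x (L-k+1) character matrix (column j = window starting at j).
kmer_window_matrix <- function(seqs, k) {
  L <- nchar(seqs[1L])
  n_pos <- L - k + 1L
  vapply(seq_len(n_pos),
         function(j) substr(seqs, j, j + k - 1L),
         character(length(seqs)))
}

## Does window w (ungapped) match gapped canonical pattern p?
## Regex with N -> . on the window or its reverse complement.
gapped_regex <- function(pattern) {
  paste0("^", gsub("N", ".", pattern), "$")
}

#' Count occurrences of a k-mer feature in a sequence
#'
#' Counts positions `j` where the window `seq[j..j+k-1]`, read on either
#' strand, matches the canonical feature pattern; `N` in the pattern matches
#' any base.  Overlapping occurrences all count.
#'
#' @param seq character vector of DNA sequences over `{A,C,G,T}`.
#' @param feature a single canonical feature pattern.
#' @return integer vector of counts, one per sequence.
#' @export
#' @examples
#' count_occurrences("AAAA", "AA")   # 3
#' count_occurrences("TTTT", "AA")   # 3: TT canonicalizes to AA
count_occurrences <- function(seq, feature) {
  stopifnot(length(feature) == 1L)
  validate_features(feature)
  k <- nchar(feature)
  n <- length(seq)
  counts <- integer(n)
  long <- nchar(seq) >= k
  if (!any(long)) return(counts)
  # pad short sequences so the window matrix stays rectangular per group
  for (L in unique(nchar(seq[long]))) {
    idx <- which(nchar(seq) == L)
    win <- kmer_window_matrix(seq[idx], k)
    if (grepl("N", feature, fixed = TRUE)) {
      rx <- gapped_regex(feature)
      hit <- grepl(rx, win) | grepl(rx, revcomp(win))
    } else {
      hit <- canonicalize(c(win)) == feature
    }
    counts[idx] <- as.integer(rowSums(matrix(hit, nrow = length(idx))))
  }
  counts
}

#' Merge overlapping top features into longer and gapped k-mers
#'
#' Implements the model's feature-growth step: among the `top_n` features
#' ranked by coefficient, every ordered pair of equal-length patterns
#' (each considered in both orientations) whose `(k-1)`-suffix equals the
#' other's `(k-1)`-prefix is merged into a `(k+1)`-mer.  Pairs are
#' additionally joined with 1--3 intervening `N` wildcard positions
#' (gapped k-mers).  All products are canonicalized and capped at total
#' length 8.
#'
#' @param features character vector of canonical patterns (candidates).
#' @param beta numeric coefficients aligned with `features`.
#' @param top_n number of top-ranked features considered (default 100).
#'   Ties at the cut are broken by lexicographic order of the pattern.
#' @param max_gap maximum number of `N` positions inserted in gapped joins.
#' @return character vector of new canonical feature patterns (possibly
#'   empty), excluding patterns already present in `features`.
#' @export
extend_features <- function(features, beta, top_n = 100L, max_gap = 3L) {
  stopifnot(length(features) == length(beta))
  keep <- beta > 0
  features <- features[keep]; beta <- beta[keep]
  if (length(features) == 0L) return(character(0))
  ord <- order(-beta, features)
  top <- features[ord][seq_len(min(top_n, length(features)))]

  # both orientations of every top pattern; merges between two distinct
  # source features only
  oriented <- c(top, revcomp(top))
  source_id <- rep(seq_along(top), 2L)
  dup <- duplicated(oriented)
  oriented <- oriented[!dup]; source_id <- source_id[!dup]
  k_len <- nchar(oriented)
  out <- character(0)
  for (u in seq_along(oriented)) {
    ku <- k_len[u]
    cand <- which(k_len == ku & source_id != source_id[u])
    if (ku + 1L <= 8L && length(cand)) {
      suf <- substr(oriented[u], 2L, ku)
      pre <- substr(oriented[cand], 1L, ku - 1L)
      hit <- cand[pre == suf]
      if (length(hit))
        out <- c(out, paste0(oriented[u], substr(oriented[hit], ku, ku)))
    }
    for (g in seq_len(max_gap)) {
      vs <- which(k_len + ku + g <= 8L & source_id != source_id[u])
      if (length(vs))
        out <- c(out, paste0(oriented[u], strrep("N", g), oriented[vs]))
    }
  }
  if (length(out) == 0L) return(character(0))
  out <- unique(canonicalize(out))
  setdiff(out, canonicalize(features))
}
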