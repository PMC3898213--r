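#' Build the k-mer design matrix for PBM regression
#'
#' Entry (i, s) is the position-effect-weighted occurrence count of feature
#' `s` in probe `i`:  sum over window start positions `j` of
#' `lambda[j] * 1[window matches s]`, windows read on both strands via
#' canonicalization.  With uniform `lambda = 1` this reduces to raw
#' occurrence counts.
#'
#' @param seqs character vector of equal-length probe sequences (ACGT).
#' @param features character vector of canonical feature patterns.
#' @param lambda position effects: `NULL` (uniform 1), a numeric vector
#'   indexed by window start position (applied to every k), or a list of
#'   such vectors keyed by k (as produced by
#'   [estimate_position_effects()]).
#' @return a sparse `dgCMatrix` of dimension `length(seqs) x length(features)`.
#' @export
build_design_matrix <- function(seqs, features, lambda = NULL) {
  n <- length(seqs)
  L <- nchar(seqs[1L])
  stopifnot(all(nchar(seqs) == L))
  validate_features(features)
  if (any(nchar(features) > L))
    stop("feature longer than probe sequence")
  lambda_at <- function(k, pos) {
    if (is.null(lambda)) return(rep(1, length(pos)))
    if (is.list(lambda)) {
      lk <- lambda[[as.character(k)]]
      if (is.null(lk)) return(rep(1, length(pos)))
      return(lk[pos])
    }
    lambda[pos]
  }
  ti <- tj <- tx <- vector("list", 0L)
  gapped <- grepl("N", features, fixed = TRUE)
  for (k in sort(unique(nchar(features)))) {
    win <- kmer_window_matrix(seqs, k)       # n x (L-k+1)
    n_pos <- L - k + 1L
    # ungapped features of this k: hash windows by canonical form
    f_un <- which(!gapped & nchar(features) == k)
    if (length(f_un)) {
      fidx <- f_un[match(canonicalize(c(win)), features[f_un])]
      hit <- which(!is.na(fidx))
      if (length(hit)) {
        pos <- ((hit - 1L) %/% n) + 1L
        ti <- c(ti, list(((hit - 1L) %% n) + 1L))
        tj <- c(tj, list(fidx[hit]))
        tx <- c(tx, list(lambda_at(k, pos)))
      }
    }
    # gapped features: regex match on either strand
    f_gap <- which(gapped & nchar(features) == k)
    if (length(f_gap)) {
      rc_win <- revcomp(c(win))
      for (f in f_gap) {
        rx <- gapped_regex(features[f])
        hit <- which(grepl(rx, c(win)) | grepl(rx, rc_win))
        if (length(hit)) {
          pos <- ((hit - 1L) %/% n) + 1L
          ti <- c(ti, list(((hit - 1L) %% n) + 1L))
          tj <- c(tj, list(rep.int(f, length(hit))))
          tx <- c(tx, list(lambda_at(k, pos)))
        }
      }
    }
  }
  if (length(ti) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, length(features))))
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(n, length(features)))
}

## Non-negative least squares with a free intercept.
nnls_intercept <- function(X, y) {
  X <- as.matrix(X)
  xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  beta <- pracma::lsqnonneg(xc, yc)$x
  a <- mean(y) - drop(colMeans(X) %*% beta)
  list(beta = pmax(beta, 0), intercept = a)
}

#' Fit the positive lasso
#'
#' Minimises `||y - a - X beta||^2 + alpha * sum(beta)` subject to
#' `beta >= 0`, with a free intercept `a`.  Solved by coordinate descent
#' (glmnet with non-negativity box constraints); `alpha = 0` falls back to
#' non-negative least squares.
#'
#' @param X design matrix (dense or sparse).
#' @param y numeric response (probe intensities).
#' @param alpha non-negative penalty on `sum(beta)`.
#' @return list with `beta` (numeric, `>= 0`) and `intercept`.
#' @export
fit_positive_lasso <- function(X, y, alpha) {
  xvals <- if (inherits(X, "sparseMatrix")) X@x else as.numeric(X)
  if (any(!is.finite(y)) || any(!is.finite(xvals)))
    stop("non-finite values in lasso inputs")
  stopifnot(alpha >= 0, nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  if (stats::sd(y) == 0)
    return(list(beta = numeric(p), intercept = mean(y)))
  if (alpha == 0) return(nnls_intercept(X, y))
  if (p == 1L) {
    # closed form on centered data: beta = max(0, (x'y - alpha/2) / x'x)
    x <- as.numeric(X[, 1L])
    xc <- x - mean(x); yc <- y - mean(y)
    denom <- sum(xc^2)
    beta <- if (denom == 0) 0 else max(0, (sum(xc * yc) - alpha / 2) / denom)
    return(list(beta = beta, intercept = mean(y) - beta * mean(x)))
  }
  lam <- alpha / (2 * n)
  path <- lam * c(64, 16, 4, 1)
  fit <- glmnet::glmnet(X, y, family = "gaussian", lambda = path,
                        lower.limits = 0, standardize = FALSE,
                        thresh = 1e-14, maxit = 1e7)
  j <- length(path)
  list(beta = pmax(as.numeric(fit$beta[, j]), 0),
       intercept = as.numeric(fit$a0[j]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Choose the lasso penalty by cross-validation
#'
#' 5-fold cross-validation over glmnet's logarithmic penalty grid; returns
#' the largest penalty within one standard error of the minimum CV error
#' (the sparser model), on the `alpha = 2 n lambda` scale used by
#' [fit_positive_lasso()].
#'
#' @param X design matrix.
#' @param y response.
#' @param nfolds number of folds.
#' @param seed integer seed controlling the fold assignment.
#' @return list with `alpha` (the 1-SE choice), `alpha_min`, and the
#'   `cv.glmnet` object.
#' @export
cv_positive_lasso <- function(X, y, nfolds = 5L, seed = 1L) {
  n <- nrow(X)
  foldid <- withr::with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  cv <- glmnet::cv.glmnet(X, y, family = "gaussian", foldid = foldid,
                          lower.limits = 0, standardize = FALSE)
  list(alpha = cv$lambda.1se * 2 * n,
       alpha_min = cv$lambda.min * 2 * n,
       cv = cv)
}

#' Estimate position effects from residual intensity structure
#'
#' With the k-mer coefficients held fixed, regresses the centred intensity
#' on the per-position aggregate coefficient mass
#' `g[i, j] = sum_s beta_s 1[window at start j of probe i matches s]`
#' under a non-negativity constraint, then renormalises the position
#' effects to mean 1.  One such pass forms the alternating
#' (beta, lambda) refinement used in training.
#'
#' @param seqs probe sequences.
#' @param y probe intensities.
#' @param features canonical feature patterns.
#' @param beta fitted coefficients aligned with `features`.
#' @param intercept fitted intercept.
#' @return a named list with one numeric vector per k-mer length present
#'   in `features`; entry `j` of the vector for length `k` is the
#'   position effect of a window starting at position `j`, normalised to
#'   mean 1 within each k.  Keeping the effects per k makes training
#'   exactly strand symmetric (reversing every probe reverses each
#'   vector but leaves the weighted counts unchanged).
#' @export
estimate_position_effects <- function(seqs, y, features, beta, intercept) {
  L <- nchar(seqs[1L])
  ks <- sort(unique(nchar(features)))
  uniform <- stats::setNames(lapply(ks, function(k) rep(1, L - k + 1L)),
                             ks)
  active <- which(beta > 0)
  if (length(active) == 0L) return(uniform)
  if (length(seqs) < 100L) {
    warning("fewer than 100 probes; returning uniform position effects")
    return(uniform)
  }
  n <- length(seqs)
  # one design column per (k, start position) pair, weighted by beta
  offset_k <- stats::setNames(cumsum(c(0L, (L - ks + 1L)[-length(ks)])), ks)
  n_col <- sum(L - ks + 1L)
  ti <- tp <- tw <- vector("list", 0L)
  gapped <- grepl("N", features, fixed = TRUE)
  for (k in sort(unique(nchar(features[active])))) {
    win <- kmer_window_matrix(seqs, k)
    f_k <- active[nchar(features[active]) == k]
    f_un <- f_k[!gapped[f_k]]
    if (length(f_un)) {
      fidx <- f_un[match(canonicalize(c(win)), features[f_un])]
      hit <- which(!is.na(fidx))
      if (length(hit)) {
        ti <- c(ti, list(((hit - 1L) %% n) + 1L))
        tp <- c(tp, list(offset_k[[as.character(k)]] +
                           ((hit - 1L) %/% n) + 1L))
        tw <- c(tw, list(beta[fidx[hit]]))
      }
    }
    for (f in f_k[gapped[f_k]]) {
      rx <- gapped_regex(features[f])
      hit <- which(grepl(rx, c(win)) | grepl(rx, revcomp(c(win))))
      if (length(hit)) {
        ti <- c(ti, list(((hit - 1L) %% n) + 1L))
        tp <- c(tp, list(offset_k[[as.character(k)]] +
                           ((hit - 1L) %/% n) + 1L))
        tw <- c(tw, list(rep.int(beta[f], length(hit))))
      }
    }
  }
  if (length(ti) == 0L) return(uniform)
  G <- as.matrix(Matrix::sparseMatrix(i = unlist(ti), j = unlist(tp),
                                      x = unlist(tw), dims = c(n, n_col)))
  used <- colSums(G) > 0
  if (!any(used)) return(uniform)
  lam_flat <- rep(NA_real_, n_col)
  lam_flat[used] <- pracma::lsqnonneg(G[, used, drop = FALSE],
                                      y - intercept)$x
  out <- uniform
  for (k in ks) {
    idx <- offset_k[[as.character(k)]] + seq_len(L - k + 1L)
    lk <- lam_flat[idx]
    if (all(is.na(lk)) || sum(lk, na.rm = TRUE) == 0) next  # keep uniform
    lk[is.na(lk)] <- mean(lk, na.rm = TRUE)
    out[[as.character(k)]] <- lk / mean(lk)
  }
  out
}

#' Train the k-mer PBM binding model
#'
#' Full training pipeline: enumerate all canonical 4--6-mers, fit the
#' positive lasso on position-weighted occurrence counts, iteratively merge
#' the top-ranked features into longer (and gapped) k-mers up to length 8
#' with refitting after each extension, optionally refine position effects
#' by one alternating pass, debias the selected coefficients by
#' non-negative least squares on the active set, and normalise so that the
#' largest coefficient equals 1.
#'
#' @param probes `data.frame` from [read_pbm_table()] (or
#'   [simulate_pbm()]), columns `sequence` and `intensity`; at least 100
#'   probes.
#' @param k_min,k_max k range of the initial feature set (default 4--6).
#' @param alpha lasso penalty on `sum(beta)`; `"auto"` (default) selects it
#'   by 5-fold cross-validation (1-SE rule).
#' @param top_n number of top features fed to the extension step.
#' @param max_gap maximum gap width in gapped joins.
#' @param lambda_passes number of alternating position-effect refinement
#'   passes (default 1).
#' @param relax if `TRUE` (default), refit the selected support by
#'   non-negative least squares so that coefficient ratios are unbiased by
#'   the lasso shrinkage.
#' @param log_intensity if `TRUE`, model `log(intensity)` instead of the
#'   raw scale (default off; the linear model is stated on raw units).
#' @param seed integer seed (cross-validation folds).
#' @return an object of class `kmer_binding_model` with elements
#'   `features`, `beta` (unnormalised), `beta_norm` (max 1), `lambda`
#'   (position effects), `intercept`, `alpha`, and training metadata.
#' @export
train_pbm_model <- function(probes, k_min = 4L, k_max = 6L, alpha = "auto",
                            top_n = 100L, max_gap = 3L, lambda_passes = 1L,
                            relax = TRUE, log_intensity = FALSE, seed = 1L) {
  stopifnot(is.data.frame(probes), all(c("sequence", "intensity") %in% names(probes)))
  if (nrow(probes) < 100L) stop("training requires at least 100 probes")
  seqs <- toupper(probes$sequence)
  y <- probes$intensity
  if (log_intensity) y <- log(y)
  L <- nchar(seqs[1L])

  features <- enumerate_features(k_min, k_max)
  lambda <- NULL   # uniform position effects until the refinement pass

  if (stats::sd(y) == 0) {
    warning("all probe intensities identical; returning an empty model")
    return(new_kmer_model(features, numeric(length(features)), NULL,
                          mean(y), 0, k_min, k_max, length(seqs), seed))
  }

  X <- build_design_matrix(seqs, features, lambda)
  if (identical(alpha, "auto"))
    alpha <- cv_positive_lasso(X, y, seed = seed)$alpha
  fit <- fit_positive_lasso(X, y, alpha)

  # extension loop: merge top features into longer/gapped k-mers, refit
  for (round in 1:10) {
    new_feats <- extend_features(features, fit$beta, top_n = top_n,
                                 max_gap = max_gap)
    new_feats <- new_feats[nchar(new_feats) <= 8L]
    if (length(new_feats) == 0L) break
    X <- cbind(X, build_design_matrix(seqs, new_feats, lambda))
    features <- c(features, new_feats)
    fit <- fit_positive_lasso(X, y, alpha)
  }

  # alternating position-effect refinement
  for (pass in seq_len(lambda_passes)) {
    lambda <- estimate_position_effects(seqs, y, features, fit$beta,
                                        fit$intercept)
    X <- build_design_matrix(seqs, features, lambda)
    fit <- fit_positive_lasso(X, y, alpha)
  }

  if (relax && any(fit$beta > 0)) {
    act <- which(fit$beta > 0)
    re <- nnls_intercept(X[, act, drop = FALSE], y)
    fit$beta[] <- 0
    fit$beta[act] <- re$beta
    fit$intercept <- re$intercept
  }

  new_kmer_model(features, fit$beta, lambda, fit$intercept, alpha,
                 k_min, k_max, length(seqs), seed)
}

new_kmer_model <- function(features, beta, lambda, intercept, alpha,
                           k_min, k_max, n_probes, seed) {
  beta <- pmax(beta, 0)
  bmax <- max(beta)
  structure(list(
    features = features,
    beta = beta,
    beta_norm = if (bmax > 0) beta / bmax else beta,
    lambda = lambda,
    intercept = intercept,
    alpha = alpha,
    k_range = c(k_min, k_max),
    n_probes = n_probes,
    n_nonzero = sum(beta > 0),
    seed = seed
  ), class = "kmer_binding_model")
}

#' @export
print.kmer_binding_model <- function(x, ...) {
  cat("k-mer PBM binding model\n")
  cat(sprintf("  features: %d candidates, %d with beta > 0\n",
              length(x$features), x$n_nonzero))
  cat(sprintf("  k range: %d-%d (extension cap 8), alpha = %.4g\n",
              x$k_range[1], x$k_range[2], x$alpha))
  if (x$n_nonzero > 0) {
    top <- order(-x$beta_norm)[seq_len(min(5L, x$n_nonzero))]
    cat("  top k-mers (beta'):\n")
    for (i in top)
      cat(sprintf("    %-8s %.3f\n", x$features[i], x$beta_norm[i]))
  }
  invisible(x)
}

#' Serialize a k-mer binding model
#'
#' Writes a flat TSV of the nonzero coefficients
#' (`pattern`, `k`, `beta`, `beta_normalized`) plus a JSON sidecar
#' (`<path>.json`) holding the intercept, penalty, position effects, k
#' range and seed.  Deterministic byte-for-byte for a fixed model.
#'
#' @param model a `kmer_binding_model`.
#' @param path TSV output path; the header goes to `paste0(path, ".json")`.
#' @return invisibly, `path`.
#' @export
write_kmer_model <- function(model, path) {
  keep <- model$beta > 0
  tab <- data.frame(pattern = model$features[keep],
                    k = nchar(model$features[keep]),
                    beta = sprintf("%.10g", model$beta[keep]),
                    beta_normalized = sprintf("%.10g", model$beta_norm[keep]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$pattern), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  hdr <- list(intercept = model$intercept, alpha = model$alpha,
              lambda = as.list(model$lambda), k_range = model$k_range,
              n_probes = model$n_probes, seed = model$seed)
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Read a serialized k-mer binding model
#'
#' @param path TSV path written by [write_kmer_model()].
#' @return a `kmer_binding_model`.
#' @export
read_kmer_model <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "integer",
                                          "numeric", "numeric"))
  hdr <- jsonlite::fromJSON(paste0(path, ".json"))
  lambda <- if (length(hdr$lambda)) lapply(hdr$lambda, as.numeric)
  new_kmer_model(tab$pattern, tab$beta, lambda, hdr$intercept,
                 hdr$alpha, hdr$k_range[1], hdr$k_range[2],
                 hdr$n_probes, hdr$seed)
}
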