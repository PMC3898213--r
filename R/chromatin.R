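#' DNase tag density of a site
#'
#' Length-weighted mean track value over a 36bp site, rounded to the
#' nearest integer count for mixture fitting.  Uncovered sites report 0.
#'
#' @param track a `coverage_track` of DNase tag densities.
#' @param sites `data.frame` with columns `chrom`, `start`, `end`.
#' @return integer vector of per-site counts.
#' @export
site_tag_density <- function(track, sites) {
  vapply(seq_len(nrow(sites)), function(i)
    round(track_mean(track, sites$chrom[i], sites$start[i], sites$end[i])),
    numeric(1))
}

## shared-dispersion NB log-likelihood matrix: n x 2
nb_loglik_mat <- function(counts, mu, size) {
  cbind(stats::dnbinom(counts, mu = mu[1], size = size, log = TRUE),
        stats::dnbinom(counts, mu = mu[2], size = size, log = TRUE))
}

mixture_loglik <- function(counts, w, mu, size) {
  ll <- nb_loglik_mat(counts, mu, size)
  sum(log(rowSums(exp(ll) %*% diag(c(1 - w, w)) + 1e-300)))
}

#' Fit the two-state chromatin mixture
#'
#' Models per-site DNase tag counts as a two-component negative-binomial
#' mixture with a shared dispersion: a low-mean *closed* component and a
#' high-mean *open* component.  Fitted by EM; the shared dispersion makes
#' the posterior probability of the open state provably monotone in the
#' count.
#'
#' @param counts non-negative integer tag counts, one per site (>= 200
#'   sites).
#' @param seed integer seed (recorded; the fit itself is deterministic
#'   given the initialisation, a split at the 90th percentile).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` (default 1e-6) or after `max_iter`
#'   iterations (default 500).
#' @return object of class `chromatin_mixture` with `weight_open`,
#'   `mean_closed`, `mean_open`, `dispersion` (NB size), `loglik` trace,
#'   `degenerate` flag and fit metadata.
#' @export
fit_chromatin_mixture <- function(counts, seed = 1L, max_iter = 500L,
                                  tol = 1e-6) {
  stopifnot(all(counts >= 0), all(is.finite(counts)))
  if (length(counts) < 200L) stop("mixture fitting requires >= 200 sites")
  counts <- round(counts)
  if (length(unique(counts)) == 1L) {
    warning("all counts identical; mixture is degenerate (threshold mode)")
    return(structure(list(weight_open = NA_real_, mean_closed = NA_real_,
                          mean_open = NA_real_, dispersion = NA_real_,
                          degenerate = TRUE, loglik = numeric(0),
                          iterations = 0L, n_sites = length(counts),
                          seed = seed), class = "chromatin_mixture"))
  }
  # initialisation: split at the 90th percentile
  cut <- stats::quantile(counts, 0.9, type = 1)
  open0 <- counts > cut
  if (!any(open0)) open0 <- counts > stats::median(counts)
  mu <- c(max(mean(counts[!open0]), 0.05), max(mean(counts[open0]), 0.1))
  if (mu[2] <= mu[1]) mu[2] <- mu[1] * 2 + 1
  w <- min(max(mean(open0), 0.01), 0.99)
  size <- 5

  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # E-step
    lmat <- nb_loglik_mat(counts, mu, size) +
      rep(log(c(1 - w, w)), each = length(counts))
    m <- pmax(lmat[, 1], lmat[, 2])
    lse <- m + log(exp(lmat[, 1] - m) + exp(lmat[, 2] - m))
    r_open <- exp(lmat[, 2] - lse)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    # M-step: weights and means are exact; shared dispersion by 1-D search
    w_new <- mean(r_open)
    mu_new <- c(max(sum((1 - r_open) * counts) / sum(1 - r_open), 1e-4),
                max(sum(r_open * counts) / sum(r_open), 1e-4))
    qfun <- function(log_size) {
      s <- exp(log_size)
      lm <- nb_loglik_mat(counts, mu_new, s)
      sum((1 - r_open) * lm[, 1] + r_open * lm[, 2])
    }
    opt <- stats::optimize(qfun, c(log(1e-2), log(1e4)), maximum = TRUE,
                           tol = 1e-4)
    size_new <- if (opt$objective >= qfun(log(size))) exp(opt$maximum) else size
    w <- w_new; mu <- mu_new; size <- size_new
    if (it > 1L && ll - ll_trace[it - 1L] < tol) break
  }
  # relabel so that the open component has the larger mean
  if (mu[1] > mu[2]) {
    mu <- rev(mu); w <- 1 - w
  }
  structure(list(weight_open = w, mean_closed = mu[1], mean_open = mu[2],
                 dispersion = size, degenerate = FALSE, loglik = ll_trace,
                 iterations = length(ll_trace), n_sites = length(counts),
                 seed = seed), class = "chromatin_mixture")
}

#' @export
print.chromatin_mixture <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("chromatin mixture: degenerate (use threshold mode)\n")
  } else {
    cat(sprintf(
      "chromatin mixture: open weight %.3f, means %.2f (closed) / %.2f (open), NB size %.2f\n",
      x$weight_open, x$mean_closed, x$mean_open, x$dispersion))
    cat(sprintf("  %d sites, %d EM iterations, loglik %.2f\n",
                x$n_sites, x$iterations, x$loglik[length(x$loglik)]))
  }
  invisible(x)
}

#' Posterior probability that a site's chromatin is open
#'
#' Bayes posterior of the open component given a tag count under the
#' fitted two-component mixture; monotone non-decreasing in the count.
#'
#' @param mixture a non-degenerate `chromatin_mixture`.
#' @param count numeric vector of tag counts (rounded to integers).
#' @return numeric vector of probabilities.
#' @export
prob_open <- function(mixture, count) {
  stopifnot(inherits(mixture, "chromatin_mixture"))
  if (isTRUE(mixture$degenerate))
    stop("degenerate mixture: use the hard density threshold (> 15) instead")
  count <- round(count)
  lmat <- nb_loglik_mat(count, c(mixture$mean_closed, mixture$mean_open),
                        mixture$dispersion) +
    rep(log(c(1 - mixture$weight_open, mixture$weight_open)),
        each = length(count))
  m <- pmax(lmat[, 1], lmat[, 2])
  exp(lmat[, 2] - m) / (exp(lmat[, 1] - m) + exp(lmat[, 2] - m))
}

#' Site occupancy
#'
#' The in vivo occupancy of a site is the product of its in vitro binding
#' probability and the probability that its chromatin is open:
#' `X = B * P(open)`.
#'
#' @param B binding probability in `[0, 1]`.
#' @param p_open open-chromatin probability in `[0, 1]`.
#' @return numeric vector `X` in `[0, 1]`.
#' @export
occupancy <- function(B, p_open) {
  if (any(B < 0 | B > 1, na.rm = FALSE) || any(p_open < 0 | p_open > 1))
    stop("B and p_open must lie in [0, 1]")
  B * p_open
}

#' Serialize a chromatin mixture to JSON
#' @param mixture a `chromatin_mixture`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_chromatin_mixture <- function(mixture, path) {
  writeLines(jsonlite::toJSON(unclass(mixture), auto_unbox = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' Read a chromatin mixture from JSON
#' @param path path written by [write_chromatin_mixture()].
#' @return a `chromatin_mixture`.
#' @export
read_chromatin_mixture <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$loglik <- as.numeric(x$loglik)
  structure(x, class = "chromatin_mixture")
}
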