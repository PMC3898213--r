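## Weighted maximum-likelihood Beta fit from sufficient statistics.
## Maximises sum_i w_i log dbeta(x_i; a, b); exponential-family objective,
## solved over (log a, log b) with a method-of-moments warm start.
beta_mle_weighted <- function(x, w, start = NULL) {
  W <- sum(w)
  if (W <= 0) return(c(1, 1))
  t1 <- sum(w * log(x)) / W
  t2 <- sum(w * log1p(-x)) / W
  negq <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -((a - 1) * t1 + (b - 1) * t2 - lbeta(a, b))
  }
  if (is.null(start)) {
    m <- sum(w * x) / W
    v <- sum(w * (x - m)^2) / W
    v <- max(min(v, m * (1 - m) * 0.999), 1e-8)
    nu <- m * (1 - m) / v - 1
    start <- c(max(m * nu, 1e-2), max((1 - m) * nu, 1e-2))
  }
  opt <- stats::optim(log(pmin(pmax(start, 1e-3), 1e5)), negq,
                      method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  est <- exp(opt$par)
  # never accept a step that is worse than the warm start
  if (negq(log(est)) > negq(log(start))) est <- start
  pmin(pmax(est, 1e-4), 1e6)
}

log_sum_exp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Fit the integrated binding model
#'
#' Latent-variable model `X <- Z -> C -> S`: each candidate site carries a
#' binary indicator `Z` of true in vivo binding.  The occupancy `X`
#' (binding probability times open-chromatin probability) follows a Beta
#' distribution whose mean is higher for bound sites; `C` is a latent
#' conserved/unconserved indicator, more likely 1 for bound sites; the
#' conservation score `S` follows a Beta distribution given `C`.  `C` is
#' always marginalised.  Fitted by EM with exact M-steps, so the observed
#' log-likelihood is non-decreasing.
#'
#' @param X numeric vector of site occupancies in `[0, 1]` (>= 500 sites);
#'   values are clamped to `[eps, 1 - eps]`.
#' @param S optional numeric vector of conservation scores in `[0, 1]`.
#' @param use_conservation include the conservation branch (default: `TRUE`
#'   when `S` is supplied).
#' @param prior_z initial prior probability of binding (default 0.05).
#' @param zero_inflated if `TRUE`, occupancies exactly 0 (closed chromatin
#'   or zero-count windows) are modelled by an explicit per-Z point mass
#'   instead of being clamped into the Beta density.  Recommended whenever
#'   a substantial fraction of sites have `X == 0`, where the clamp would
#'   otherwise make one Beta component collapse onto the boundary atom and
#'   reduce the posterior to an open/closed indicator.
#' @param eps clamp width for exact 0/1 observations (default 1e-6).
#' @param max_iter,tol EM stopping rule (loglik improvement < `tol`,
#'   default 1e-6, or `max_iter` = 500 iterations).
#' @param seed integer seed, recorded in the fit metadata.
#' @return object of class `pipes_model` with `prior_z`, `x_given_z`
#'   (2 x 2 matrix of Beta parameters, rows Z=0/Z=1), `c_given_z`
#'   (Bernoulli rates `q0`, `q1`), `s_given_c` (Beta parameters, rows
#'   C=0/C=1, when fitted), `loglik` trace, and metadata.
#' @export
fit_pipes <- function(X, S = NULL, use_conservation = !is.null(S),
                      prior_z = 0.05, zero_inflated = FALSE, eps = 1e-6,
                      max_iter = 500L, tol = 1e-6, seed = 1L) {
  stopifnot(all(X >= 0 & X <= 1))
  if (length(X) < 500L) stop("fitting requires >= 500 sites")
  if (use_conservation && is.null(S))
    stop("use_conservation = TRUE but no conservation scores supplied")
  x <- pmin(pmax(X, eps), 1 - eps)
  n <- length(x)
  if (length(unique(x)) == 1L) {
    warning("all occupancies identical; posterior equals the prior")
    return(structure(list(prior_z = prior_z, x_given_z = NULL,
                          c_given_z = NULL, s_given_c = NULL,
                          degenerate = TRUE, use_conservation = FALSE,
                          eps = eps, loglik = numeric(0), n_sites = n,
                          seed = seed), class = "pipes_model"))
  }
  s <- if (use_conservation) pmin(pmax(S, eps), 1 - eps) else NULL
  zero <- zero_inflated & (X <= eps)
  pos <- !zero

  # initial responsibilities from the ranking of X (and of S for C)
  r1 <- ifelse(rank(x, ties.method = "first") > n * (1 - prior_z), 0.9, 0.02)
  ax <- rbind(beta_mle_weighted(x[pos], (1 - r1)[pos]),
              beta_mle_weighted(x[pos], r1[pos]))
  w0 <- if (zero_inflated)
    pmin(pmax(c(sum((1 - r1) * zero) / sum(1 - r1),
                sum(r1 * zero) / sum(r1)), 1e-6), 1 - 1e-6)
  pi1 <- mean(r1)
  q <- c(0.2, 0.6)
  as <- NULL
  if (use_conservation) {
    u1 <- ifelse(rank(s, ties.method = "first") > n * 0.7, 0.9, 0.1)
    as <- rbind(beta_mle_weighted(s, 1 - u1), beta_mle_weighted(s, u1))
  }

  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lfx <- cbind(stats::dbeta(x, ax[1, 1], ax[1, 2], log = TRUE),
                 stats::dbeta(x, ax[2, 1], ax[2, 2], log = TRUE))
    if (zero_inflated) {
      # per-Z point mass at zero; Beta density applies to positives only
      lfx[, 1] <- ifelse(zero, log(w0[1]), log1p(-w0[1]) + lfx[, 1])
      lfx[, 2] <- ifelse(zero, log(w0[2]), log1p(-w0[2]) + lfx[, 2])
    }
    if (use_conservation) {
      lgs <- cbind(stats::dbeta(s, as[1, 1], as[1, 2], log = TRUE),
                   stats::dbeta(s, as[2, 1], as[2, 2], log = TRUE))
      # log P(S | Z=z) marginalising C
      lps <- cbind(log_sum_exp2(log(1 - q[1]) + lgs[, 1], log(q[1]) + lgs[, 2]),
                   log_sum_exp2(log(1 - q[2]) + lgs[, 1], log(q[2]) + lgs[, 2]))
    } else {
      lps <- matrix(0, n, 2L)
    }
    lz <- cbind(log(1 - pi1) + lfx[, 1] + lps[, 1],
                log(pi1) + lfx[, 2] + lps[, 2])
    lse <- log_sum_exp2(lz[, 1], lz[, 2])
    ll_trace <- c(ll_trace, sum(lse))
    r <- exp(lz - lse)                     # responsibilities for Z = 0, 1

    # M-step
    pi1 <- min(max(mean(r[, 2]), 1e-6), 1 - 1e-6)
    if (zero_inflated) {
      w0 <- pmin(pmax(colSums(r * zero) / colSums(r), 1e-6), 1 - 1e-6)
      ax <- rbind(beta_mle_weighted(x[pos], r[pos, 1], ax[1, ]),
                  beta_mle_weighted(x[pos], r[pos, 2], ax[2, ]))
    } else {
      ax <- rbind(beta_mle_weighted(x, r[, 1], ax[1, ]),
                  beta_mle_weighted(x, r[, 2], ax[2, ]))
    }
    if (use_conservation) {
      # joint responsibilities for (Z = z, C = c)
      w_c1 <- sapply(1:2, function(z)
        r[, z] * exp(log(q[z]) + lgs[, 2] - lps[, z]))
      w_c0 <- sapply(1:2, function(z)
        r[, z] * exp(log(1 - q[z]) + lgs[, 1] - lps[, z]))
      q <- pmin(pmax(colSums(w_c1) / pmax(colSums(w_c1) + colSums(w_c0),
                                          1e-300), 1e-6), 1 - 1e-6)
      u1 <- rowSums(w_c1); u0 <- rowSums(w_c0)
      as <- rbind(beta_mle_weighted(s, u0, as[1, ]),
                  beta_mle_weighted(s, u1, as[2, ]))
    }
    if (it > 1L && ll_trace[it] - ll_trace[it - 1L] < tol) break
  }

  # relabel so that E[X | Z=1] > E[X | Z=0] (zero mass included)
  mean_x <- ax[, 1] / rowSums(ax)
  if (zero_inflated) mean_x <- (1 - w0) * mean_x
  if (mean_x[2] < mean_x[1]) {
    ax <- ax[2:1, ]; pi1 <- 1 - pi1; q <- rev(q)
    if (zero_inflated) w0 <- rev(w0)
  }
  if (use_conservation) {
    mean_s <- as[, 1] / rowSums(as)
    if (mean_s[2] < mean_s[1]) {
      as <- as[2:1, ]; q <- 1 - q
    }
  }
  dimnames(ax) <- list(c("z0", "z1"), c("shape1", "shape2"))
  if (use_conservation) dimnames(as) <- list(c("c0", "c1"),
                                             c("shape1", "shape2"))
  structure(list(prior_z = pi1, x_given_z = ax,
                 x_zero = if (zero_inflated) stats::setNames(w0, c("z0", "z1")),
                 c_given_z = if (use_conservation) stats::setNames(q, c("q0", "q1")),
                 s_given_c = as, degenerate = FALSE,
                 use_conservation = use_conservation, eps = eps,
                 loglik = ll_trace, iterations = length(ll_trace),
                 n_sites = n, seed = seed), class = "pipes_model")
}

#' @export
print.pipes_model <- function(x, ...) {
  cat("integrated binding model (X <- Z -> C -> S)\n")
  if (isTRUE(x$degenerate)) {
    cat(sprintf("  degenerate fit: posterior = prior = %.3f\n", x$prior_z))
    return(invisible(x))
  }
  mx <- x$x_given_z[, 1] / rowSums(x$x_given_z)
  cat(sprintf("  prior P(Z=1) = %.4f\n", x$prior_z))
  cat(sprintf("  E[X|Z=0] = %.4f, E[X|Z=1] = %.4f\n", mx[1], mx[2]))
  if (x$use_conservation) {
    ms <- x$s_given_c[, 1] / rowSums(x$s_given_c)
    cat(sprintf("  P(C=1|Z=0) = %.3f, P(C=1|Z=1) = %.3f\n",
                x$c_given_z[1], x$c_given_z[2]))
    cat(sprintf("  E[S|C=0] = %.3f, E[S|C=1] = %.3f\n", ms[1], ms[2]))
  }
  cat(sprintf("  %d sites, %d EM iterations\n", x$n_sites, x$iterations))
  invisible(x)
}

#' Posterior probability of in vivo binding
#'
#' `P(Z = 1 | X, S)` by Bayes' rule under a fitted integrated model, with
#' the conservation likelihood marginalised over the latent conserved
#' state: `P(S | Z=z) = sum_c P(C=c | Z=z) P(S | C=c)`.  When `S` is
#' absent (or the model was fitted without conservation) only the
#' occupancy branch is used.
#'
#' @param model a fitted `pipes_model`.
#' @param X occupancy values in `[0, 1]`.
#' @param S optional conservation scores in `[0, 1]`.
#' @return numeric vector of posterior probabilities.
#' @export
posterior_binding <- function(model, X, S = NULL) {
  stopifnot(inherits(model, "pipes_model"))
  if (isTRUE(model$degenerate)) return(rep(model$prior_z, length(X)))
  if (is.null(model$x_given_z)) stop("model is not fitted")
  x <- pmin(pmax(X, model$eps), 1 - model$eps)
  lx0 <- stats::dbeta(x, model$x_given_z[1, 1], model$x_given_z[1, 2],
                      log = TRUE)
  lx1 <- stats::dbeta(x, model$x_given_z[2, 1], model$x_given_z[2, 2],
                      log = TRUE)
  if (!is.null(model$x_zero)) {
    zero <- X <= model$eps
    lx0 <- ifelse(zero, log(model$x_zero[[1]]),
                  log1p(-model$x_zero[[1]]) + lx0)
    lx1 <- ifelse(zero, log(model$x_zero[[2]]),
                  log1p(-model$x_zero[[2]]) + lx1)
  }
  lz0 <- log(1 - model$prior_z) + lx0
  lz1 <- log(model$prior_z) + lx1
  if (!is.null(S) && model$use_conservation) {
    s <- pmin(pmax(S, model$eps), 1 - model$eps)
    lg0 <- stats::dbeta(s, model$s_given_c[1, 1], model$s_given_c[1, 2],
                        log = TRUE)
    lg1 <- stats::dbeta(s, model$s_given_c[2, 1], model$s_given_c[2, 2],
                        log = TRUE)
    q <- model$c_given_z
    lz0 <- lz0 + log_sum_exp2(log(1 - q[[1]]) + lg0, log(q[[1]]) + lg1)
    lz1 <- lz1 + log_sum_exp2(log(1 - q[[2]]) + lg0, log(q[[2]]) + lg1)
  }
  unname(1 / (1 + exp(lz0 - lz1)))
}

#' Threshold posterior probabilities into predicted binding sites
#'
#' @param model a fitted `pipes_model`.
#' @param sites `data.frame` of scored sites with columns `chrom`, `start`,
#'   `end`, `B`, `p_open`, `X` and optionally `S` (conservation).
#' @param threshold posterior cutoff (default 0.5).
#' @return the subset of `sites` with `posterior >= threshold`, with a
#'   `posterior` column appended, sorted by (chrom, start).
#' @export
predict_sites <- function(model, sites, threshold = 0.5) {
  stopifnot(is.data.frame(sites), "X" %in% names(sites))
  S <- if ("S" %in% names(sites)) sites$S
  sites$posterior <- posterior_binding(model, sites$X, S)
  out <- sites[sites$posterior >= threshold, , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Serialize an integrated model to JSON
#' @param model a `pipes_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pipes_model <- function(model, path) {
  writeLines(jsonlite::toJSON(unclass(model), auto_unbox = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' Read an integrated model from JSON
#' @param path path written by [write_pipes_model()].
#' @return a `pipes_model`.
#' @export
read_pipes_model <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (!is.null(x$x_given_z)) x$x_given_z <- as.matrix(x$x_given_z)
  if (!is.null(x$s_given_c)) x$s_given_c <- as.matrix(x$s_given_c)
  if (!is.null(x$c_given_z)) x$c_given_z <- unlist(x$c_given_z)
  if (!is.null(x$x_zero)) x$x_zero <- unlist(x$x_zero)
  x$loglik <- as.numeric(x$loglik)
  structure(x, class = "pipes_model")
}
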