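#' HMM initial and transition probabilities
#'
#' Three expression states coded 0 = decreased, 1 = stable, 2 = increased.
#' Defaults follow the published parameterization: the stable state is
#' initially most likely and states tend to persist across adjacent sites.
#'
#' @param pi0 Initial state probabilities over (down, stable, up); must sum
#'   to 1. Default `c(0.05, 0.9, 0.05)`.
#' @param trans 3x3 transition matrix, rows summing to 1. Default 0.8 on the
#'   diagonal, 0.1 off.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(pi0 = c(0.05, 0.9, 0.05),
                       trans = matrix(c(0.8, 0.1, 0.1,
                                        0.1, 0.8, 0.1,
                                        0.1, 0.1, 0.8), 3, 3, byrow = TRUE)) {
  pi0 <- as.numeric(pi0); trans <- as.matrix(trans)
  stopifnot(length(pi0) == 3L, all(dim(trans) == c(3L, 3L)))
  if (any(pi0 < 0) || any(trans < 0) || any(pi0 > 1) || any(trans > 1))
    stop("probabilities must lie in [0, 1]")
  if (abs(sum(pi0) - 1) > 1e-8) stop("pi0 must sum to 1")
  if (any(abs(rowSums(trans) - 1) > 1e-8)) stop("transition rows must sum to 1")
  dimnames(trans) <- list(c("down", "stable", "up"), c("down", "stable", "up"))
  structure(list(pi0 = stats::setNames(pi0, c("down", "stable", "up")),
                 trans = trans), class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("hmm_params\n  pi0:", format(x$pi0), "\n  transition matrix:\n")
  print(x$trans)
  invisible(x)
}

#' Emission model parameters
#'
#' Tunables of the per-site emission model built on the log fold change of
#' sample coverage against the reference mean.
#'
#' @param alpha Two-sided significance level defining the critical shift
#'   `c = z_(1-alpha/2) * s` that separates the state means (default 0.05).
#' @param low_mu_threshold Reference mean (normalized reads) below which the
#'   log-fold-change model is unreliable and the low-coverage rule applies
#'   (default 0.5).
#' @param low_mu_sample_min Sample reads at or above which a low-coverage
#'   site is scored as clearly upregulated (default 5).
#' @param low_mu_prob Probability assigned to the favored state under the
#'   low-coverage rule (default 0.95); the remainder splits equally between
#'   the other two states.
#' @param epsilon Floor on sample coverage inside the log (default 0.5, half
#'   a normalized read), so zero-coverage sites get a finite, strongly
#'   down-favoring log fold change.
#' @param sigma2_floor Floor on the reference variance before the delta
#'   method (default 1e-6), avoiding infinite statistics on constant tracks.
#' @param orientation `"monotone"` (default): each state's emission is a tail
#'   probability increasing toward that state's side, the unique assignment
#'   under which up-emissions are nondecreasing and down-emissions
#'   nonincreasing in the log fold change. `"literal"`: the upper tail of
#'   each state's own distribution read verbatim, kept only for comparison
#'   (it misranks states for large shifts).
#' @return An object of class `emission_params`.
#' @export
emission_params <- function(alpha = 0.05, low_mu_threshold = 0.5,
                            low_mu_sample_min = 5, low_mu_prob = 0.95,
                            epsilon = 0.5, sigma2_floor = 1e-6,
                            orientation = c("monotone", "literal")) {
  stopifnot(alpha > 0, alpha < 1, low_mu_prob > 0, low_mu_prob < 1,
            epsilon > 0, sigma2_floor >= 0)
  structure(list(alpha = alpha, low_mu_threshold = low_mu_threshold,
                 low_mu_sample_min = low_mu_sample_min,
                 low_mu_prob = low_mu_prob, epsilon = epsilon,
                 sigma2_floor = sigma2_floor,
                 orientation = match.arg(orientation)),
            class = "emission_params")
}

#' Delta-method standard deviation of the log fold change
#'
#' Under no expression change the sample shares the reference per-site mean
#' and variance, and the delta method gives the variance of the natural log
#' of the fold change as `2 * sigma2 / mu^2`. Returns its square root `s`.
#' Sites with `mu` below `low_mu_threshold` bypass this formula (the
#' low-coverage emission rule applies there) and return `NA`.
#'
#' @param mu Reference per-site mean (vectorized).
#' @param sigma2 Reference per-site variance (vectorized).
#' @param low_mu_threshold Threshold under which `NA` is returned
#'   (default 0.5).
#' @param sigma2_floor Variance floor (default 1e-6).
#' @return Numeric vector `s = sqrt(2 * sigma2 / mu^2)`, `NA` where
#'   `mu < low_mu_threshold`.
#' @export
delta_lfc_sd <- function(mu, sigma2, low_mu_threshold = 0.5,
                         sigma2_floor = 1e-6) {
  s <- sqrt(2 * pmax(sigma2, sigma2_floor) / mu^2)
  s[mu < low_mu_threshold] <- NA_real_
  s
}

#' Per-site emission scores for the three expression states
#'
#' For each site, compares sample coverage to the reference mean. Where the
#' reference mean is at least `low_mu_threshold`, the natural-log fold
#' change `L = ln(max(sample, epsilon) / mu)` is scored under three normal
#' models with common sd `s` (from the delta method) and means `-c`, `0`,
#' `+c`, where `c = z_(1-alpha/2) * s` is the critical shift:
#' stable `= 2 * (1 - Phi(|L| / s))` (two-sided tail under no change),
#' up `= Phi((L - c) / s)`, down `= 1 - Phi((L + c) / s)`. Where the
#' reference mean is below the threshold, the fold-change model is
#' uninformative and the low-coverage rule applies: sample coverage of at
#' least `low_mu_sample_min` reads scores upregulation at `low_mu_prob`
#' (clear activation of silent sequence), anything less scores stable at
#' `low_mu_prob`. Emissions are scores, not densities: only within-site
#' relative magnitudes matter to the HMM.
#'
#' @param sample_cov Sample coverage per site (normalized reads).
#' @param ref A `reference_summary` (or list with `mu`, `sigma2`) aligned to
#'   the same sites.
#' @param params An [emission_params].
#' @return List with `L` (log fold change, `NA` at low-coverage sites) and
#'   `e`, an n x 3 matrix of (down, stable, up) scores in `[0, 1]`.
#' @export
emission_probs <- function(sample_cov, ref, params = emission_params()) {
  mu <- ref$mu; sigma2 <- ref$sigma2
  n <- length(sample_cov)
  stopifnot(length(mu) == n, length(sigma2) == n, all(sample_cov >= 0))
  e <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("down", "stable", "up")))
  L <- rep(NA_real_, n)
  low <- mu < params$low_mu_threshold
  if (any(low)) {
    p <- params$low_mu_prob; q <- (1 - p) / 2
    upward <- low & sample_cov >= params$low_mu_sample_min
    e[upward, ] <- rep(c(q, q, p), each = sum(upward))
    e[low & !upward, ] <- rep(c(q, p, q), each = sum(low & !upward))
  }
  if (any(!low)) {
    i <- which(!low)
    s <- sqrt(2 * pmax(sigma2[i], params$sigma2_floor) / mu[i]^2)
    cc <- stats::qnorm(1 - params$alpha / 2) * s
    Li <- log(pmax(sample_cov[i], params$epsilon) / mu[i])
    L[i] <- Li
    e[i, "stable"] <- 2 * stats::pnorm(-abs(Li) / s)
    if (params$orientation == "monotone") {
      e[i, "up"] <- stats::pnorm((Li - cc) / s)
      e[i, "down"] <- stats::pnorm(-(Li + cc) / s)
    } else {
      e[i, "up"] <- stats::pnorm(-(Li - cc) / s)
      e[i, "down"] <- stats::pnorm((Li + cc) / s)
    }
  }
  list(L = L, e = e)
}

#' Forward-backward posterior decoding
#'
#' Computes per-site posterior state probabilities by the forward-backward
#' algorithm with per-site scaling (numerically safe for chains of many
#' millions of sites). Posterior argmax decoding maximizes the expected
#' number of correctly predicted sites, the property wanted for
#' site-specific differential expression testing (Viterbi is deliberately
#' not offered).
#'
#' @param e n x 3 matrix of per-site emission scores (columns down, stable,
#'   up); scores need not be normalized.
#' @param params An [hmm_params].
#' @param positions Optional site coordinates carried through to the result.
#' @return An object of class `state_track`: list with `positions`,
#'   `posterior` (n x 3, rows summing to 1), `state` (0/1/2 per site, from
#'   [decode_states()]) and `loglik` (log of the total emission-weighted path
#'   sum).
#' @export
forward_backward <- function(e, params = hmm_params(), positions = NULL) {
  e <- as.matrix(e)
  n <- nrow(e)
  stopifnot(n >= 1L, ncol(e) == 3L)
  if (anyNA(e) || any(!is.finite(e))) stop("emissions must be finite")
  bad <- which(rowSums(e) == 0)
  if (length(bad))
    stop("all-zero emission row at site ", bad[1L],
         if (!is.null(positions)) paste0(" (position ", positions[bad[1L]], ")"))
  pi0 <- params$pi0; tr <- params$trans
  al <- matrix(0, n, 3); sc <- numeric(n)
  a <- pi0 * e[1L, ]; sc[1L] <- sum(a); al[1L, ] <- a / sc[1L]
  if (n > 1L) for (t in 2:n) {
    a <- (al[t - 1L, ] %*% tr) * e[t, ]
    sc[t] <- sum(a); al[t, ] <- a / sc[t]
  }
  be <- matrix(0, n, 3); be[n, ] <- 1
  if (n > 1L) for (t in (n - 1L):1L) {
    b <- tr %*% (e[t + 1L, ] * be[t + 1L, ])
    be[t, ] <- b / sc[t + 1L]
  }
  post <- al * be
  post <- post / rowSums(post)
  colnames(post) <- c("down", "stable", "up")
  structure(list(positions = if (is.null(positions)) seq_len(n) else positions,
                 posterior = post, state = decode_states(post),
                 loglik = sum(log(sc))),
            class = "state_track")
}

#' @export
print.state_track <- function(x, ...) {
  tab <- table(factor(x$state, levels = 0:2,
                      labels = c("down", "stable", "up")))
  cat(sprintf("state_track: %d sites (down %d, stable %d, up %d), logLik %.3f\n",
              length(x$state), tab[1L], tab[2L], tab[3L], x$loglik))
  invisible(x)
}

#' Decode states from a posterior matrix
#'
#' Per-site argmax of the posterior; exact ties resolve to the stable state
#' (code 1), the conservative no-change call.
#'
#' @param posterior n x 3 matrix (or a `state_track`).
#' @return Integer vector of state codes: 0 = down, 1 = stable, 2 = up.
#' @export
decode_states <- function(posterior) {
  if (inherits(posterior, "state_track")) posterior <- posterior$posterior
  posterior <- as.matrix(posterior)
  mx <- pmax(posterior[, 1L], posterior[, 2L], posterior[, 3L])
  nmax <- rowSums(posterior == mx)
  st <- max.col(posterior, ties.method = "first") - 1L
  st[nmax > 1L] <- 1L
  st
}

#' Baum-Welch re-estimation of initial and transition probabilities
#'
#' EM over the chain with emissions held fixed: only `pi0` and the
#' transition matrix are re-estimated (the emission model is the fixed
#' statistical model of the data, so only the chain's persistence is
#' learned). The log-likelihood is nondecreasing across iterations; the
#' loop stops when its increase falls below `tol` or after `max_iter`
#' iterations. A single-site chain carries no transition evidence and
#' returns the starting parameters unchanged.
#'
#' @param e n x 3 emission score matrix.
#' @param start Starting [hmm_params].
#' @param max_iter Maximum EM iterations (default 50).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-6).
#' @return An [hmm_params] with attributes `loglik` (per-iteration trace)
#'   and `iterations`.
#' @export
baum_welch_transitions <- function(e, start = hmm_params(), max_iter = 50,
                                   tol = 1e-6) {
  e <- as.matrix(e)
  n <- nrow(e)
  stopifnot(max_iter >= 1)
  if (n < 2L) {
    out <- start
    attr(out, "loglik") <- forward_backward(e, start)$loglik
    attr(out, "iterations") <- 0L
    return(out)
  }
  pi0 <- start$pi0; tr <- start$trans
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    ## E step: scaled forward-backward plus expected transition counts
    al <- matrix(0, n, 3); sc <- numeric(n)
    a <- pi0 * e[1L, ]; sc[1L] <- sum(a); al[1L, ] <- a / sc[1L]
    for (t in 2:n) {
      a <- (al[t - 1L, ] %*% tr) * e[t, ]
      sc[t] <- sum(a); al[t, ] <- a / sc[t]
    }
    be <- matrix(0, n, 3); be[n, ] <- 1
    for (t in (n - 1L):1L) {
      b <- tr %*% (e[t + 1L, ] * be[t + 1L, ])
      be[t, ] <- b / sc[t + 1L]
    }
    ll <- sum(log(sc))
    ## xi[i,j] = tr[i,j] * sum_t alpha[t,i] * e[t+1,j] * beta[t+1,j] / sc[t+1]
    wb <- e[2:n, , drop = FALSE] * be[2:n, , drop = FALSE] / sc[2:n]
    xi <- tr * crossprod(al[1:(n - 1L), , drop = FALSE], wb)
    gamma1 <- al[1L, ] * be[1L, ]
    ## M step
    pi0 <- gamma1 / sum(gamma1)
    tr_new <- xi / rowSums(xi)
    ll_trace <- c(ll_trace, ll)
    converged <- iter > 1L && (ll - ll_trace[iter - 1L]) < tol
    tr <- tr_new
    if (converged) break
  }
  out <- hmm_params(pi0, tr)
  attr(out, "loglik") <- ll_trace
  attr(out, "iterations") <- length(ll_trace)
  out
}
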