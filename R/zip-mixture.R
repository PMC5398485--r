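# Zero-inflated Poisson null and the two-component count mixture used to
# score aggregated per-position mutation counts.

#' Zero-inflated Poisson distribution
#'
#' Probability mass function and random generation for the zero-inflated
#' Poisson (ZIP) distribution: a point mass at zero with weight `pi0`
#' mixed with a Poisson(`lambda`) component of weight `1 - pi0`, so that
#' `P(X = 0) = pi0 + (1 - pi0) exp(-lambda)` and
#' `P(X = j) = (1 - pi0) exp(-lambda) lambda^j / j!` for `j >= 1`.
#'
#' The ZIP is the empirical null for per-position somatic mutation counts
#' within a domain family: most aligned positions carry no variant at all
#' (zero inflation on top of the Poisson's own zero mass), and the
#' remaining background positions accumulate passenger mutations at a low
#' Poisson rate.
#'
#' @param x Vector of non-negative integer counts.
#' @param n Number of draws.
#' @param pi0 Zero-inflation weight in `[0, 1]`.
#' @param lambda Non-negative Poisson rate.
#' @param log If `TRUE`, return log probabilities.
#' @return `dzip` returns probabilities (or log probabilities); `rzip`
#'   returns an integer vector of length `n`.
#' @examples
#' dzip(0, pi0 = 0.3, lambda = 0.5)
#' sum(dzip(0:50, pi0 = 0.3, lambda = 0.5))  # == 1
#' @export
dzip <- function(x, pi0, lambda, log = FALSE) {
  if (any(!is.finite(pi0)) || any(pi0 < 0) || any(pi0 > 1))
    stop("`pi0` must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(lambda)) || any(lambda < 0))
    stop("`lambda` must be non-negative", call. = FALSE)
  if (any(x < 0) || any(x != floor(x)))
    stop("`x` must contain non-negative integers", call. = FALSE)
  n <- max(length(x), length(pi0), length(lambda))
  x <- rep_len(x, n); pi0 <- rep_len(pi0, n); lambda <- rep_len(lambda, n)
  lp <- log1p(-pi0) + stats::dpois(x, lambda, log = TRUE)
  z <- x == 0
  lp[z] <- log(pi0[z] + exp(log1p(-pi0[z]) - lambda[z]))
  if (log) lp else exp(lp)
}

#' @rdname dzip
#' @export
rzip <- function(n, pi0, lambda) {
  ifelse(stats::runif(n) < pi0, 0L, stats::rpois(n, lambda))
}

## log f0(j) for the ZIP null, vectorised over j
.zip_log_pmf <- function(j, pi0, lambda) {
  lp <- log1p(-pi0) + stats::dpois(j, lambda, log = TRUE)
  z <- j == 0
  if (any(z)) lp[z] <- log(pi0 + exp(log1p(-pi0) - lambda))
  lp
}

.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

## EM for a pure ZIP fit (used when the signal component degenerates away)
.fit_zip_only <- function(j, nj, max_iter = 200, tol = 1e-10) {
  N <- sum(nj)
  n0 <- sum(nj[j == 0])
  m <- sum(nj * j) / N
  if (m == 0) return(list(pi0 = 1, lambda = 0, loglik = 0))
  pi0 <- min(max((n0 / N - exp(-m)) / (1 - exp(-m)), 0), 0.999)
  lam <- if (pi0 < 1) m / (1 - pi0) else m
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # tau: P(zero came from the inflation mass | j = 0)
    tau <- pi0 / (pi0 + exp(log1p(-pi0) - lam))
    pi0 <- n0 * tau / N
    denom <- N - n0 * tau
    lam <- if (denom > 0) sum(nj * j) / denom else 0
    ll <- sum(nj * .zip_log_pmf(j, pi0, lam))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(pi0 = pi0, lambda = lam, loglik = ll)
}

#' Fit the ZIP-null / Poisson-signal count mixture
#'
#' Fits, by expectation-maximisation, the two-component mixture
#' `f(j) = p0 f0(j) + p1 f1(j)` to the per-position mutation counts of one
#' domain family in one cancer type, where the null `f0` is zero-inflated
#' Poisson `ZIP(pi0, lambda0)` (non-significantly mutated positions) and
#' the signal `f1` is Poisson(`lambda1`) with the identifiability
#' constraint `lambda1 >= lambda0`.  The fitted mixture is the basis of
#' the local false discovery rate `fdr(t) = p0 f0(t) / f(t)`.
#'
#' Initialisation is deterministic: `pi0` from the excess of zeros over a
#' Poisson moment estimate, `lambda0` from the mean of counts at or below
#' the median non-zero count, `p0 = 0.95`, and
#' `lambda1 = max(2 lambda0, mean of the top decile of counts)`.  The fit
#' degrades gracefully to a pure ZIP null with `p0 = 1` when the fitted
#' signal weight falls below one position (`p1 < 1/N`) or when the
#' mixture fails to beat a pure ZIP null by a BIC margin
#' (`log-likelihood gain < log(N)` for its two extra parameters) — on
#' null-only data the constraint `lambda1 >= lambda0` leaves the two
#' components interchangeable and the mixture weight unidentifiable, so
#' the guard keeps `p0` honest.  All-zero count vectors yield a
#' degenerate pure-zero null, flagged but not an error.
#'
#' @param counts Integer vector of per-position mutation counts (one entry
#'   per model position), or a [build_position_counts()] element.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param min_positions Minimum number of positions required; shorter
#'   inputs are skipped (returns `NULL` with a warning).
#' @param support_cap Optional upper bound for the evaluated count
#'   support; defaults to `max(j_max, lambda1 + 10 sqrt(lambda1), 20)`.
#' @return An object of class `zip_mixture`: list with elements `pi0`,
#'   `lambda0`, `p0`, `p1`, `lambda1`, `loglik`, `converged`, `n_iter`,
#'   `degenerate`, `n` (number of positions), `support`, `f0`, `f1`, `f`
#'   (densities over the support), `fdr_local` (monotonised local fdr over
#'   the support) and `fdr_tail` (tail-area analogue); or `NULL` if the
#'   input has fewer than `min_positions` positions.
#' @examples
#' set.seed(1)
#' fit <- fit_null_mixture(rzip(500, 0.3, 0.5))
#' fit$p0
#' @export
fit_null_mixture <- function(counts, max_iter = 500, tol = 1e-8,
                             min_positions = 10, support_cap = NULL) {
  if (inherits(counts, "position_counts")) counts <- counts$counts
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 0))
    stop("`counts` must be non-negative integers", call. = FALSE)
  N <- length(counts)
  if (N < min_positions) {
    warning(sprintf("only %d positions (< min_positions = %d); fit skipped",
                    N, min_positions), call. = FALSE)
    return(NULL)
  }
  tab <- tabulate(counts + 1L)
  j <- which(tab > 0) - 1L
  nj <- tab[tab > 0]
  jmax <- max(j)

  if (jmax == 0L) {                      # all-zero counts: pure zero mass
    return(.finish_fit(pi0 = 1, lambda0 = 0, p0 = 1, lambda1 = NA_real_,
                       loglik = 0, converged = TRUE, n_iter = 0L,
                       degenerate = TRUE, N = N, jmax = 0L,
                       support_cap = support_cap))
  }

  # deterministic initialisation
  m <- sum(nj * j) / N
  n0 <- sum(nj[j == 0])
  pi0 <- min(max((n0 / N - exp(-m)) / max(1 - exp(-m), 1e-12), 0.01), 0.95)
  nzmed <- stats::median(rep.int(j, nj)[rep.int(j, nj) > 0])
  low <- rep.int(j, nj)[rep.int(j, nj) <= nzmed]
  lam0 <- max(mean(low), 1e-3)
  topq <- stats::quantile(rep.int(j, nj), 0.9, names = FALSE, type = 1)
  lam1 <- max(2 * lam0, mean(rep.int(j, nj)[rep.int(j, nj) >= topq]))
  p0 <- 0.95

  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    lf0 <- .zip_log_pmf(j, pi0, lam0)
    lf1 <- stats::dpois(j, lam1, log = TRUE)
    a0 <- log(p0) + lf0
    a1 <- log1p(-p0) + lf1
    lden <- .logsumexp2(a0, a1)
    r1 <- exp(a1 - lden)               # posterior weight of the signal component
    r1[!is.finite(r1)] <- 0
    ll <- sum(nj * lden)
    ll_trace <- c(ll_trace, ll)

    # M step
    S1 <- sum(nj * r1)
    p1_new <- S1 / N
    w0 <- nj * (1 - r1)
    tau <- pi0 / (pi0 + exp(log1p(-pi0) - lam0))   # inflation share of null zeros
    sw0 <- sum(w0)
    pi0_new <- if (sw0 > 0) sum(w0[j == 0]) * tau / sw0 else 1
    u <- w0 * ifelse(j == 0, 1 - tau, 1)           # Poisson-member weight in null
    lam0_new <- if (sum(u) > 0) sum(u * j) / sum(u) else 0
    lam1_new <- if (S1 > 0) sum(nj * r1 * j) / S1 else lam0_new
    lam1_new <- max(lam1_new, lam0_new)            # identifiability

    pi0 <- min(max(pi0_new, 0), 1)
    lam0 <- max(lam0_new, 0)
    lam1 <- lam1_new
    p0 <- min(max(1 - p1_new, 0), 1)

    if (is.finite(ll_old)) {
      rel <- abs(ll - ll_old) / (abs(ll_old) + 1)
      if (rel < tol) { converged <- TRUE; break }
    }
    ll_old <- ll
  }
  loglik <- sum(nj * .logsumexp2(log(p0) + .zip_log_pmf(j, pi0, lam0),
                                 log1p(-p0) + stats::dpois(j, lam1, log = TRUE)))

  # Graceful degradation to a pure ZIP null: either the signal weight
  # fell below one position, or the two-component fit does not earn its
  # two extra parameters (lambda1 ~ lambda0 makes the components
  # interchangeable on null-only data, arbitrarily splitting p0).  The
  # BIC margin log(N) decides the latter deterministically.
  z <- .fit_zip_only(j, nj)
  out <- if ((1 - p0) < 1 / N || (loglik - z$loglik) < log(N)) {
    .finish_fit(pi0 = z$pi0, lambda0 = z$lambda, p0 = 1,
                lambda1 = NA_real_, loglik = z$loglik,
                converged = TRUE, n_iter = it, degenerate = FALSE,
                N = N, jmax = jmax, support_cap = support_cap)
  } else {
    .finish_fit(pi0 = pi0, lambda0 = lam0, p0 = p0, lambda1 = lam1,
                loglik = loglik, converged = converged, n_iter = it,
                degenerate = FALSE, N = N, jmax = jmax,
                support_cap = support_cap)
  }
  out$ll_trace <- ll_trace   # per-iteration observed-data log-likelihood
  out
}

## assemble the zip_mixture object: densities over the support plus the
## monotonised local fdr and its tail-area analogue
.finish_fit <- function(pi0, lambda0, p0, lambda1, loglik, converged, n_iter,
                        degenerate, N, jmax, support_cap = NULL) {
  top <- max(jmax, 20,
             if (is.finite(lambda1)) ceiling(lambda1 + 10 * sqrt(lambda1)) else 0,
             ceiling(lambda0 + 10 * sqrt(max(lambda0, 1))))
  if (!is.null(support_cap)) top <- max(jmax, min(top, support_cap))
  support <- 0:top
  f0 <- dzip(support, pi0, lambda0)
  f1 <- if (is.finite(lambda1)) stats::dpois(support, lambda1) else rep(0, length(support))
  f <- p0 * f0 + (1 - p0) * f1

  raw <- ifelse(f > 0, pmin(1, p0 * f0 / f), ifelse(f0 > 0, 1, 0))
  if (p0 >= 1) raw <- rep(1, length(support))
  fdr_local <- raw
  if (length(support) > 1)             # cumulative minimum over t >= 1
    fdr_local[-1] <- cummin(raw[-1])

  S0 <- rev(cumsum(rev(f0)))           # P0(J >= t) over the capped support
  S <- rev(cumsum(rev(f)))
  fdr_tail <- ifelse(S > 0, pmin(1, p0 * S0 / S), 1)
  if (p0 >= 1) fdr_tail <- rep(1, length(support))

  structure(list(pi0 = pi0, lambda0 = lambda0, p0 = p0, p1 = 1 - p0,
                 lambda1 = lambda1, loglik = loglik, converged = converged,
                 n_iter = n_iter, degenerate = degenerate, n = N,
                 jmax = jmax, support = support, f0 = f0, f1 = f1, f = f,
                 fdr_local = fdr_local, fdr_tail = fdr_tail),
            class = "zip_mixture")
}

#' @export
print.zip_mixture <- function(x, ...) {
  cat("ZIP-null count mixture fit\n")
  cat(sprintf("  null:   ZIP(pi0 = %.4f, lambda0 = %.4f), weight p0 = %.4f\n",
              x$pi0, x$lambda0, x$p0))
  if (is.finite(x$lambda1))
    cat(sprintf("  signal: Poisson(lambda1 = %.4f), weight p1 = %.4f\n",
                x$lambda1, x$p1))
  cat(sprintf("  n = %d positions, jmax = %d, loglik = %.3f, %s (%d iter)%s\n",
              x$n, x$jmax, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Local false discovery rate at a count level
#'
#' Evaluates `fdr(t) = min(1, p0 f0(t) / f(t))` from a fitted
#' [fit_null_mixture()] object, after a monotone non-increasing
#' regularisation (cumulative minimum) over `t >= 1`, so that hotspot
#' calls are nested in the count: if count `t` is significant, so is any
#' `t' >= t`.
#'
#' @param t Vector of non-negative integer count levels.
#' @param fit A `zip_mixture` object.
#' @return Numeric vector of local fdr values in `[0, 1]`, never `NaN`.
#' @export
local_fdr <- function(t, fit) {
  stopifnot(inherits(fit, "zip_mixture"))
  if (any(t < 0) || any(t != floor(t)))
    stop("`t` must contain non-negative integers", call. = FALSE)
  out <- numeric(length(t))
  inside <- t <= max(fit$support)
  out[inside] <- fit$fdr_local[t[inside] + 1L]
  if (any(!inside)) {
    # beyond the capped support the monotone envelope can only shrink
    tail_min <- fit$fdr_local[length(fit$fdr_local)]
    tt <- t[!inside]
    lf0 <- .zip_log_pmf(tt, fit$pi0, fit$lambda0)
    lf <- if (fit$p0 >= 1 || !is.finite(fit$lambda1)) lf0 else
      .logsumexp2(log(fit$p0) + lf0,
                  log1p(-fit$p0) + stats::dpois(tt, fit$lambda1, log = TRUE))
    raw <- exp(log(max(fit$p0, .Machine$double.xmin)) + lf0 - lf)
    raw[!is.finite(raw)] <- 0
    out[!inside] <- pmin(pmin(1, raw), tail_min)
    if (fit$p0 >= 1) out[!inside] <- 1
  }
  out
}

#' Tail-area false discovery rate at a count level
#'
#' Cumulative analogue of [local_fdr()]:
#' `q(t) = min(1, p0 P0(J >= t) / P(J >= t))`, a q-value-style statistic
#' reported alongside the local fdr.
#'
#' @inheritParams local_fdr
#' @return Numeric vector of tail-area fdr values in `[0, 1]`.
#' @export
tail_fdr <- function(t, fit) {
  stopifnot(inherits(fit, "zip_mixture"))
  if (any(t < 0) || any(t != floor(t)))
    stop("`t` must contain non-negative integers", call. = FALSE)
  out <- numeric(length(t))
  inside <- t <= max(fit$support)
  out[inside] <- fit$fdr_tail[t[inside] + 1L]
  out[!inside] <- if (fit$p0 >= 1) 1 else fit$fdr_tail[length(fit$fdr_tail)]
  out
}
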