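# Discrete power-law fitting for degree sequences: maximum-likelihood
# exponent, Kolmogorov-Smirnov xmin selection, and a semi-parametric
# bootstrap goodness-of-fit p-value. Follows the standard procedure for
# testing power laws in empirical data (discrete formulation, since node
# degrees are integers).

# Hurwitz zeta  sum_{k>=0} (a+k)^(-s)  for s > 1, via direct summation plus
# an Euler-Maclaurin tail; absolute accuracy ~1e-12 for s in (1, 20].
hurwitz_zeta <- function(s, a, terms = 200L) {
  k <- 0:(terms - 1L)
  head_sum <- sum((a + k)^(-s))
  z <- a + terms
  tail <- z^(1 - s) / (s - 1) + 0.5 * z^(-s) + s * z^(-s - 1) / 12 -
    s * (s + 1) * (s + 2) * z^(-s - 3) / 720
  head_sum + tail
}

# MLE of the exponent for a discrete power law on {xmin, xmin+1, ...}.
# sum_log is sum(log(x_tail)), n the tail size.
plfit_alpha <- function(sum_log, n, xmin) {
  optimize(function(alpha) n * log(hurwitz_zeta(alpha, xmin)) + alpha * sum_log,
           interval = c(1.01, 12), tol = 1e-5)$minimum
}

# KS distance between the empirical tail CDF and the fitted discrete
# power-law CDF, evaluated on the integer support xmin..max(x).
plfit_ks <- function(x_tail, alpha, xmin) {
  support <- xmin:max(x_tail)
  pmf <- support^(-alpha) / hurwitz_zeta(alpha, xmin)
  fit_cdf <- cumsum(pmf)
  emp_cdf <- cumsum(tabulate(x_tail - xmin + 1L, nbins = length(support))) /
    length(x_tail)
  max(abs(emp_cdf - fit_cdf))
}

# Full fit: scan candidate xmin values, keep the one minimizing the KS
# distance. Candidates must leave at least `min_tail` observations and
# `min_distinct` distinct values in the tail.
plfit <- function(x, min_tail = 10L, min_distinct = 2L) {
  x <- sort(as.integer(x))
  cand <- unique(x)
  ok <- vapply(cand, function(xm) {
    tail_vals <- x[x >= xm]
    length(tail_vals) >= min_tail && length(unique(tail_vals)) >= min_distinct
  }, logical(1))
  cand <- cand[ok]
  if (length(cand) == 0) {
    stopf("power-law fit undefined: no candidate xmin leaves a usable tail",
          class = "gcntools_degenerate_fit_error")
  }
  best <- NULL
  for (xm in cand) {
    tail_vals <- x[x >= xm]
    alpha <- plfit_alpha(sum(log(tail_vals)), length(tail_vals), xm)
    d <- plfit_ks(tail_vals, alpha, xm)
    if (is.null(best) || d < best$ks_distance) {
      best <- list(alpha = alpha, xmin = xm, ks_distance = d,
                   n_tail = length(tail_vals))
    }
  }
  best
}

# Draw n variates from the fitted discrete power law by inverse CDF.
rpowerlaw_discrete <- function(n, alpha, xmin, tail_eps = 1e-9) {
  # support cap where the remaining tail mass is negligible
  kmax <- max(1000L, ceiling(xmin * (tail_eps * (alpha - 1))^(-1 / (alpha - 1))))
  kmax <- min(kmax, 5e6)
  support <- xmin:kmax
  pmf <- support^(-alpha) / hurwitz_zeta(alpha, xmin)
  cdf <- cumsum(pmf)
  cdf[length(cdf)] <- 1
  support[findInterval(runif(n), c(0, cdf), rightmost.closed = TRUE)]
}

#' Fit a discrete power law to a degree sequence with a K-S bootstrap test
#'
#' Fits `P(k) ~ k^(-alpha)` for `k >= xmin` to positive integer degrees by
#' discrete maximum likelihood, choosing `xmin` to minimize the
#' Kolmogorov-Smirnov (K-S) distance between the empirical and fitted tail
#' CDFs. With `bootstrap_reps > 0` a semi-parametric bootstrap
#' goodness-of-fit p-value is computed: synthetic data sets draw tail values
#' from the fitted law and body values from the empirical body, each is
#' refitted, and `p` is the fraction of synthetic K-S distances at least as
#' large as the observed one. Small `p` (conventionally < 0.1) rejects the
#' power law; scale-free status is plausible otherwise.
#'
#' @param degrees Positive integer vector (a network degree sequence). Zeros
#'   are dropped with a message.
#' @param bootstrap_reps Number of bootstrap replicates (0 = no p-value).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `powerlaw_fit`: list with `alpha`, `xmin`,
#'   `ks_distance`, `p_value` (`NA` if `bootstrap_reps = 0`), `n_tail`, and
#'   `bootstrap_reps`.
#' @examples
#' net <- generate_scale_free_graph(500, 2, seed = 1)
#' powerlaw_fit_ks(igraph::degree(net), bootstrap_reps = 0)
#' @export
powerlaw_fit_ks <- function(degrees, bootstrap_reps = 100, seed = 1) {
  assert_number(bootstrap_reps, "bootstrap_reps", lower = 0, integer = TRUE)
  x <- as.integer(degrees)
  if (length(x) == 0 || any(x < 0)) stopf("'degrees' must be non-negative integers")
  if (any(x == 0)) {
    message(sprintf("powerlaw_fit_ks: dropping %d zero degree(s)", sum(x == 0)))
    x <- x[x > 0]
  }
  if (length(unique(x)) < 2) {
    stopf("power-law fit undefined: all degrees equal",
          class = "gcntools_degenerate_fit_error")
  }
  fit <- plfit(x, min_tail = 10L, min_distinct = 10L)
  p_value <- NA_real_
  if (bootstrap_reps > 0) {
    n <- length(x)
    body <- x[x < fit$xmin]
    p_tail <- fit$n_tail / n
    exceed <- with_seed(seed, {
      vapply(seq_len(bootstrap_reps), function(rep) {
        from_tail <- if (length(body)) runif(n) < p_tail else rep(TRUE, n)
        synth <- integer(n)
        if (any(from_tail)) {
          synth[from_tail] <- rpowerlaw_discrete(sum(from_tail),
                                                 fit$alpha, fit$xmin)
        }
        if (any(!from_tail)) {
          synth[!from_tail] <- sample(body, sum(!from_tail), replace = TRUE)
        }
        refit <- tryCatch(plfit(synth, min_tail = 10L, min_distinct = 2L),
                          gcntools_degenerate_fit_error = function(e) NULL)
        if (is.null(refit)) return(NA)
        refit$ks_distance >= fit$ks_distance
      }, logical(1))
    })
    p_value <- mean(exceed, na.rm = TRUE)
  }
  structure(list(alpha = fit$alpha, xmin = fit$xmin,
                 ks_distance = fit$ks_distance, p_value = p_value,
                 n_tail = fit$n_tail, bootstrap_reps = bootstrap_reps),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("powerlaw_fit: alpha = %.3f, xmin = %d, KS = %.4f, n_tail = %d%s\n",
              x$alpha, x$xmin, x$ks_distance, x$n_tail,
              if (is.na(x$p_value)) "" else sprintf(", p = %.3f", x$p_value)))
  invisible(x)
}
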