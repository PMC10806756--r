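#' Tail probability of a weighted sum of 1-df chi-squares
#'
#' Computes `P(sum_k lambda_k X_k > q)` for independent 1-df chi-square
#' variables `X_k`, the null distribution of the HEIDI and multi-SNP SMR
#' statistics (the weights being eigenvalues of the LD-induced correlation
#' matrix of the per-SNP z statistics). Uses Imhof's exact inversion
#' integral, evaluated by composite Simpson quadrature on a grid fine enough
#' for the integrand's oscillation and truncated where the oscillation
#' envelope falls below the target precision; a moment-matched
#' (Satterthwaite-Welch) scaled chi-square approximation is the numerical
#' fallback for degenerate inputs.
#'
#' @param q Observed statistic (scalar, >= 0).
#' @param lambda Numeric vector of nonnegative weights; near-zero weights are
#'   dropped.
#' @return Upper-tail probability in \[0, 1\].
#' @export
quadform_pvalue <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-8 * max(lambda, 1)]
  if (length(lambda) == 0L) return(1)
  if (q <= 0) return(1)
  if (length(lambda) == 1L) {
    return(pchisq(q / lambda, df = 1, lower.tail = FALSE))
  }
  if (diff(range(lambda)) < 1e-10 * max(lambda)) {
    return(pchisq(q / lambda[1], df = length(lambda), lower.tail = FALSE))
  }
  p <- tryCatch(.imhof_tail(q, lambda), error = function(e) NA_real_)
  if (is.na(p) || p < -1e-6 || p > 1 + 1e-6) p <- .satterthwaite_tail(q, lambda)
  min(max(p, .Machine$double.xmin), 1)
}

# Imhof (1961): P(Q > q) = 1/2 + (1/pi) * Int_0^inf sin(theta(u))/(u rho(u)) du
# with theta(u) = 0.5*sum(atan(lambda_k u)) - 0.5*q*u and
# rho(u) = prod (1 + lambda_k^2 u^2)^(1/4).
.imhof_tail <- function(q, lambda, eps = 1e-9) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    val <- sin(theta) / (u * rho)
    val[!is.finite(val)] <- 0
    val
  }
  envelope <- function(u) 1 / (u * exp(0.25 * sum(log1p(lambda^2 * u^2))))
  # the phase derivative is bounded by (q + sum lambda)/2: resolve the
  # fastest oscillation with >= 40 points per period
  freq <- 0.5 * (q + sum(lambda))
  h <- (2 * pi / freq) / 40
  # truncate where one further oscillation contributes < eps (consecutive
  # half-periods nearly cancel, so the local envelope bounds the remainder)
  period <- 4 * pi / max(q, 0.25)
  U <- 10 * h
  while (envelope(U) * period > eps && U < 2e5) U <- U * 1.4
  n <- ceiling(U / h)
  if (n %% 2L == 1L) n <- n + 1L
  if (n > 4e6) stop("oscillation grid too large")
  u <- seq(0, U, length.out = n + 1L)
  f <- c(0.5 * sum(lambda) - 0.5 * q, integrand(u[-1L]))
  w <- rep(c(2, 4), length.out = n + 1L)
  w[c(1L, n + 1L)] <- 1
  int <- (U / n) / 3 * sum(w * f)
  0.5 + int / pi
}

.satterthwaite_tail <- function(q, lambda) {
  # match mean and variance with a*chi2_d: a = sum(l^2)/sum(l), d = sum(l)^2/sum(l^2)
  a <- sum(lambda^2) / sum(lambda)
  d <- sum(lambda)^2 / sum(lambda^2)
  pchisq(q / a, df = d, lower.tail = FALSE)
}
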