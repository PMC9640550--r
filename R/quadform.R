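# Tail probabilities of positive linear combinations of chi-square(1)
# variables: Q = sum_k lambda_k * chisq_1. These arise as the null
# distribution of the variance-component score statistic and of the
# weighted p-value combination statistic.

#' Upper-tail probability of a weighted sum of chi-square(1) variables
#'
#' Computes `P(sum_k lambda_k * X_k > q)` with `X_k` independent 1-df
#' chi-squares, by numerical inversion of the characteristic function
#' (the Imhof/Davies integral). Equal-weight spectra reduce to a scaled
#' chi-square and are evaluated in closed form.
#'
#' @param q Observed statistic (scalar).
#' @param lambda Non-negative weights; at least one must be positive.
#' @param acc Target absolute accuracy of the integration.
#' @return A list with elements `p` (the tail probability, clipped to
#'   `(1e-300, 1]`) and `ok` (`FALSE` when the integration failed or
#'   returned a value outside `(0, 1]`, signalling that the caller
#'   should fall back to moment matching).
#' @examples
#' davies_pvalue(qchisq(0.95, df = 2), c(1, 1))$p  # 0.05
#' @export
davies_pvalue <- function(q, lambda, acc = 1e-9) {
  stopifnot(length(q) == 1L, is.finite(q))
  lambda <- lambda[lambda > 0]
  if (!length(lambda)) stop_config("davies_pvalue: no positive eigenvalues")
  if (q <= 0) return(list(p = 1, ok = TRUE))

  # Equal weights: Q/lambda ~ chi-square with m df, exact.
  if (diff(range(lambda)) <= 1e-12 * max(lambda)) {
    p <- stats::pchisq(q / lambda[1L], df = length(lambda), lower.tail = FALSE)
    return(list(p = clip_p(p), ok = TRUE))
  }

  # Gil-Pelaez inversion: P(Q > q) = 1/2 + (1/pi) * I with
  #   I = int_0^inf sin(theta(u)) / (u * rho(u)) du,
  #   theta(u) = 0.5 sum atan(lambda u) - 0.5 q u,
  #   rho(u) = prod (1 + lambda^2 u^2)^(1/4).
  # The integrand oscillates with a polynomially decaying envelope, so a
  # single adaptive pass diverges; instead the half-line is cut into
  # half-period panels integrated by Gauss-Legendre, and the alternating
  # partial sums are accelerated by iterated averaging.
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    log_rho <- 0.25 * colSums(log1p(outer(lambda, u)^2))
    out <- sin(theta) / (u * exp(log_rho))
    out[u == 0] <- 0.5 * (sum(lambda) - q)
    out
  }
  gl <- .gauss_legendre_24
  # Panels of one asymptotic half-period (the phase -qu/2 changes by pi),
  # so successive panel integrals alternate in sign; each panel is
  # integrated by composite Gauss-Legendre with at most one total phase
  # wavelength per sub-interval (the atan transient adds 0.5*sum(lambda)
  # to the phase rate near the origin).
  period <- 2 * pi / q
  nsub <- min(256L, max(1L, ceiling((0.5 * sum(lambda) + 0.5 * q) *
                                      period / (2 * pi))))
  hs <- period / (2 * nsub)
  offsets <- rep((seq_len(nsub) - 1) * period / nsub, each = 24L) +
    hs * (gl$nodes + 1)
  wts <- rep.int(gl$weights, nsub)
  batch <- 64L
  max_batches <- 8L
  pieces <- numeric(0)
  done <- FALSE
  for (bt in seq_len(max_batches)) {
    k <- (bt - 1L) * batch + seq_len(batch)
    a <- (k - 1) * period                       # panel left edges
    u <- rep(a, each = 24L * nsub) + offsets
    f <- integrand(u) * wts
    pieces <- c(pieces, hs * colSums(matrix(f, nrow = 24L * nsub)))
    if (abs(pieces[length(pieces)]) < acc / 10) { done <- TRUE; break }
  }
  sums <- cumsum(pieces)
  n <- length(sums)
  if (done && abs(pieces[n]) < acc / 10) {
    val <- sums[n]
    conv <- TRUE
  } else {
    val <- .euler_average(sums[(n - 63L):n])
    val2 <- .euler_average(sums[(n - 55L):(n - 8L)])
    conv <- is.finite(val) && is.finite(val2) &&
      abs(val - val2) < max(acc, 1e-10) * 10
  }
  p <- 0.5 + val / pi
  if (conv && is.finite(p) && p >= -1e-8 && p <= 1 + 1e-8 &&
      p >= 1e-8) {
    return(list(p = clip_p(p), ok = TRUE))
  }
  # Far tail (or unstable inversion): Lugannani-Rice saddlepoint, whose
  # relative error is small exactly where the inversion loses absolute
  # accuracy.
  sp <- .saddlepoint_tail(q, lambda)
  if (is.finite(sp)) list(p = clip_p(sp), ok = TRUE)
  else list(p = NA_real_, ok = FALSE)
}

# Lugannani-Rice tail approximation for sum lambda_k chisq_1.
.saddlepoint_tail <- function(q, lambda) {
  K <- function(t) -0.5 * sum(log1p(-2 * t * lambda))
  K1 <- function(t) sum(lambda / (1 - 2 * t * lambda))
  K2 <- function(t) sum(2 * lambda^2 / (1 - 2 * t * lambda)^2)
  mu <- sum(lambda)
  if (abs(q - mu) < 1e-8 * mu) return(NA_real_)
  upper <- 1 / (2 * max(lambda)) * (1 - 1e-12)
  root <- tryCatch(
    stats::uniroot(function(t) K1(t) - q, lower = -1e4, upper = upper,
                   tol = 1e-14)$root,
    error = function(e) NA_real_)
  if (!is.finite(root)) return(NA_real_)
  w <- sign(root) * sqrt(2 * (root * q - K(root)))
  v <- root * sqrt(K2(root))
  if (abs(v) < 1e-12 || abs(w) < 1e-12) return(NA_real_)
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

# 24-point Gauss-Legendre rule on [-1, 1].
.gauss_legendre_24 <- local({
  j <- seq_len(23)
  b <- j / sqrt(4 * j^2 - 1)
  J <- matrix(0, 24, 24)
  J[cbind(j, j + 1)] <- b
  J[cbind(j + 1, j)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
})

# Euler-style iterated averaging: the stable accelerated limit of an
# asymptotically alternating partial-sum sequence.
.euler_average <- function(s) {
  while (length(s) > 1) s <- (s[-1] + s[-length(s)]) / 2
  s
}

#' Moment-matching approximation to the weighted chi-square tail
#'
#' Liu-type approximation matching the first two moments plus skewness
#' (or kurtosis when the spectrum is too light-tailed) to a noncentral
#' chi-square. Used as the fallback when the characteristic-function
#' inversion in [davies_pvalue()] fails.
#'
#' @inheritParams davies_pvalue
#' @return Tail probability (scalar).
#' @export
liu_pvalue <- function(q, lambda) {
  lambda <- lambda[lambda > 0]
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    a <- 1 / s1
    d <- 0
    l <- c2^3 / c3^2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + d; sigma_x <- sqrt(2) * sqrt(l + 2 * d)
  tstar <- (q - mu_q) / sigma_q
  clip_p(stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = d,
                       lower.tail = FALSE))
}

#' Weighted chi-square tail with automatic fallback
#'
#' @inheritParams davies_pvalue
#' @return List with `p` and `fallback` (`TRUE` when the Liu
#'   approximation was used).
#' @export
quadform_pvalue <- function(q, lambda, acc = 1e-9) {
  d <- davies_pvalue(q, lambda, acc = acc)
  if (d$ok) list(p = d$p, fallback = FALSE)
  else list(p = liu_pvalue(q, lambda), fallback = TRUE)
}

#' Cauchy combination (ACAT) of p-values
#'
#' Combines possibly dependent p-values by averaging their Cauchy
#' transforms; tiny p-values use the asymptote `tan(pi(0.5 - p)) ~ 1/(pi p)`
#' for numerical stability.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @param weights Optional non-negative weights, normalised internally.
#' @return Combined p-value in `(0, 1]`.
#' @export
cauchy_combine <- function(p, weights = NULL) {
  stopifnot(all(p > 0 & p <= 1))
  if (length(p) == 1L) return(p)
  w <- weights %||% rep(1, length(p))
  w <- w / sum(w)
  # asymptotes at both ends avoid the tanpi poles
  t <- numeric(length(p))
  lo <- p < 1e-15; hi <- p > 1 - 1e-15; mid <- !lo & !hi
  t[mid] <- tanpi(0.5 - p[mid])
  t[lo] <- 1 / (p[lo] * pi)
  t[hi] <- -1 / (pmax(1 - p[hi], 1e-300) * pi)
  stat <- sum(w * t)
  if (!is.finite(stat)) return(if (stat > 0) P_FLOOR else 1)
  if (stat > 1e15) return(clip_p(1 / (stat * pi)))
  clip_p(0.5 - atan(stat) / pi)
}
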