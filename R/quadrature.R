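# Adaptive Gauss-Hermite quadrature machinery.
#
# All marginal likelihoods in this package are integrals of a product of
# binomial probabilities against a standard normal density in a standardised
# random effect z.  They are computed with quadrature nodes recentred at the
# per-study mode of the log-integrand and rescaled by its curvature; one node
# per axis is the Laplace approximation.

.gh_cache <- new.env(parent = emptyenv())

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for the weight function `exp(-x^2)`, computed by the
#' Golub-Welsch algorithm (eigendecomposition of the Jacobi matrix).
#'
#' @param n number of nodes (>= 1).
#' @return A list with numeric vectors `nodes` and `weights` satisfying
#'   `sum(weights * f(nodes)) ~ integral of exp(-x^2) f(x)`.
#' @examples
#' r <- gh_rule(7)
#' sum(r$weights)  # integral of exp(-x^2) = sqrt(pi)
#' @export
gh_rule <- function(n) {
  stopifnot(n >= 1)
  key <- as.character(n)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  if (n == 1L) {
    rule <- list(nodes = 0, weights = sqrt(pi))
  } else {
    i <- seq_len(n - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- sqrt(i / 2)
    J[cbind(i + 1, i)] <- sqrt(i / 2)
    ev <- eigen(J, symmetric = TRUE)
    ord <- order(ev$values)
    rule <- list(nodes = ev$values[ord],
                 weights = sqrt(pi) * ev$vectors[1, ord]^2)
  }
  .gh_cache[[key]] <- rule
  rule
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp for a matrix (k studies x Q nodes).
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- mx[!is.finite(mx)]
  out
}

# One-dimensional adaptive GH, vectorised over studies.
#   h(z)  : k-vector log-integrand (including the N(0,1) density term)
#   h1,h2 : first and second derivatives of h, same shape
# Returns the k-vector of log-integrals log int exp(h(z)) dz.
agh1_log <- function(h, h1, h2, n_agq, k, z0 = NULL) {
  z <- if (is.null(z0)) rep(0, k) else z0
  for (it in 1:50) {
    g <- h1(z); H <- h2(z)
    H <- pmin(H, -1e-8)
    step <- g / H
    step <- pmax(pmin(step, 4), -4)
    z <- z - step
    if (max(abs(step)) < 1e-10) break
  }
  sigma <- 1 / sqrt(-pmin(h2(z), -1e-8))
  rule <- gh_rule(n_agq)
  lw <- log(rule$weights) + rule$nodes^2
  vals <- matrix(0, k, n_agq)
  for (q in seq_len(n_agq))
    vals[, q] <- lw[q] + h(z + sqrt(2) * sigma * rule$nodes[q])
  log(sqrt(2) * sigma) + row_logsumexp(vals)
}

# Two-dimensional adaptive GH, vectorised over studies.
#   h(z1, z2)     : k-vector log-integrand (including the N(0, I2) term)
#   grad(z1, z2)  : list(g1, g2)
#   hess(z1, z2)  : list(h11, h12, h22)  (negative definite at the mode)
agh2_log <- function(h, grad, hess, n_agq, k) {
  z1 <- rep(0, k); z2 <- rep(0, k)
  for (it in 1:80) {
    g <- grad(z1, z2); H <- hess(z1, z2)
    a <- -H$h11; b <- -H$h12; c <- -H$h22          # positive definite -hess
    det <- pmax(a * c - b^2, 1e-12)
    s1 <- (c * g$g1 - b * g$g2) / det
    s2 <- (a * g$g2 - b * g$g1) / det
    s1 <- pmax(pmin(s1, 4), -4); s2 <- pmax(pmin(s2, 4), -4)
    z1 <- z1 + s1; z2 <- z2 + s2
    if (max(abs(s1), abs(s2)) < 1e-10) break
  }
  H <- hess(z1, z2)
  a <- -H$h11; b <- -H$h12; c <- -H$h22
  det <- pmax(a * c - b^2, 1e-12)
  # lower Cholesky of H^{-1}
  i11 <- c / det; i12 <- -b / det; i22 <- a / det
  L11 <- sqrt(pmax(i11, 1e-12))
  L21 <- i12 / L11
  L22 <- sqrt(pmax(i22 - L21^2, 1e-12))
  rule <- gh_rule(n_agq)
  lw <- log(rule$weights) + rule$nodes^2
  vals <- matrix(0, k, n_agq * n_agq)
  q <- 0L
  for (q1 in seq_len(n_agq)) for (q2 in seq_len(n_agq)) {
    q <- q + 1L
    x1 <- rule$nodes[q1]; x2 <- rule$nodes[q2]
    vals[, q] <- lw[q1] + lw[q2] +
      h(z1 + sqrt(2) * L11 * x1, z2 + sqrt(2) * (L21 * x1 + L22 * x2))
  }
  log(2 * L11 * L22) + row_logsumexp(vals)
}

# Binomial log-pmf in terms of the logit; vectorised, stable.
# log C(n, e) + e*eta - n*log(1 + exp(eta))
ldbinom_logit <- function(e, n, eta) {
  lchoose(n, e) + e * eta - n * log1p(exp(-abs(eta))) -
    n * pmax(eta, 0)
}
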