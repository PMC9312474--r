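## Conway-Maxwell-Poisson distribution: pmf proportional to
## lambda^y / (y!)^nu.  nu = 1 recovers the Poisson; nu < 1 is
## overdispersed, nu > 1 underdispersed.

## log normalizing constant log Z(lambda, nu) = log sum_j lambda^j/(j!)^nu,
## by direct series summation with log-sum-exp stabilization.  The series
## is summed until a term falls below 1e-12 of the running sum past the
## mode (cap 1e4 terms).
.com_log_z <- function(lambda, nu, max_terms = 1e4, rel_tol = 1e-12) {
  stopifnot(lambda > 0, nu > 0)
  log_lambda <- log(lambda)
  mode_guess <- lambda^(1 / nu)
  lt <- 0         # log term at j = 0
  m <- 0          # running max of log terms
  lsum <- 1       # sum of exp(log term - m), includes the j = 0 term
  j <- 0
  repeat {
    j <- j + 1
    if (j > max_terms)
      stop("COM-Poisson normalizing series did not converge within ",
           max_terms, " terms")
    lt <- j * log_lambda - nu * lgamma(j + 1)
    if (lt > m) {
      lsum <- lsum * exp(m - lt) + 1
      m <- lt
    } else {
      lsum <- lsum + exp(lt - m)
    }
    if (j > mode_guess && lt - m < log(rel_tol)) break
  }
  m + log(lsum)
}

#' COM-Poisson log probability mass
#'
#' Log of `P(Y = y)` for the Conway-Maxwell-Poisson distribution with rate
#' parameter `lambda` and dispersion `nu` (pmf proportional to
#' `lambda^y / (y!)^nu`).  The normalizing constant is computed by series
#' summation with log-sum-exp stabilization, truncated when a term falls
#' below `1e-12` of the running sum (cap `1e4` terms).
#'
#' @param y Non-negative integer quantiles (vectorized).
#' @param lambda Positive rate parameter.
#' @param nu Positive dispersion parameter; `nu = 1` gives the Poisson,
#'   `nu < 1` overdispersion, `nu > 1` underdispersion.
#' @return Numeric vector of log-probabilities.
#' @examples
#' com_poisson_logpmf(0:3, lambda = 2, nu = 1) - dpois(0:3, 2, log = TRUE)
#' @export
com_poisson_logpmf <- function(y, lambda, nu) {
  stopifnot(all(y >= 0), all(y == round(y)))
  lz <- .com_log_z(lambda, nu)
  y * log(lambda) - nu * lgamma(y + 1) - lz
}

#' Sample from the COM-Poisson distribution
#'
#' Draws by inversion of the truncated cumulative distribution function.
#'
#' @param n Number of draws.
#' @param lambda Positive rate parameter (scalar or length `n`).
#' @param nu Positive dispersion parameter (scalar or length `n`).
#' @return Integer vector of `n` non-negative draws.
#' @export
rcompois <- function(n, lambda, nu) {
  lambda <- rep_len(lambda, n)
  nu <- rep_len(nu, n)
  u <- stats::runif(n)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (lambda[i] <= 0) { out[i] <- 0L; next }
    lz <- .com_log_z(lambda[i], nu[i])
    ll <- log(lambda[i])
    y <- 0
    lp <- -lz            # log pmf at 0
    cum <- exp(lp)
    while (cum < u[i] && y < 1e4) {
      y <- y + 1
      lp <- y * ll - nu[i] * lgamma(y + 1) - lz
      cum <- cum + exp(lp)
    }
    out[i] <- as.integer(y)
  }
  out
}
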