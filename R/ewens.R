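#' Ewens sampling formula log-probability
#'
#' Log-probability of an unordered species abundance configuration under the
#' single-level neutral model (Hoppe urn with fundamental biodiversity
#' number theta):
#' \deqn{P(a | \theta) = \frac{J!}{\theta_{(J)}} \frac{\theta^S}{\prod_j j^{a_j} a_j!}}
#' where \eqn{a_j} is the number of species with abundance j, \eqn{S} the
#' number of species, \eqn{J} the total count, and \eqn{\theta_{(J)}} the
#' rising factorial.
#'
#' @param config Vector of positive integer abundances (a multiset; order
#'   irrelevant).
#' @param theta Positive fundamental biodiversity number.
#' @return The log-probability (a single numeric).
#' @examples
#' exp(ewens_log_prob(c(2), 1))     # 0.5
#' exp(ewens_log_prob(c(1, 1), 1))  # 0.5
#' @export
ewens_log_prob <- function(config, theta) {
  if (length(config) == 0L) stop("config must be non-empty")
  if (any(config <= 0) || any(config != round(config)))
    stop("abundances must be positive integers")
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stop("theta must be a positive scalar")
  J <- sum(config)
  S <- length(config)
  a <- table(config)
  j <- as.numeric(names(a))
  lgamma(J + 1) + S * log(theta) - sum(log(theta + seq_len(J) - 1)) -
    sum(as.numeric(a) * log(j) + lgamma(as.numeric(a) + 1))
}

#' Log unsigned Stirling numbers of the first kind
#'
#' Returns `log |s(n, t)|` for `t = 0..n`, computed by the stable log-space
#' recurrence `|s(n+1,t)| = n |s(n,t)| + |s(n,t-1)|`.  These are the seating
#' weights of the Chinese restaurant process: the number of ways `n`
#' customers can occupy `t` tables.
#'
#' @param n Non-negative integer.
#' @return Numeric vector of length `n + 1` (index `t + 1` holds
#'   `log |s(n, t)|`).
#' @export
log_stirling <- function(n) {
  stirling_log_row_cpp(as.integer(n))
}
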