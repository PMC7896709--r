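#' Expected species abundance distribution of the niche-neutral kernel
#'
#' Each niche (site) is internally neutral with niche-specific per-capita
#' birth-to-death ratio `x` and immigration parameter `gamma`; its
#' stationary species abundance distribution is the zero-truncated
#' negative binomial
#' \deqn{\langle\phi_n\rangle = \theta_i \frac{\Gamma(n+\gamma)}{n!\,\Gamma(\gamma)} x^n (1-x)^\gamma}
#' with \eqn{\theta_i = S / (1 - (1-x)^\gamma)} so that the expected counts
#' sum exactly to the observed richness `S`.  In the limit
#' \eqn{\gamma \to 0} with \eqn{\alpha = \theta\gamma} fixed the kernel
#' reduces to the Fisher log-series \eqn{\alpha x^n / n}, the classical
#' neutral metacommunity SAD.
#'
#' @param J Maximum abundance at which to evaluate the expectation.
#' @param S Observed richness (sets the normalization).
#' @param params List with `x` in (0, 1) and `gamma` > 0.
#' @return Numeric vector `phi[n]`, n = 1..J, with the niche-level
#'   diversity scaling attached as attribute `"theta"`.
#' @export
expected_sad <- function(J, S, params) {
  x <- params$x
  gamma <- params$gamma
  if (!is.numeric(x) || x <= 0 || x >= 1) stop("x must be in (0, 1)")
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be positive")
  if (J < S || S < 1) stop("J >= S >= 1 required")
  n <- seq_len(J)
  lq <- gamma * log1p(-x)                       # log (1-x)^gamma
  theta <- S / (-expm1(lq))
  phi <- theta * exp(lgamma(n + gamma) - lgamma(n + 1) - lgamma(gamma) +
                       n * log(x) + lq)
  attr(phi, "theta") <- theta
  phi
}

ztnb_loglik <- function(abund, x, gamma) {
  lq <- gamma * log1p(-x)
  sum(lgamma(abund + gamma) - lgamma(abund + 1) - lgamma(gamma) +
        abund * log(x) + lq - log(-expm1(lq)))
}

#' Preston octave index
#'
#' Octave bins double in width: abundance 1 is octave 0, 2–3 octave 1,
#' 4–7 octave 2, and so on; each abundance belongs to exactly one octave.
#'
#' @param n Positive integer abundances.
#' @return Integer octave indices `floor(log2(n))`.
#' @export
preston_octave <- function(n) {
  if (any(n < 1)) stop("abundances must be >= 1")
  floor(log2(n))
}

#' Fit the niche-neutral kernel to one local community
#'
#' Maximum-likelihood fit of the zero-truncated negative-binomial species
#' abundance kernel to the positive abundances of one site (niche).  The
#' optimizer is quasi-Newton on `(logit x, log gamma)` started from a small
#' multistart grid.  Degenerate communities (richness below 3, all
#' abundances identical, or fewer than 3 occupied octaves) are flagged
#' untestable rather than raising an error.
#'
#' @param counts Abundance vector (zeros ignored) or a `local_community`.
#' @param x_grid,gamma_grid Multistart values.
#' @return An object of class `niche_fit`: `x`, `gamma`, `theta`,
#'   `loglik`, `convergence`, `untestable` flag with `reason`, and the
#'   positive abundances in `abund`.
#' @export
fit_niche <- function(counts, x_grid = c(0.3, 0.6, 0.9, 0.99),
                      gamma_grid = c(0.1, 1, 10)) {
  if (inherits(counts, "local_community")) counts <- counts$counts
  abund <- as.numeric(counts[counts > 0])
  S <- length(abund)
  out <- list(x = NA_real_, gamma = NA_real_, theta = NA_real_,
              loglik = NA_real_, convergence = NA_integer_,
              untestable = FALSE, reason = NA_character_, abund = abund)
  class(out) <- "niche_fit"
  if (S < 3L) {
    out$untestable <- TRUE
    out$reason <- "richness below 3"
    return(out)
  }
  if (length(unique(abund)) == 1L) {
    out$untestable <- TRUE
    out$reason <- "all abundances identical"
    return(out)
  }
  if (length(unique(preston_octave(abund))) < 3L) {
    out$untestable <- TRUE
    out$reason <- "fewer than 3 occupied octave bins"
    return(out)
  }
  nll <- function(par) {
    x <- stats::plogis(par[1L])
    g <- exp(par[2L])
    if (x >= 1 - 1e-12 || x <= 1e-12 || g <= 1e-10 || g > 1e6) return(1e10)
    v <- -ztnb_loglik(abund, x, g)
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (x0 in x_grid) for (g0 in gamma_grid) {
    o <- tryCatch(stats::optim(c(stats::qlogis(x0), log(g0)), nll,
                               method = "BFGS",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    out$untestable <- TRUE
    out$reason <- "optimizer failed from every start"
    return(out)
  }
  out$x <- stats::plogis(best$par[1L])
  out$gamma <- exp(best$par[2L])
  out$theta <- S / (-expm1(out$gamma * log1p(-out$x)))
  out$loglik <- -best$value
  out$convergence <- best$convergence
  out
}

#' @export
print.niche_fit <- function(x, ...) {
  if (x$untestable) {
    cat("Niche fit: untestable (", x$reason, ")\n", sep = "")
  } else {
    cat("Niche-neutral kernel fit: x =", signif(x$x, 4),
        " gamma =", signif(x$gamma, 4),
        " (S =", length(x$abund), ", logLik =", signif(x$loglik, 6), ")\n")
  }
  invisible(x)
}

#' Pearson chi-squared statistic with explicit degrees of freedom
#'
#' @param observed,expected Bin counts (same length).
#' @param dof Degrees of freedom for the upper-tail p-value.
#' @return List with `chi2`, `dof`, `p`.
#' @export
pearson_chi2 <- function(observed, expected, dof) {
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, dof = dof,
       p = stats::pchisq(chi2, dof, lower.tail = FALSE))
}

#' Chi-squared goodness of fit of a niche kernel over Preston octaves
#'
#' Observed abundances are binned into Preston octaves; expected bin counts
#' come from the fitted kernel's expected SAD summed over each octave, with
#' the open top octave absorbing the analytic tail so the expectations sum
#' to the observed richness.  Bins with expected count below `min_expected`
#' are merged with their neighbor (from the sparse top end down) to protect
#' the chi-squared approximation; two fitted parameters are charged to the
#' degrees of freedom: `dof = bins - 1 - 2`.
#'
#' @param counts Abundances (zeros ignored) or a `local_community`.
#' @param params List or `niche_fit` with `x` and `gamma`.
#' @param min_expected Minimum expected count per bin before merging.
#' @return List with `chi2`, `dof`, `p`, `pass` (`p > 0.05`), `observed`
#'   and `expected` merged bin counts, and `untestable`/`reason`.
#' @export
gof_chi2 <- function(counts, params, min_expected = 1) {
  if (inherits(counts, "local_community")) counts <- counts$counts
  abund <- as.numeric(counts[counts > 0])
  S <- length(abund)
  fail <- function(reason)
    list(chi2 = NA_real_, dof = NA_integer_, p = NA_real_, pass = NA,
         observed = NULL, expected = NULL, untestable = TRUE,
         reason = reason)
  if (S < 3L) return(fail("richness below 3"))
  if (isTRUE(params$untestable)) return(fail(params$reason))
  oct <- preston_octave(abund)
  B <- max(oct)
  obs <- tabulate(oct + 1L, nbins = B + 1L)
  nmax <- 2L^(B + 1L) - 1L
  phi <- expected_sad(max(nmax, S), S, params)[seq_len(nmax)]
  exp_bins <- vapply(0:B, function(b)
    sum(phi[(2L^b):(2L^(b + 1L) - 1L)]), numeric(1))
  exp_bins[B + 1L] <- S - sum(exp_bins[seq_len(B)])  # open-ended top octave
  # merge adjacent sparse bins, starting from the top end
  while (length(exp_bins) > 1L && any(exp_bins < min_expected)) {
    i <- max(which(exp_bins < min_expected))
    j <- if (i == length(exp_bins)) i - 1L else i + 1L
    exp_bins[j] <- exp_bins[j] + exp_bins[i]
    obs[j] <- obs[j] + obs[i]
    exp_bins <- exp_bins[-i]
    obs <- obs[-i]
  }
  dof <- length(exp_bins) - 1L - 2L
  if (dof < 1L) return(fail("fewer than 4 usable octave bins"))
  res <- pearson_chi2(obs, exp_bins, dof)
  c(res, list(pass = res$p > 0.05, observed = obs, expected = exp_bins,
              untestable = FALSE, reason = NA_character_))
}

#' Metacommunity-level niche-neutral hybrid test
#'
#' Combines per-niche chi-squared goodness-of-fit results: the
#' metacommunity statistic is the sum of the independent per-niche
#' chi-squares with summed degrees of freedom (Fisher-style additivity).
#' The metacommunity passes the NNH — assembly co-driven by niche and
#' neutral processes, each niche internally neutral — when the combined
#' upper-tail p-value exceeds `threshold`.
#'
#' @param niche_results List of per-niche lists, each holding the
#'   [fit_niche()] output under `fit` and the [gof_chi2()] output under
#'   `gof` (as produced by [fit_nnh()]).
#' @param threshold Pass threshold (default 0.05).
#' @return List with `chi2_total`, `dof_total`, `p_meta`, `pass_meta`,
#'   `n_testable`, `n_local_pass`, `pct_local_pass` (percentage of
#'   testable niches passing locally), and `untestable`.
#' @export
nnh_test <- function(niche_results, threshold = 0.05) {
  testable <- Filter(function(r) isFALSE(r$gof$untestable), niche_results)
  if (length(testable) < 2L)
    return(list(chi2_total = NA_real_, dof_total = NA_integer_,
                p_meta = NA_real_, pass_meta = NA,
                n_testable = length(testable),
                n_local_pass = NA_integer_, pct_local_pass = NA_real_,
                untestable = TRUE))
  chi2_total <- sum(vapply(testable, function(r) r$gof$chi2, numeric(1)))
  dof_total <- sum(vapply(testable, function(r) r$gof$dof, numeric(1)))
  p_meta <- stats::pchisq(chi2_total, dof_total, lower.tail = FALSE)
  n_pass <- sum(vapply(testable, function(r) isTRUE(r$gof$pass), logical(1)))
  list(chi2_total = chi2_total, dof_total = dof_total, p_meta = p_meta,
       pass_meta = p_meta > threshold, n_testable = length(testable),
       n_local_pass = n_pass,
       pct_local_pass = 100 * n_pass / length(testable),
       untestable = FALSE)
}

#' Fit the niche-neutral hybrid model to a metacommunity
#'
#' Treats each site as a niche, fits the zero-truncated negative-binomial
#' neutral kernel to each niche by maximum likelihood, runs the per-niche
#' chi-squared goodness-of-fit over Preston octaves, and combines the
#' niches into the metacommunity-level NNH test (see [nnh_test()]).
#'
#' @param x A `metacommunity` or taxa-by-sites count matrix.
#' @param threshold Pass threshold on p-values.
#' @param min_expected Minimum expected octave count before merging.
#' @return An object of class `nnh_fit`: `niches` (a data.frame of per-
#'   niche `x`, `gamma`, `theta`, `chi2`, `dof`, `p`, `pass`,
#'   `untestable`), the raw per-niche results in `niche_results`, and the
#'   metacommunity-level `chi2_total`, `dof_total`, `p_meta`, `pass_meta`,
#'   `n_local_pass`, `pct_local_pass`.
#' @examples
#' x <- simulate_nnh_collection(n_meta = 1, n_sites = 3, J = 300,
#'                              S = 40, x_niche = 0.9, gamma_niche = 0.5,
#'                              seed = 1)
#' fit <- fit_nnh(x$metacommunities[[1]])
#' fit$pass_meta
#' @export
fit_nnh <- function(x, threshold = 0.05, min_expected = 1) {
  n <- if (inherits(x, "metacommunity")) x$n_matrix else as.matrix(x)
  meta_id <- if (inherits(x, "metacommunity")) x$meta_id else "meta"
  sites <- colnames(n)
  if (is.null(sites)) sites <- sprintf("site_%d", seq_len(ncol(n)))
  niche_results <- lapply(seq_len(ncol(n)), function(j) {
    fit <- fit_niche(n[, j])
    gof <- gof_chi2(n[, j], fit, min_expected)  # propagates untestable flags
    list(site_id = sites[j], fit = fit, gof = gof)
  })
  meta <- nnh_test(niche_results, threshold)
  niches <- do.call(rbind, lapply(niche_results, function(r)
    data.frame(site_id = r$site_id, x = r$fit$x, gamma = r$fit$gamma,
               theta = r$fit$theta, chi2 = r$gof$chi2, dof = r$gof$dof,
               p = r$gof$p, pass = r$gof$pass,
               untestable = isTRUE(r$gof$untestable) | isTRUE(r$fit$untestable))))
  structure(c(list(meta_id = meta_id, niches = niches,
                   niche_results = niche_results, threshold = threshold),
              meta),
            class = "nnh_fit")
}

#' @export
print.nnh_fit <- function(x, ...) {
  cat("Niche-neutral hybrid fit:", x$meta_id, "\n")
  if (isTRUE(x$untestable)) {
    cat("  untestable: fewer than 2 testable niches\n")
    return(invisible(x))
  }
  cat(sprintf("  chi2 = %.3f on %d dof, p = %.4g: %s at %.2g\n",
              x$chi2_total, x$dof_total, x$p_meta,
              if (x$pass_meta) "PASS" else "FAIL", x$threshold))
  cat(sprintf("  local niches passing: %d of %d (%.1f%%)\n",
              x$n_local_pass, x$n_testable, x$pct_local_pass))
  invisible(x)
}

#' @export
coef.nnh_fit <- function(object, ...) {
  ok <- !object$niches$untestable
  c(X = mean(object$niches$x[ok]), Y = mean(object$niches$gamma[ok]))
}

#' @export
summary.nnh_fit <- function(object, ...) {
  object$niches
}

#' @export
plot.nnh_fit <- function(x, which = 1L, ...) {
  r <- x$niche_results[[which]]
  if (isTRUE(r$gof$untestable)) {
    warning("niche ", r$site_id, " is untestable; nothing to plot")
    return(invisible(x))
  }
  nb <- length(r$gof$observed)
  bars <- rbind(observed = r$gof$observed, expected = r$gof$expected)
  graphics::barplot(bars, beside = TRUE, names.arg = seq_len(nb),
                    xlab = "Preston octave (merged bins)",
                    ylab = "species", legend.text = TRUE,
                    main = paste(x$meta_id, "-", r$site_id), ...)
  invisible(x)
}

#' Sample abundances from the zero-truncated negative-binomial kernel
#'
#' @param n Number of species abundances to draw.
#' @param x Birth-to-death ratio in (0, 1).
#' @param gamma Immigration parameter > 0.
#' @return Integer vector of positive abundances.
#' @export
rztnb <- function(n, x, gamma) {
  if (x <= 0 || x >= 1) stop("x must be in (0, 1)")
  if (gamma <= 0) stop("gamma must be positive")
  p0 <- exp(gamma * log1p(-x))
  out <- integer(0)
  while (length(out) < n) {
    need <- n - length(out)
    batch <- stats::rnbinom(ceiling(need / max(1 - p0, 1e-6)) + 8L,
                            size = gamma, prob = 1 - x)
    out <- c(out, batch[batch > 0L])
  }
  out[seq_len(n)]
}
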