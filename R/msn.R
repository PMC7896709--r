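#' Convert immigration concentration to immigration probability
#'
#' Standard neutral-theory identity between the dispersal concentration
#' `I` of a local community of size `J` and the per-birth immigration
#' probability `m`: `m = I / (I + J - 1)`.
#'
#' @param I Positive immigration concentration(s).
#' @param J Local community size(s), integer >= 2.
#' @return `m` in (0, 1).
#' @seealso [I_from_m()] for the inverse.
#' @export
m_from_I <- function(I, J) {
  if (any(I <= 0)) stop("I must be positive")
  if (any(J < 2)) stop("J must be at least 2")
  I / (I + J - 1)
}

#' @rdname m_from_I
#' @param m Immigration probability in (0, 1).
#' @export
I_from_m <- function(m, J) {
  if (any(m <= 0 | m >= 1)) stop("m must be in (0, 1)")
  if (any(J < 2)) stop("J must be at least 2")
  m * (J - 1) / (1 - m)
}

check_msn_params <- function(params, n_sites = NULL) {
  stopifnot(is.list(params))
  if (is.null(params$theta) || params$theta <= 0)
    stop("params$theta must be positive")
  if (is.null(params$I) || any(params$I <= 0))
    stop("params$I must be positive")
  if (!is.null(n_sites) && length(params$I) != n_sites)
    stop("params$I must have one entry per site")
  if (!is.null(params$beta)) {
    if (any(params$beta < 0) || abs(sum(params$beta) - 1) > 1e-12)
      stop("params$beta must be non-negative and sum to 1")
  }
  invisible(params)
}

#' Joint Chinese-restaurant-franchise log-likelihood
#'
#' Log-probability of an observed taxa-by-sites count table together with
#' its latent table counts under the two-level hierarchical Dirichlet
#' process.  With `level = "meta"` the metacommunity weights are integrated
#' out: each site contributes a CRP(`I_j`) seating term with unsigned
#' Stirling weights and the pooled table counts contribute a top-level
#' CRP(`theta`) (Ewens) term.  With `level = "local"` the likelihood
#' conditions on the drawn weights `beta` (length K + 1, last entry the
#' unseen stick) and keeps only the per-site seating terms — the neutral
#' local community given a possibly non-neutral metacommunity.
#'
#' @param x A `metacommunity` or a taxa-by-sites integer matrix.
#' @param params List with `theta`, `I` (one per site), and (for
#'   `level = "local"`) `beta`.
#' @param table_counts Integer matrix of latent table counts T, same shape
#'   as the count matrix, `1 <= T_jk <= n_jk` where `n_jk > 0` and 0
#'   elsewhere.
#' @param level `"meta"` (collapsed joint) or `"local"` (per-site terms
#'   conditional on beta).
#' @param stirling_cap Abundance above which the Antoniak/Stirling terms
#'   switch to a normal approximation.
#' @return Log-likelihood (a single numeric).
#' @export
crf_log_likelihood <- function(x, params, table_counts,
                               level = c("meta", "local"),
                               stirling_cap = 5000L) {
  level <- match.arg(level)
  n <- if (inherits(x, "metacommunity")) x$n_matrix else as.matrix(x)
  storage.mode(n) <- "integer"
  T <- as.matrix(table_counts)
  storage.mode(T) <- "integer"
  if (!all(dim(T) == dim(n))) stop("table_counts shape must match counts")
  if (any(T > n)) stop("table counts cannot exceed abundances (T_jk > n_jk)")
  if (any(T[n > 0L] < 1L)) stop("T_jk must be >= 1 where n_jk > 0")
  if (any(T[n == 0L] != 0L)) stop("T_jk must be 0 where n_jk = 0")
  check_msn_params(params, ncol(n))
  if (level == "meta") {
    crf_loglik_cpp(n, T, params$theta, params$I, NULL,
                   as.integer(stirling_cap))
  } else {
    beta <- params$beta
    if (is.null(beta)) stop("level = 'local' requires params$beta")
    if (length(beta) == nrow(n)) beta <- c(beta, 0)
    if (length(beta) != nrow(n) + 1L)
      stop("beta must have one weight per taxon plus the unseen stick")
    crf_loglik_cpp(n, T, params$theta, params$I, beta,
                   as.integer(stirling_cap))
  }
}

#' Fit the multisite neutral model by Gibbs sampling
#'
#' Fits the hierarchical-Dirichlet-process multisite neutral (MSN) model to
#' a metacommunity: a top-level neutral metacommunity with fundamental
#' biodiversity number `theta` feeding every site through site-specific
#' immigration concentrations `I_j` (equivalently migration probabilities
#' `m_j`).  Each Gibbs sweep (1) samples every latent table count `T_jk`
#' from its Antoniak conditional with weights `|s(n,t)| (I_j beta_k)^t`,
#' (2) samples the metacommunity weights `beta` from a Dirichlet with
#' parameters `(T_.1, ..., T_.K, theta)`, (3) samples `theta` by the
#' Escobar–West auxiliary-variable update, and (4) samples each `I_j` by the
#' Teh auxiliary-variable update.  Priors are vague Gamma(1, 0.1) on both
#' `theta` and `I_j`.
#'
#' @param x A `metacommunity` (or taxa-by-sites integer matrix with at
#'   least two columns).
#' @param iterations Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before retention.
#' @param thin Retain every `thin`-th post-burn-in sweep; the default
#'   schedule (50000, 25000, 10) retains exactly 2,500 draws.
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @param prior_shape,prior_rate Gamma prior on `theta` and each `I_j`.
#' @param stirling_cap Abundance above which a normal approximation to the
#'   Antoniak distribution is used.
#' @return An object of class `msn_fit`: posterior draws of `theta`, `I`
#'   (draws x sites), `m`, `beta` (draws x (K+1), last column the unseen
#'   stick), latent table counts `T` (taxa x sites x draws), the collapsed
#'   joint log-likelihood trace, the data and the configuration.
#' @examples
#' x <- simulate_msn_collection(n_meta = 1, n_sites = 3, J = 200,
#'                              theta = 10, m = 0.2, seed = 1)
#' fit <- fit_msn(x$metacommunities[[1]], iterations = 500, burn_in = 250,
#'                thin = 5, seed = 1)
#' coef(fit)["theta"]
#' @export
fit_msn <- function(x, iterations = 50000L, burn_in = 25000L, thin = 10L,
                    seed = NULL, prior_shape = 1, prior_rate = 0.1,
                    stirling_cap = 5000L) {
  n <- if (inherits(x, "metacommunity")) x$n_matrix else as.matrix(x)
  storage.mode(n) <- "integer"
  if (ncol(n) < 2L) stop("MSN requires at least 2 sites")
  if (any(colSums(n) == 0L)) stop("every site must have at least one taxon")
  if (iterations <= burn_in)
    stop("config error: iterations must exceed burn_in")
  if (thin < 1L) stop("config error: thin must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  res <- msn_gibbs_cpp(n, as.integer(iterations), as.integer(burn_in),
                       as.integer(thin), prior_shape, prior_rate,
                       1.0, 1.0, as.integer(stirling_cap))
  J <- colSums(n)
  m <- sweep(res$I, 2L, J - 1, function(I, Jm1) I / (I + Jm1))
  colnames(res$I) <- colnames(m) <- colnames(n)
  structure(list(theta = res$theta, I = res$I, m = m, beta = res$beta,
                 T = res$T, loglik_trace = res$loglik,
                 n_matrix = n,
                 meta_id = if (inherits(x, "metacommunity")) x$meta_id else "meta",
                 config = list(iterations = iterations, burn_in = burn_in,
                               thin = thin, seed = seed,
                               prior_shape = prior_shape,
                               prior_rate = prior_rate,
                               stirling_cap = stirling_cap)),
            class = "msn_fit")
}

#' @export
print.msn_fit <- function(x, ...) {
  cat("Multisite neutral (HDP) model fit:", x$meta_id, "\n")
  cat("  ", nrow(x$n_matrix), "taxa x", ncol(x$n_matrix), "sites;",
      length(x$theta), "retained draws\n")
  cat("  theta (posterior median):", signif(stats::median(x$theta), 4), "\n")
  cat("  m_j   (posterior median):",
      paste(signif(apply(x$m, 2L, stats::median), 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.msn_fit <- function(object, ...) {
  c(theta = stats::median(object$theta),
    stats::setNames(apply(object$m, 2L, stats::median),
                    paste0("m_", colnames(object$m))))
}

#' @export
logLik.msn_fit <- function(object, ...) {
  ll <- stats::median(object$loglik_trace)
  attr(ll, "df") <- 1L + ncol(object$n_matrix)
  class(ll) <- "logLik"
  ll
}

#' @export
summary.msn_fit <- function(object, ...) {
  qs <- function(v) stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE)
  th <- qs(object$theta)
  ms <- t(apply(object$m, 2L, qs))
  out <- list(meta_id = object$meta_id, n_draws = length(object$theta),
              theta = stats::setNames(th, c("median", "lo95", "hi95")),
              m = `colnames<-`(ms, c("median", "lo95", "hi95")),
              loglik = summary(object$loglik_trace))
  class(out) <- "summary.msn_fit"
  out
}

#' @export
print.summary.msn_fit <- function(x, ...) {
  cat("MSN fit for", x$meta_id, "(", x$n_draws, "draws )\n")
  cat("theta:", signif(x$theta[1], 4), sprintf("[%.3g, %.3g]\n",
                                               x$theta[2], x$theta[3]))
  cat("per-site migration m_j (median [95% interval]):\n")
  print(signif(x$m, 3))
  invisible(x)
}

#' @export
plot.msn_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$theta, type = "l", xlab = "retained draw",
                 ylab = expression(theta), main = x$meta_id, ...)
  graphics::plot(x$loglik_trace, type = "l", xlab = "retained draw",
                 ylab = "joint log-likelihood", ...)
  invisible(x)
}

#' Simulate a metacommunity from MSN parameters
#'
#' Generates an integer abundance matrix by Chinese-restaurant-franchise
#' seating: each site seats `J_j` customers with concentration `I_j`; new
#' tables draw their taxon from the metacommunity weights `beta` (novel
#' taxa arise from the unseen stick through a CRP(`theta`)), or, when
#' `beta` is `NULL`, from a fully collapsed top-level CRP(`theta`).
#' Column sums equal `site_sizes` exactly.
#'
#' @param params List with `theta`, `I` (length = number of sites) and
#'   optionally `beta` (K + 1 weights, last the unseen stick).
#' @param site_sizes Positive integer vector of community sizes `J_j`.
#' @param seed Optional seed.
#' @return A `metacommunity`; the latent table counts are attached as
#'   attribute `"tables"` and the count of taxa that map to `beta` entries
#'   as attribute `"n_obs_dishes"`.
#' @export
simulate_from_params <- function(params, site_sizes, seed = NULL) {
  if (any(site_sizes <= 0)) stop("site sizes must be positive")
  check_msn_params(params, length(site_sizes))
  if (!is.null(seed)) set.seed(seed)
  res <- simulate_crf_cpp(params$theta, params$I, as.integer(site_sizes),
                          params$beta)
  counts <- res$counts
  rownames(counts) <- sprintf("OTU_%06d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("site_%d", seq_len(ncol(counts)))
  keep <- rowSums(counts) > 0L
  m <- metacommunity("simulated", counts[keep, , drop = FALSE])
  attr(m, "tables") <- res$tables[keep, , drop = FALSE]
  attr(m, "n_obs_dishes") <- res$n_obs_dishes
  m
}

#' @export
simulate.msn_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(object$theta), nsim, replace = TRUE)
  lapply(idx, function(i) {
    simulate_from_params(list(theta = object$theta[i], I = object$I[i, ],
                              beta = object$beta[i, ]),
                         colSums(object$n_matrix))
  })
}

#' Two-level posterior-predictive neutrality test
#'
#' For each retained posterior draw, one replicate dataset is simulated
#' from that draw's parameters and its log-likelihood `L` is compared with
#' the observed data's log-likelihood `L_0` under the same draw.  The
#' pseudo-p-value is the fraction of draws with `L <= L_0`; the community
#' passes (is indistinguishable from neutral) when `p > threshold`.  The
#' metacommunity level uses the full collapsed joint likelihood (top-level
#' CRP(theta) term included); the local level uses only the per-site
#' seating terms conditional on the drawn metacommunity weights, pooled
#' over sites (per-site pseudo-p-values are also returned).
#'
#' @param fit An [fit_msn()] object with at least 100 retained draws.
#' @param level `"meta"` or `"local"`.
#' @param threshold Pass threshold on the pseudo-p (default 0.05).
#' @param seed Optional seed for the replicate simulations.
#' @return An object of class `neutrality_test` with elements `level`, `p`
#'   (P_M or pooled P_L), `p_site` (per-site pseudo-p, local level),
#'   `pass`, `n_sim`, `L0_summary`, `L_sim_median` (diagnostic), and
#'   `threshold`.
#' @export
neutrality_test <- function(fit, level = c("meta", "local"),
                            threshold = 0.05, seed = NULL) {
  level <- match.arg(level)
  if (!inherits(fit, "msn_fit")) stop("fit must be an msn_fit")
  N <- length(fit$theta)
  if (N < 100L) stop("need at least 100 retained draws for the pseudo-p")
  if (!is.null(seed)) set.seed(seed)
  pp <- msn_pp_test_cpp(fit$n_matrix, fit$theta, fit$I, fit$beta, fit$T,
                        as.integer(fit$config$stirling_cap))
  if (level == "meta") {
    L0 <- pp$L0_meta
    Ls <- pp$Lsim_meta
    p <- mean(Ls <= L0)
    p_site <- NULL
  } else {
    L0s <- pp$L0_local
    Lss <- pp$Lsim_local
    L0 <- rowSums(L0s)
    Ls <- rowSums(Lss)
    p <- mean(Ls <= L0)
    p_site <- colMeans(Lss <= L0s)
    names(p_site) <- colnames(fit$n_matrix)
  }
  structure(list(level = level, p = p, p_site = p_site,
                 pass = p > threshold, n_sim = N,
                 L0_summary = summary(L0),
                 L_sim_median = stats::median(Ls),
                 threshold = threshold, meta_id = fit$meta_id),
            class = "neutrality_test")
}

#' @export
print.neutrality_test <- function(x, ...) {
  lab <- if (x$level == "meta") "P_M" else "P_L"
  cat("Posterior-predictive neutrality test (", x$level, " level) for ",
      x$meta_id, "\n", sep = "")
  cat("  ", lab, " = ", format(x$p, digits = 4), " (N = ", x$n_sim, "); ",
      if (x$pass) "PASS" else "FAIL",
      " at threshold ", x$threshold, "\n", sep = "")
  if (!is.null(x$p_site)) {
    cat("  per-site pseudo-p:\n")
    print(signif(x$p_site, 3))
  }
  invisible(x)
}
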