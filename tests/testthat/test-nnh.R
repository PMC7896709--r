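test_that("expected SAD normalizes to richness and matches closed forms", {
  # geometric closed form at gamma = 1, x = 0.5: phi_n / theta = 0.5^(n+1)/0.5
  phi <- expected_sad(60, 10, list(x = 0.5, gamma = 1))
  theta <- attr(phi, "theta")
  expect_equal(phi, theta * 0.5^(seq_len(60) + 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(theta, 10 / 0.5, tolerance = 1e-12)
  # normalization for random (x, gamma)
  set.seed(8)
  for (r in 1:20) {
    x <- runif(1, 0.05, 0.99)
    g <- exp(runif(1, log(0.05), log(20)))
    S <- sample(3:50, 1)
    phi <- expected_sad(5000, S, list(x = x, gamma = g))
    # analytic tail beyond the truncation via the zero-truncated NB cdf
    tail <- S * stats::pnbinom(5000, size = g, prob = 1 - x,
                               lower.tail = FALSE) /
      (1 - (1 - x)^g)
    expect_equal(sum(phi) + tail, S, tolerance = 1e-9)
  }
})

test_that("gamma -> 0 limit recovers the Fisher log-series", {
  x <- 0.8
  g <- 1e-6
  S <- 25
  phi <- expected_sad(300, S, list(x = x, gamma = g))
  alpha <- attr(phi, "theta") * g
  n <- seq_len(300)
  expect_equal(phi, alpha * x^n / n, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("kernel domain errors are raised", {
  expect_error(expected_sad(10, 5, list(x = 1.2, gamma = 1)), "x must")
  expect_error(expected_sad(10, 5, list(x = 0.5, gamma = -1)), "gamma")
  expect_error(expected_sad(3, 5, list(x = 0.5, gamma = 1)), "J >= S")
})

test_that("niche MLE recovers generating parameters", {
  set.seed(42)
  xs <- gs <- numeric(8)
  for (r in 1:8) {
    ab <- rztnb(500, 0.9, 0.5)
    f <- fit_niche(ab)
    xs[r] <- f$x
    gs[r] <- f$gamma
  }
  expect_lt(abs(median(xs) - 0.9), 0.05)
  expect_lt(abs(log2(median(gs) / 0.5)), 1)   # within a factor of 2
})

test_that("degenerate niches are flagged untestable, not errors", {
  expect_true(fit_niche(c(5, 7))$untestable)            # S < 3
  expect_true(fit_niche(rep(4L, 10))$untestable)        # identical
  f <- fit_niche(c(1, 1, 2, 2, 3))                      # octaves 0,1 only
  expect_true(f$untestable)
  expect_match(f$reason, "octave")
})

test_that("niche fit is invariant to taxon order", {
  set.seed(13)
  ab <- rztnb(120, 0.85, 1)
  f1 <- fit_niche(ab)
  f2 <- fit_niche(sample(ab))
  expect_equal(f1$x, f2$x, tolerance = 1e-6)
  expect_equal(f1$gamma, f2$gamma, tolerance = 1e-6)
})

test_that("Preston octaves assign each abundance to exactly one bin", {
  expect_identical(preston_octave(c(1, 2, 3, 4, 7, 8, 15, 16)),
                   c(0, 1, 1, 2, 2, 3, 3, 4))
  expect_error(preston_octave(0), ">= 1")
})

test_that("Pearson chi-squared matches hand-computed toy values", {
  r <- pearson_chi2(c(10, 0), c(5, 5), 1)
  expect_equal(r$chi2, 10)
  expect_equal(r$p, pchisq(10, 1, lower.tail = FALSE))
  expect_equal(r$p, 0.00157, tolerance = 5e-3)
  perfect <- pearson_chi2(c(3, 4, 5), c(3, 4, 5), 2)
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p, 1)
})

test_that("goodness of fit flags thin communities and respects dof charge", {
  set.seed(3)
  ab <- rztnb(200, 0.95, 0.8)
  f <- fit_niche(ab)
  g <- gof_chi2(ab, f)
  expect_false(g$untestable)
  expect_identical(g$dof, length(g$observed) - 3L)
  expect_true(all(g$expected >= 1))
  expect_equal(sum(g$expected), length(ab), tolerance = 1e-9)
  expect_identical(sum(g$observed), length(ab))
  # too few occupied octaves -> untestable flag propagates
  thin <- gof_chi2(c(1, 2, 3), fit_niche(c(1, 2, 3)))
  expect_true(thin$untestable)
})

test_that("metacommunity NNH statistic is additive over niches", {
  set.seed(4)
  col <- simulate_nnh_collection(n_meta = 1, n_sites = 4, J = 600, S = 50,
                                 x_niche = 0.9, gamma_niche = 0.5, seed = 5)
  fit <- fit_nnh(col$metacommunities[[1]])
  ok <- !fit$niches$untestable
  expect_equal(fit$chi2_total, sum(fit$niches$chi2[ok]))
  expect_equal(fit$dof_total, sum(fit$niches$dof[ok]))
  expect_equal(fit$p_meta,
               pchisq(fit$chi2_total, fit$dof_total, lower.tail = FALSE))
  expect_identical(fit$pass_meta, fit$p_meta > 0.05)
  expect_equal(fit$pct_local_pass,
               100 * fit$n_local_pass / fit$n_testable)
})

test_that("adding a perfectly fitting niche cannot decrease the combined p", {
  # a niche with chi2 = 0 on d dof adds pure degrees of freedom, so the
  # combined upper tail can only grow
  base <- list(list(gof = list(chi2 = 9, dof = 4, p = 0.06, pass = TRUE,
                               untestable = FALSE)),
               list(gof = list(chi2 = 7, dof = 3, p = 0.07, pass = TRUE,
                               untestable = FALSE)))
  with_perfect <- c(base, list(list(gof = list(chi2 = 0, dof = 2, p = 1,
                                               pass = TRUE,
                                               untestable = FALSE))))
  expect_gte(nnh_test(with_perfect)$p_meta, nnh_test(base)$p_meta)
})

test_that("local pass bookkeeping matches the 2-of-7 worked example", {
  res <- lapply(seq_len(7), function(i)
    list(gof = list(chi2 = if (i <= 2) 1 else 30, dof = 3,
                    p = if (i <= 2) 0.8 else 1e-5, pass = i <= 2,
                    untestable = FALSE)))
  agg <- nnh_test(res)
  expect_identical(agg$n_local_pass, 2L)
  expect_equal(agg$pct_local_pass, 28.6, tolerance = 0.05)
})

test_that("fewer than two testable niches makes the metacommunity untestable", {
  res <- list(list(gof = list(chi2 = 1, dof = 3, p = 0.8, pass = TRUE,
                              untestable = FALSE)),
              list(gof = list(untestable = TRUE)))
  expect_true(nnh_test(res)$untestable)
})
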