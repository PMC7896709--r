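test_that("immigration identity m = I/(I+J-1) and its inverse round-trip", {
  expect_equal(m_from_I(100, 101), 0.5)
  expect_equal(m_from_I(I_from_m(0.069, 1000), 1000), 0.069, tolerance = 1e-12)
  expect_lt(m_from_I(1e-9, 100), 1e-10)   # no-immigration limit
  expect_error(m_from_I(-1, 10), "positive")
  expect_error(m_from_I(1, 1), "at least 2")
  expect_error(I_from_m(1.2, 10), "in \\(0, 1\\)")
})

test_that("Gibbs schedule arithmetic fixes the number of retained draws", {
  m <- toy_meta()
  fit <- fit_msn(m, iterations = 300, burn_in = 100, thin = 10, seed = 1)
  expect_identical(length(fit$theta), 20L)
  expect_identical(nrow(fit$I), 20L)
  fit2 <- fit_msn(m, iterations = 2000, burn_in = 1000, thin = 10, seed = 1)
  expect_identical(length(fit2$theta), 100L)
  expect_error(fit_msn(m, iterations = 100, burn_in = 100, thin = 10),
               "config error")
})

test_that("table-count draws respect their support", {
  m <- toy_meta()
  fit <- fit_msn(m, iterations = 400, burn_in = 200, thin = 2, seed = 3)
  n <- m$n_matrix
  for (i in seq_len(dim(fit$T)[3])) {
    T <- fit$T[, , i]
    expect_true(all(T[n > 0] >= 1))
    expect_true(all(T <= n))
    expect_true(all(T[n == 0] == 0))
  }
  expect_true(all(is.finite(fit$loglik_trace)))
})

test_that("collapsed CRF likelihood reduces to the Ewens formula for one
           site without dispersal limitation", {
  for (config in list(c(2L), c(1L, 1L), c(2L, 1L, 1L), c(3L, 2L))) {
    n <- matrix(config, ncol = 1)
    T <- n   # I -> infinity: every individual founds its own table
    theta <- 1.7
    ll <- crf_loglik_cpp(n, T, theta, 1e9, NULL, 5000L)
    # residual error is O(J^2/I) plus lgamma cancellation at huge arguments
    expect_equal(ll, ewens_log_prob(config, theta), tolerance = 1e-4)
  }
})

test_that("CRF likelihood validates table counts and parameters", {
  m <- toy_meta()
  n <- m$n_matrix
  T <- pmin(n, 1L)
  params <- list(theta = 2, I = c(1, 1))
  expect_silent(crf_log_likelihood(m, params, T, "meta"))
  bad <- T; bad[1, 1] <- n[1, 1] + 1L
  expect_error(crf_log_likelihood(m, params, bad, "meta"), "exceed")
  bad2 <- T; bad2[1, 1] <- 0L
  expect_error(crf_log_likelihood(m, params, bad2, "meta"), ">= 1")
  expect_error(crf_log_likelihood(m, list(theta = -1, I = c(1, 1)), T),
               "theta")
  expect_error(crf_log_likelihood(m, params, T, "local"), "beta")
})

test_that("per-site local terms are exchangeable: duplicated sites double
           the log-likelihood", {
  counts <- c(4L, 2L, 1L)
  n1 <- matrix(counts, ncol = 1)
  n2 <- cbind(n1, n1)
  T1 <- matrix(c(2L, 1L, 1L), ncol = 1)
  beta <- c(0.4, 0.3, 0.2, 0.1)
  l1 <- crf_loglik_cpp(n1, T1, 2, 1.5, beta, 5000L)
  l2 <- crf_loglik_cpp(n2, cbind(T1, T1), 2, c(1.5, 1.5), beta, 5000L)
  expect_equal(l2, 2 * l1, tolerance = 1e-10)
})

test_that("likelihoods are invariant to taxon relabeling", {
  set.seed(5)
  col <- simulate_msn_collection(n_meta = 1, n_sites = 3, J = 150,
                                 theta = 8, m = 0.2, seed = 9)
  m <- col$metacommunities[[1]]
  n <- m$n_matrix
  fit <- fit_msn(m, iterations = 600, burn_in = 300, thin = 3, seed = 2)
  i <- 50
  T <- fit$T[, , i]
  params <- list(theta = fit$theta[i], I = fit$I[i, ])
  perm <- sample(nrow(n))
  expect_equal(
    crf_log_likelihood(n, params, T, "meta"),
    crf_log_likelihood(n[perm, ], params, T[perm, ], "meta"),
    tolerance = 1e-10)
  params$beta <- fit$beta[i, ]
  expect_equal(
    crf_log_likelihood(n, params, T, "local"),
    crf_log_likelihood(n[perm, ],
                       list(theta = params$theta, I = params$I,
                            beta = c(params$beta[perm], params$beta[nrow(n) + 1])),
                       T[perm, ], "local"),
    tolerance = 1e-10)
})

test_that("simulated metacommunities conserve requested site sizes", {
  params <- list(theta = 5, I = c(10, 20, 5))
  sim <- simulate_from_params(params, c(100, 250, 60), seed = 4)
  expect_equal(unname(colSums(sim$n_matrix)), c(100, 250, 60))
  expect_error(simulate_from_params(params, c(100, 0, 60)), "positive")
  # theta -> 0: a single shared taxon dominates everywhere
  mono <- simulate_from_params(list(theta = 1e-9, I = c(5, 5)),
                               c(200, 200), seed = 6)
  expect_identical(mono$K, 1L)
})

test_that("fits and tests are bit-reproducible under a fixed seed", {
  col <- simulate_msn_collection(n_meta = 1, n_sites = 3, J = 200,
                                 theta = 10, m = 0.15, seed = 21)
  m <- col$metacommunities[[1]]
  f1 <- fit_msn(m, iterations = 600, burn_in = 300, thin = 3, seed = 77)
  f2 <- fit_msn(m, iterations = 600, burn_in = 300, thin = 3, seed = 77)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$I, f2$I)
  expect_identical(f1$T, f2$T)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  t1 <- neutrality_test(f1, "meta", seed = 5)
  t2 <- neutrality_test(f2, "meta", seed = 5)
  expect_identical(t1$p, t2$p)
})

test_that("neutrality test requires enough draws and reports both levels", {
  col <- simulate_msn_collection(n_meta = 1, n_sites = 3, J = 200,
                                 theta = 10, m = 0.15, seed = 22)
  fit <- fit_msn(col$metacommunities[[1]], iterations = 2000, burn_in = 1000,
                 thin = 10, seed = 1)
  tiny <- fit_msn(col$metacommunities[[1]], iterations = 300, burn_in = 100,
                  thin = 10, seed = 1)
  expect_error(neutrality_test(tiny, "meta"), "100")
  tm <- neutrality_test(fit, "meta", seed = 2)
  tl <- neutrality_test(fit, "local", seed = 3)
  expect_true(tm$p >= 0 && tm$p <= 1)
  expect_identical(tm$pass, tm$p > 0.05)
  expect_identical(length(tl$p_site), 3L)
  expect_identical(tl$pass, tl$p > 0.05)
  expect_true(is.numeric(tl$L_sim_median))
})

test_that("posterior summaries expose theta and per-site migration", {
  col <- simulate_msn_collection(n_meta = 1, n_sites = 3, J = 200,
                                 theta = 10, m = 0.15, seed = 30)
  fit <- fit_msn(col$metacommunities[[1]], iterations = 600, burn_in = 300,
                 thin = 3, seed = 1)
  cf <- coef(fit)
  expect_identical(names(cf)[1], "theta")
  expect_identical(length(cf), 4L)
  s <- summary(fit)
  expect_true(s$theta["lo95"] <= s$theta["median"])
  expect_true(all(s$m[, "median"] > 0 & s$m[, "median"] < 1))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(length(sims), 2L)
  expect_identical(unname(colSums(sims[[1]]$n_matrix)),
                   unname(colSums(col$metacommunities[[1]]$n_matrix)))
})
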