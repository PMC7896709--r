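test_that("generators are bit-reproducible from (spec, seed)", {
  a <- simulate_msn_collection(n_meta = 3, n_sites = 4, J = 200, theta = 10,
                               m = 0.2, seed = 31)
  b <- simulate_msn_collection(n_meta = 3, n_sites = 4, J = 200, theta = 10,
                               m = 0.2, seed = 31)
  for (id in names(a$metacommunities))
    expect_identical(a$metacommunities[[id]]$n_matrix,
                     b$metacommunities[[id]]$n_matrix)
  h1 <- simulate_nnh_collection(n_meta = 2, n_sites = 3, J = 300, S = 30,
                                seed = 32)
  h2 <- simulate_nnh_collection(n_meta = 2, n_sites = 3, J = 300, S = 30,
                                seed = 32)
  expect_identical(h1$metacommunities[[2]]$n_matrix,
                   h2$metacommunities[[2]]$n_matrix)
  g1 <- simulate_non_neutral_collection(n_meta = 2, seed = 33)
  g2 <- simulate_non_neutral_collection(n_meta = 2, seed = 33)
  expect_identical(g1$metacommunities[[1]]$n_matrix,
                   g2$metacommunities[[1]]$n_matrix)
  expect_identical(attr(g1, "manifest")$seed, 33)
})

test_that("all generators emit valid metacommunities with exact site sizes", {
  cols <- list(
    simulate_msn_collection(n_meta = 2, n_sites = 5, J = 400, seed = 1),
    simulate_nnh_collection(n_meta = 2, n_sites = 5, J = 400, seed = 2),
    simulate_non_neutral_collection(n_meta = 2, n_sites = 5, J = 400, seed = 3))
  for (col in cols) {
    for (m in col$metacommunities) {
      expect_s3_class(m, "metacommunity")
      expect_identical(unname(m$J), rep(400L, 5))
      expect_true(all(rowSums(m$n_matrix) > 0))
    }
  }
})

test_that("gut-shaped design: 11 metacommunities of 7 sites", {
  col <- simulate_msn_collection(n_meta = 11, n_sites = 7, J = 150,
                                 theta = 10, m = 0.1, seed = 41)
  expect_identical(length(col$metacommunities), 11L)
  expect_true(all(vapply(col$metacommunities,
                         function(m) ncol(m$n_matrix), 1L) == 7L))
})

test_that("theta -> 0 collapses every site onto one shared taxon", {
  col <- simulate_msn_collection(n_meta = 2, n_sites = 4, J = 300,
                                 theta = 1e-9, m = 0.3, seed = 51)
  for (m in col$metacommunities) expect_identical(m$K, 1L)
})

test_that("niche overlap controls shared taxa across sites", {
  disjoint <- simulate_nnh_collection(n_meta = 1, n_sites = 3, J = 400,
                                      S = 30, overlap = 0, seed = 61)
  n <- disjoint$metacommunities[[1]]$n_matrix
  expect_true(all(rowSums(n > 0) == 1))   # no taxon in more than one niche
  shared <- simulate_nnh_collection(n_meta = 1, n_sites = 3, J = 400,
                                    S = 30, overlap = 1, seed = 62)
  n2 <- shared$metacommunities[[1]]$n_matrix
  expect_gt(mean(rowSums(n2 > 0) > 1), 0.5)
})

test_that("per-niche parameters are recovered in order from hybrid data", {
  set.seed(63)
  ok <- 0
  for (r in 1:6) {
    col <- simulate_nnh_collection(n_meta = 1, n_sites = 2, J = 1500,
                                   S = c(60, 60), x_niche = c(0.9, 0.6),
                                   gamma_niche = c(0.5, 5))
    n <- col$metacommunities[[1]]$n_matrix
    f1 <- fit_niche(n[, 1])
    f2 <- fit_niche(n[, 2])
    if (f1$x > f2$x && f1$gamma < f2$gamma) ok <- ok + 1
  }
  expect_gte(ok, 5)
})

test_that("geometric control has the prescribed dominance and rotated ranks", {
  k <- 0.7; S <- 30
  col <- simulate_non_neutral_collection(n_meta = 1, n_sites = 5, J = 2000,
                                         S = S, k = k, noise = 0, seed = 71)
  n <- col$metacommunities[[1]]$n_matrix
  top_share <- apply(n, 2, max) / colSums(n)
  expect_equal(unname(top_share), rep(k / (1 - (1 - k)^S), 5),
               tolerance = 0.01)
  # each site has a different dominant taxon
  expect_identical(length(unique(apply(n, 2, which.max))), 5L)
})

test_that("single-site richness under weak dispersal limitation follows the
           CRP expectation", {
  set.seed(81)
  theta <- 5; J <- 100; reps <- 400
  rich <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- msnnh:::simulate_crf_cpp(theta, 1e9, J, NULL)
    rich[r] <- sum(rowSums(sim$counts) > 0)
  }
  expected <- sum(theta / (theta + 0:(J - 1)))
  se <- sd(rich) / sqrt(reps)
  expect_lt(abs(mean(rich) - expected), 3 * se)
})
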