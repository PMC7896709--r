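test_that("TSV reading preserves counts, ordering, and dimensions", {
  path <- write_toy_tsv(matrix(c(5L, 1L, 0L, 0L, 1L, 2L), nrow = 3),
                        c("otuA", "otuB", "otuC"), c("s1", "s2"))
  tab <- read_abundance_table(path, quiet = TRUE)
  expect_identical(dim(tab), c(3L, 2L))
  expect_equal(unname(colSums(tab)), c(6, 3))
  expect_identical(rownames(tab), c("otuA", "otuB", "otuC"))
})

test_that("malformed input is rejected with informative errors", {
  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(read_abundance_table(empty, quiet = TRUE), "parse error")
  frac <- write_toy_tsv(matrix(c(2.7, 1, 1, 1), nrow = 2),
                        c("a", "b"), c("s1", "s2"))
  expect_error(read_abundance_table(frac, quiet = TRUE), "fractional")
  tab <- read_abundance_table(frac, strict = FALSE, quiet = TRUE)
  expect_identical(tab["a", "s1"], 3L)
  neg <- write_toy_tsv(matrix(c(-1L, 1L, 1L, 1L), nrow = 2),
                       c("a", "b"), c("s1", "s2"))
  expect_error(read_abundance_table(neg, quiet = TRUE), "negative")
  expect_error(read_abundance_table(tempfile(), quiet = TRUE), "not found")
})

test_that("grouping builds gut-style metacommunities and drops degenerate input", {
  set.seed(1)
  tab <- matrix(rpois(20 * 9, 5), nrow = 20,
                dimnames = list(sprintf("t%02d", 1:20),
                                c(sprintf("s404_%d", 1:7), "s405_1", "zero")))
  tab[, "zero"] <- 0L
  storage.mode(tab) <- "integer"
  map <- c(setNames(rep("subject404", 7), sprintf("s404_%d", 1:7)),
           s405_1 = "subject405", zero = "subject405")
  expect_warning(col <- group_into_metacommunities(tab, map), "all-zero")
  # subject404 keeps its 7 gut sites; subject405 loses its only nonzero mate
  expect_identical(ncol(col$metacommunities$subject404$n_matrix), 7L)
  expect_false("subject405" %in% names(col$metacommunities))
  expect_identical(attr(col, "excluded"), "subject405")
  # metadata missing a sample names the sample
  expect_error(group_into_metacommunities(tab, map[-1]), "s404_1")
})

test_that("metacommunity invariants: positive rows, >=2 sites, column sums", {
  m <- toy_meta()
  expect_identical(m$K, 3L)
  expect_identical(unname(m$J), c(6L, 3L))
  expect_identical(vapply(m$sites, `[[`, 1L, "J"), unname(m$J))
  one_col <- matrix(1:3, ncol = 1, dimnames = list(letters[1:3], "s1"))
  expect_error(metacommunity("x", one_col), "2 sites")
  withzero <- rbind(m$n_matrix, dead = c(0L, 0L))
  expect_identical(metacommunity("x", withzero)$K, 3L)
  expect_error(metacommunity("x", -m$n_matrix), "negative")
})

test_that("write/read round-trip reproduces matrices and conserves totals", {
  set.seed(2)
  col <- simulate_msn_collection(n_meta = 3, n_sites = 4, J = 120,
                                 theta = 8, m = 0.2, seed = 11)
  dir <- tempfile()
  write_study_collection(col, dir)
  for (m in col$metacommunities) {
    tab <- read_abundance_table(file.path(dir, paste0(m$meta_id, ".tsv")),
                                quiet = TRUE)
    expect_identical(unname(tab), unname(m$n_matrix))
    expect_identical(sum(tab), sum(m$n_matrix))
  }
  pooled <- pool_study_collection(col)
  regrouped <- group_into_metacommunities(pooled$table, pooled$metadata)
  for (id in names(col$metacommunities)) {
    a <- col$metacommunities[[id]]$n_matrix
    b <- regrouped$metacommunities[[id]]$n_matrix
    expect_identical(a[order(rownames(a)), ], b[order(rownames(b)), ])
  }
})

test_that("BIOM v1 tables read identically to their TSV counterpart", {
  skip_if_not_installed("biomformat")
  m <- matrix(c(5L, 0L, 1L, 1L, 0L, 2L), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  f <- tempfile(fileext = ".biom")
  suppressWarnings(biomformat::write_biom(biomformat::make_biom(m), f))
  tab <- read_abundance_table(f, format = "biom", quiet = TRUE)
  expect_identical(unname(as.matrix(tab)), unname(m))
  expect_identical(rownames(tab), rownames(m))
})
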