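# Independent oracles used across tests.

# Exhaustive enumeration of Hoppe-urn histories: J individuals arrive one by
# one; individual i founds a new species with probability theta/(theta+i-1)
# or copies an existing individual's species with probability
# size/(theta+i-1).  Returns the exact probability of every abundance
# partition (named by sorted abundances, e.g. "2,1,1").
urn_partition_probs <- function(J, theta) {
  acc <- new.env(parent = emptyenv())
  recurse <- function(blocks, i, prob) {
    if (i > J) {
      key <- paste(sort(blocks, decreasing = TRUE), collapse = ",")
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + prob
      return(invisible())
    }
    denom <- theta + i - 1
    recurse(c(blocks, 1L), i + 1L, prob * theta / denom)
    for (b in seq_along(blocks)) {
      nb <- blocks
      nb[b] <- nb[b] + 1L
      recurse(nb, i + 1L, prob * blocks[b] / denom)
    }
  }
  recurse(integer(0), 1L, 1)
  out <- unlist(as.list(acc))
  out
}

# All abundance partitions of J (as list of integer vectors).
all_partitions <- function(J, max_part = J) {
  if (J == 0) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(J, max_part))) {
    for (rest in all_partitions(J - p, p)) {
      out[[length(out) + 1L]] <- c(p, rest)
    }
  }
  out
}

# Small deterministic taxa-by-sites fixture.
toy_meta <- function() {
  n <- matrix(c(5L, 1L, 0L,
                0L, 1L, 2L), nrow = 3,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  metacommunity("toy", n)
}

# Write a small abundance TSV; returns the path.
write_toy_tsv <- function(counts, taxa, samples, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(taxon = taxa, counts, check.names = FALSE)
  colnames(df) <- c("taxon", samples)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
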