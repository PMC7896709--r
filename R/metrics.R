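#' Hill numbers (diversity profile)
#'
#' Diversity of order q: `qD = (sum p_i^q)^(1/(1-q))` with the q = 1 limit
#' `exp(-sum p_i log p_i)` (exponential Shannon).  q = 0 is richness,
#' q = 2 the inverse Simpson concentration.
#'
#' @param counts Non-negative abundances (zeros ignored) or a
#'   `local_community`.
#' @param q Orders to evaluate.
#' @return Named numeric vector of `qD` values.
#' @export
hill_numbers <- function(counts, q = c(0, 1, 2)) {
  if (inherits(counts, "local_community")) counts <- counts$counts
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("all-zero abundance vector")
  p <- counts / sum(counts)
  vapply(q, function(qq) {
    if (abs(qq - 1) < 1e-12) exp(-sum(p * log(p)))
    else sum(p^qq)^(1 / (1 - qq))
  }, numeric(1)) -> out
  names(out) <- paste0("q", q)
  out
}

#' Shannon entropy of a community
#'
#' @inheritParams hill_numbers
#' @return Shannon entropy (nats).
#' @export
shannon_entropy <- function(counts) {
  if (inherits(counts, "local_community")) counts <- counts$counts
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("all-zero abundance vector")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Community and species dominance
#'
#' Community dominance is the Berger–Parker share of the most abundant
#' taxon.  Species dominance, defined for a metacommunity, is each taxon's
#' mean relative abundance across the member sites.
#'
#' @param x A `metacommunity`, a taxa-by-sites matrix, or a single
#'   abundance vector.
#' @return List with `community_dominance` (for a matrix, the dominance of
#'   the pooled community, plus `site_dominance` per site) and
#'   `species_dominance` (per-taxon mean relative abundance, matrices
#'   only).
#' @export
dominance <- function(x) {
  if (inherits(x, "metacommunity")) x <- x$n_matrix
  if (is.matrix(x)) {
    if (all(x == 0)) stop("all-zero abundance matrix")
    p <- sweep(x, 2L, colSums(x), "/")
    pooled <- rowSums(x) / sum(x)
    list(community_dominance = max(pooled),
         site_dominance = apply(p, 2L, max),
         species_dominance = rowMeans(p))
  } else {
    x <- x[x > 0]
    if (length(x) == 0L) stop("all-zero abundance vector")
    list(community_dominance = max(x) / sum(x),
         site_dominance = NULL, species_dominance = NULL)
  }
}

#' Community metrics for a metacommunity
#'
#' Per-site and pooled Hill numbers, Shannon entropy, and community /
#' species dominance — the covariate block fed to the regression stage.
#'
#' @param x A `metacommunity` or taxa-by-sites matrix.
#' @param top_decile_species Aggregate species dominance as the mean over
#'   the top decile of taxa by species dominance (default), else over all
#'   taxa.
#' @return List with `per_site` (data.frame of site, J, S, hill q0/q1/q2,
#'   shannon, dominance) and `meta` (pooled hill numbers, shannon,
#'   community and aggregated species dominance).
#' @export
community_metrics <- function(x, top_decile_species = TRUE) {
  n <- if (inherits(x, "metacommunity")) x$n_matrix else as.matrix(x)
  per_site <- do.call(rbind, lapply(seq_len(ncol(n)), function(j) {
    v <- n[, j]
    h <- hill_numbers(v)
    data.frame(site_id = colnames(n)[j], J = sum(v), S = sum(v > 0),
               hill0 = h[["q0"]], hill1 = h[["q1"]], hill2 = h[["q2"]],
               shannon = shannon_entropy(v),
               dominance = max(v) / sum(v))
  }))
  dom <- dominance(n)
  sd_vals <- sort(dom$species_dominance, decreasing = TRUE)
  k <- if (top_decile_species) max(1L, ceiling(length(sd_vals) / 10)) else length(sd_vals)
  pooled <- rowSums(n)
  h <- hill_numbers(pooled)
  list(per_site = per_site,
       meta = list(hill0 = h[["q0"]], hill1 = h[["q1"]], hill2 = h[["q2"]],
                   shannon = shannon_entropy(pooled),
                   community_dominance = dom$community_dominance,
                   species_dominance = mean(sd_vals[seq_len(k)])))
}
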