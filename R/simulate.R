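#' Simulate a collection of multisite neutral metacommunities
#'
#' Generates metacommunities under the full multisite neutral process: a
#' top-level CRP(`theta`) species pool feeding every site through
#' Chinese-restaurant-franchise seating with site concentrations
#' `I_j = m_j (J_j - 1) / (1 - m_j)`.  Column sums equal the requested site
#' sizes exactly.
#'
#' @param n_meta Number of metacommunities.
#' @param n_sites Sites (local communities) per metacommunity.
#' @param J Individuals (reads) per site: a scalar or vector of length
#'   `n_sites`.
#' @param theta Fundamental biodiversity number of the top-level pool.
#' @param m Immigration probability per site: scalar or length `n_sites`,
#'   each in (0, 1).
#' @param seed Optional seed; the full generator configuration and seed
#'   are recorded in the collection's `manifest` attribute.
#' @return A `study_collection` whose metacommunities are named
#'   `meta_001`, ... and whose taxa are generator-scoped `OTU_` labels.
#' @export
simulate_msn_collection <- function(n_meta = 20L, n_sites = 5L, J = 1000L,
                                    theta = 20, m = 0.1, seed = NULL) {
  if (any(m <= 0 | m >= 1)) stop("m must be in (0, 1)")
  if (any(J <= 0)) stop("J must be positive")
  if (!is.null(seed)) set.seed(seed)
  J <- rep_len(as.integer(J), n_sites)
  m <- rep_len(m, n_sites)
  I <- I_from_m(m, J)
  metas <- list()
  for (i in seq_len(n_meta)) {
    res <- simulate_crf_cpp(theta, I, J, NULL)
    counts <- res$counts
    id <- sprintf("meta_%03d", i)
    rownames(counts) <- sprintf("OTU_%06d", seq_len(nrow(counts)))
    colnames(counts) <- sprintf("%s_s%d", id, seq_len(ncol(counts)))
    metas[[id]] <- metacommunity(id, counts)
  }
  structure(list(metacommunities = metas, dataset_label = "msn_neutral"),
            class = "study_collection",
            manifest = list(generator = "msn_neutral", n_meta = n_meta,
                            n_sites = n_sites, J = J, theta = theta, m = m,
                            seed = seed))
}

#' Simulate a collection of niche-differentiated hybrid metacommunities
#'
#' Each site is a niche with its own birth/death ratio and immigration
#' parameter: `S` species abundances are drawn from the zero-truncated
#' negative-binomial kernel and rescaled multinomially to the requested
#' site size.  Niches draw their species from disjoint pools
#' (`overlap = 0`) through a single shared pool (`overlap = 1`).
#'
#' @param n_meta Number of metacommunities.
#' @param n_sites Niches (sites) per metacommunity.
#' @param J Individuals per site (scalar or length `n_sites`).
#' @param S Species per niche (scalar or length `n_sites`).
#' @param x_niche Birth-to-death ratio per niche (scalar or vector).
#' @param gamma_niche Immigration parameter per niche (scalar or vector).
#' @param overlap Fraction of each niche's species drawn from a shared
#'   pool, in `[0, 1]`.
#' @param seed Optional seed.
#' @return A `study_collection` with a `manifest` attribute.
#' @export
simulate_nnh_collection <- function(n_meta = 20L, n_sites = 5L, J = 1000L,
                                    S = 40L, x_niche = 0.9,
                                    gamma_niche = 0.5, overlap = 0,
                                    seed = NULL) {
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  J <- rep_len(as.integer(J), n_sites)
  S <- rep_len(as.integer(S), n_sites)
  x_niche <- rep_len(x_niche, n_sites)
  gamma_niche <- rep_len(gamma_niche, n_sites)
  metas <- list()
  for (i in seq_len(n_meta)) {
    id <- sprintf("meta_%03d", i)
    # species identities: a shared pool plus per-niche private blocks
    n_shared <- round(overlap * max(S))
    shared <- if (n_shared > 0) sprintf("OTU_S%05d", seq_len(n_shared))
      else character()
    cols <- list()
    for (j in seq_len(n_sites)) {
      k_shared <- min(round(overlap * S[j]), length(shared))
      ids <- c(if (k_shared > 0) shared[seq_len(k_shared)] else character(),
               sprintf("OTU_N%d_%05d", j, seq_len(S[j] - k_shared)))
      ab <- rztnb(S[j], x_niche[j], gamma_niche[j])
      counts <- stats::rmultinom(1L, J[j], ab)[, 1L]
      # multinomial rescaling can zero a species; re-seed each with one
      # individual taken from the largest cell so richness stays S_j
      while (any(counts == 0L)) {
        z <- which(counts == 0L)[1L]
        donor <- which.max(counts)
        counts[z] <- 1L
        counts[donor] <- counts[donor] - 1L
      }
      cols[[j]] <- stats::setNames(counts, ids)
    }
    taxa <- unique(unlist(lapply(cols, names)))
    n <- matrix(0L, length(taxa), n_sites,
                dimnames = list(taxa, sprintf("%s_s%d", id, seq_len(n_sites))))
    for (j in seq_len(n_sites)) n[names(cols[[j]]), j] <- cols[[j]]
    metas[[id]] <- metacommunity(id, n)
  }
  structure(list(metacommunities = metas, dataset_label = "nnh_hybrid"),
            class = "study_collection",
            manifest = list(generator = "nnh_hybrid", n_meta = n_meta,
                            n_sites = n_sites, J = J, S = S,
                            x_niche = x_niche, gamma_niche = gamma_niche,
                            overlap = overlap, seed = seed))
}

#' Simulate a collection of strongly non-neutral control metacommunities
#'
#' Negative control emulating deterministic niche structure (species
#' sorting): every site holds the same `S` taxa, each site's abundances
#' follow the same geometric series (niche preemption with fixed ratio
#' `k`), but the species-to-rank assignment is a fixed site-specific cyclic
#' rotation, so the dominant taxa are disjoint across sites while the taxa
#' themselves are shared.  Compositions are deterministic up to a small
#' multinomial perturbation (`noise` fraction of reads).  This pattern —
#' every taxon abundant somewhere and rare elsewhere, with near-zero
#' replicate variance — conflicts with a shared neutral metacommunity and
#' is the kind of composition the multisite neutral model fits poorly.
#'
#' @param n_meta Number of metacommunities.
#' @param n_sites Sites per metacommunity.
#' @param J Individuals per site.
#' @param S Species in the shared pool.
#' @param k Geometric-series preemption ratio in (0, 1); the top species
#'   holds a share close to `k` of its site.
#' @param noise Fraction of each site's reads allocated multinomially
#'   (default 0.05).
#' @param seed Optional seed.
#' @return A `study_collection` with a `manifest` attribute.
#' @export
simulate_non_neutral_collection <- function(n_meta = 20L, n_sites = 5L,
                                            J = 1000L, S = 30L, k = 0.7,
                                            noise = 0.05, seed = NULL) {
  if (k <= 0 || k >= 1) stop("k must be in (0, 1)")
  if (noise < 0 || noise > 1) stop("noise must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  J <- rep_len(as.integer(J), n_sites)
  p <- k * (1 - k)^(seq_len(S) - 1L)
  p <- p / sum(p)
  shift <- max(1L, S %/% n_sites)  # rotate ranks so dominants are disjoint
  taxa <- sprintf("OTU_%06d", seq_len(S))
  metas <- list()
  for (i in seq_len(n_meta)) {
    id <- sprintf("meta_%03d", i)
    n <- matrix(0L, S, n_sites,
                dimnames = list(taxa, sprintf("%s_s%d", id, seq_len(n_sites))))
    for (j in seq_len(n_sites)) {
      ranks <- 1L + (seq_len(S) - 1L + (j - 1L) * shift) %% S
      pj <- p[ranks]  # taxon r has rank ranks[r] at site j
      det <- floor((1 - noise) * J[j] * pj)
      rest <- J[j] - sum(det)
      n[, j] <- as.integer(det + stats::rmultinom(1L, rest, pj)[, 1L])
    }
    metas[[id]] <- metacommunity(id, n)
  }
  structure(list(metacommunities = metas, dataset_label = "non_neutral"),
            class = "study_collection",
            manifest = list(generator = "non_neutral", n_meta = n_meta,
                            n_sites = n_sites, J = J, S = S, k = k,
                            noise = noise, seed = seed))
}
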