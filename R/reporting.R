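#' Four-way MSN/NNH classification
#'
#' Deterministic mapping of the two metacommunity-level pass flags to the
#' four classes: passing MSN only, passing NNH only, passing both, or
#' passing none.  Undefined flags (untestable metacommunities) give `NA`
#' and are excluded from summaries rather than folded into "none".
#'
#' @param msn_pass,nnh_pass Logical vectors (recycled to common length).
#' @return Factor with levels `msn_only`, `nnh_only`, `both`, `none`.
#' @examples
#' classify_four_way(TRUE, FALSE)  # msn_only
#' classify_four_way(TRUE, TRUE)   # both
#' @export
classify_four_way <- function(msn_pass, nnh_pass) {
  n <- max(length(msn_pass), length(nnh_pass))
  msn_pass <- rep_len(as.logical(msn_pass), n)
  nnh_pass <- rep_len(as.logical(nnh_pass), n)
  out <- rep(NA_character_, n)
  ok <- !is.na(msn_pass) & !is.na(nnh_pass)
  out[ok & msn_pass & !nnh_pass] <- "msn_only"
  out[ok & !msn_pass & nnh_pass] <- "nnh_only"
  out[ok & msn_pass & nnh_pass] <- "both"
  out[ok & !msn_pass & !nnh_pass] <- "none"
  factor(out, levels = c("msn_only", "nnh_only", "both", "none"))
}

#' Run the full MSN + NNH pipeline over a study collection
#'
#' For every metacommunity: fit the MSN model by Gibbs sampling, run the
#' metacommunity- and local-level posterior-predictive neutrality tests,
#' fit the niche-neutral hybrid model, and compute the community metrics.
#' Returns one row per metacommunity with everything the reporting and
#' regression stages need.
#'
#' @param collection A `study_collection`.
#' @param iterations,burn_in,thin Gibbs schedule passed to [fit_msn()].
#' @param threshold Pass threshold for all tests.
#' @param seed Optional seed controlling the whole run.
#' @param quiet Suppress per-metacommunity progress messages.
#' @return A data.frame of class `msnnh_results` with columns `meta_id`,
#'   `theta`, `M`, `X`, `Y`, `p_meta`, `p_local`, `msn_meta_pass`,
#'   `msn_local_pass`, `chi2_total`, `p_nnh`, `nnh_meta_pass`,
#'   `nnh_pct_local_pass`, `nnh_untestable`, plus the metric covariates.
#' @export
run_msnnh <- function(collection, iterations = 5000L, burn_in = 2500L,
                      thin = 10L, threshold = 0.05, seed = NULL,
                      quiet = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(collection$metacommunities, function(meta) {
    if (!quiet) message("fitting ", meta$meta_id)
    fit <- fit_msn(meta, iterations = iterations, burn_in = burn_in,
                   thin = thin)
    tm <- neutrality_test(fit, "meta", threshold)
    tl <- neutrality_test(fit, "local", threshold)
    nn <- fit_nnh(meta, threshold)
    cm <- community_metrics(meta)
    xy <- coef(nn)
    data.frame(meta_id = meta$meta_id,
               n_sites = ncol(meta$n_matrix), K = meta$K,
               theta = stats::median(fit$theta),
               M = mean(apply(fit$m, 2L, stats::median)),
               X = xy[["X"]], Y = xy[["Y"]],
               p_meta = tm$p, p_local = tl$p,
               msn_meta_pass = tm$pass, msn_local_pass = tl$pass,
               chi2_total = nn$chi2_total, p_nnh = nn$p_meta,
               nnh_meta_pass = if (isTRUE(nn$untestable)) NA else nn$pass_meta,
               nnh_pct_local_pass = nn$pct_local_pass,
               nnh_untestable = isTRUE(nn$untestable),
               community_dominance = cm$meta$community_dominance,
               species_dominance = cm$meta$species_dominance,
               hill0 = cm$meta$hill0, hill1 = cm$meta$hill1,
               hill2 = cm$meta$hill2, shannon = cm$meta$shannon)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("msnnh_results", "data.frame")
  attr(out, "dataset_label") <- collection$dataset_label
  out
}

#' Summarize pass rates and the four-way classification
#'
#' Aggregates per-metacommunity results into the two summary surfaces of a
#' multisite neutrality study: pass counts and percentages for each model
#' and level, and the four-way MSN/NNH classification with percentages.
#' Percentage identities hold exactly before rounding; rounding to one
#' decimal is applied for display only.
#'
#' @param results A results data.frame from [run_msnnh()] (or any
#'   data.frame with `msn_meta_pass`, `msn_local_pass`, `nnh_meta_pass`,
#'   `nnh_pct_local_pass` columns), optionally with a `dataset` column for
#'   stratified rows.
#' @return An object of class `msnnh_summary`: `pass_rates` (one row per
#'   dataset: N, MSN meta/local pass counts and percentages, NNH
#'   metacommunity pass count and percentage, average niche-level pass
#'   percentage), `four_way` (counts and percentages per class, plus the
#'   untestable count in its own column), and `classification` (the
#'   per-metacommunity factor).
#' @export
summarize_msnnh <- function(results) {
  if (!"dataset" %in% names(results))
    results$dataset <- attr(results, "dataset_label") %||% "study"
  cls <- classify_four_way(results$msn_meta_pass, results$nnh_meta_pass)
  by_ds <- split(seq_len(nrow(results)), results$dataset)
  pass_rates <- do.call(rbind, lapply(names(by_ds), function(ds) {
    i <- by_ds[[ds]]
    N <- length(i)
    data.frame(dataset = ds, N = N,
               msn_meta_pass = sum(results$msn_meta_pass[i]),
               msn_meta_pct = 100 * mean(results$msn_meta_pass[i]),
               msn_local_pass = sum(results$msn_local_pass[i]),
               msn_local_pct = 100 * mean(results$msn_local_pass[i]),
               nnh_meta_pass = sum(results$nnh_meta_pass[i], na.rm = TRUE),
               nnh_meta_pct = 100 * mean(results$nnh_meta_pass[i], na.rm = TRUE),
               nnh_avg_local_pct = mean(results$nnh_pct_local_pass[i],
                                        na.rm = TRUE))
  }))
  four_way <- do.call(rbind, lapply(names(by_ds), function(ds) {
    i <- by_ds[[ds]]
    tab <- table(cls[i])
    n_cls <- sum(tab)
    pct <- if (n_cls > 0) 100 * as.numeric(tab) / n_cls else rep(0, 4)
    data.frame(dataset = ds, N = length(i),
               msn_only = as.numeric(tab)[1], msn_only_pct = pct[1],
               nnh_only = as.numeric(tab)[2], nnh_only_pct = pct[2],
               both = as.numeric(tab)[3], both_pct = pct[3],
               none = as.numeric(tab)[4], none_pct = pct[4],
               untestable = sum(is.na(cls[i])))
  }))
  structure(list(pass_rates = pass_rates, four_way = four_way,
                 classification = cls),
            class = "msnnh_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.msnnh_summary <- function(x, ...) {
  cat("Pass rates (counts and %):\n")
  pr <- x$pass_rates
  pr[vapply(pr, is.numeric, logical(1))] <-
    lapply(pr[vapply(pr, is.numeric, logical(1))], round, 1)
  print(pr, row.names = FALSE)
  cat("\nFour-way MSN/NNH classification:\n")
  fw <- x$four_way
  fw[vapply(fw, is.numeric, logical(1))] <-
    lapply(fw[vapply(fw, is.numeric, logical(1))], round, 1)
  print(fw, row.names = FALSE)
  invisible(x)
}

#' @export
plot.msnnh_summary <- function(x, ...) {
  fw <- x$four_way
  m <- t(as.matrix(fw[, c("msn_only_pct", "nnh_only_pct", "both_pct",
                          "none_pct")]))
  colnames(m) <- fw$dataset
  graphics::barplot(m, beside = TRUE,
                    legend.text = c("MSN only", "NNH only", "both", "none"),
                    ylab = "% of metacommunities", ...)
  invisible(x)
}

#' Write summary tables to TSV
#'
#' @param x An `msnnh_summary`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_msnnh_summary <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "pass_rates.tsv")
  p2 <- file.path(dir, "four_way.tsv")
  utils::write.table(x$pass_rates, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$four_way, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
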