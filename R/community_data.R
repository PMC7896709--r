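#' Construct a local community
#'
#' A local community is one sampled site: a named vector of integer read
#' counts (reads treated as individuals), with its total size `J` and
#' observed richness `S`.
#'
#' @param site_id Character label for the site (sample).
#' @param counts Named non-negative integer vector of taxon abundances.
#' @return An object of class `local_community` with elements `site_id`,
#'   `counts`, `J` (total individuals) and `S` (taxa with positive counts).
#' @export
local_community <- function(site_id, counts) {
  if (is.null(names(counts)) || anyNA(names(counts)))
    stop("counts must be a named vector of taxon abundances")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integers")
  counts <- as.integer(round(counts))
  names(counts) <- names(counts)
  structure(list(site_id = as.character(site_id), counts = counts,
                 J = sum(counts), S = sum(counts > 0L)),
            class = "local_community")
}

#' Construct a metacommunity
#'
#' A metacommunity is the set of all sampled sites (local communities) of
#' one subject, sharing a single taxon index: a taxa-by-sites integer count
#' matrix.  Taxa absent from every site are dropped; at least two sites are
#' required (the multisite setting).
#'
#' @param meta_id Character label (subject, or subject x habitat).
#' @param n_matrix Integer matrix, taxa in rows, sites in columns, with
#'   dimnames.
#' @return An object of class `metacommunity` with elements `meta_id`,
#'   `n_matrix`, `K` (number of taxa), `sites` (list of
#'   [local_community()]), `J` (per-site totals).
#' @export
metacommunity <- function(meta_id, n_matrix) {
  n_matrix <- as.matrix(n_matrix)
  if (is.null(rownames(n_matrix)))
    rownames(n_matrix) <- sprintf("OTU_%06d", seq_len(nrow(n_matrix)))
  if (is.null(colnames(n_matrix)))
    colnames(n_matrix) <- sprintf("site_%d", seq_len(ncol(n_matrix)))
  if (any(n_matrix < 0)) stop("negative counts are not allowed")
  if (any(n_matrix != round(n_matrix))) stop("counts must be integers")
  storage.mode(n_matrix) <- "integer"
  keep <- rowSums(n_matrix) > 0L
  n_matrix <- n_matrix[keep, , drop = FALSE]
  if (nrow(n_matrix) == 0L) stop("metacommunity has no positive counts")
  if (ncol(n_matrix) < 2L)
    stop("a metacommunity needs at least 2 sites")
  sites <- lapply(seq_len(ncol(n_matrix)), function(j)
    local_community(colnames(n_matrix)[j],
                    stats::setNames(n_matrix[, j], rownames(n_matrix))))
  structure(list(meta_id = as.character(meta_id), n_matrix = n_matrix,
                 K = nrow(n_matrix), sites = sites,
                 J = stats::setNames(as.integer(colSums(n_matrix)),
                                     colnames(n_matrix))),
            class = "metacommunity")
}

#' @export
print.metacommunity <- function(x, ...) {
  cat("Metacommunity", x$meta_id, "-", x$K, "taxa x", ncol(x$n_matrix),
      "sites; J =", paste(x$J, collapse = ", "), "\n")
  invisible(x)
}

#' Read a taxa-by-samples abundance table
#'
#' Reads an OTU/taxon count table from tab-separated text (taxa in rows,
#' first column the taxon id, header row of sample ids) or BIOM v1 JSON
#' (through the biomformat package).
#'
#' @param path Path to the input file.
#' @param format `"tsv"` or `"biom"`.
#' @param strict If `TRUE` (default) fractional counts are a validation
#'   error; if `FALSE` they are rounded.
#' @param quiet Suppress the dimension log line.
#' @return Integer matrix of counts with taxon rownames and sample colnames,
#'   in file order.
#' @export
read_abundance_table <- function(path, format = c("tsv", "biom"),
                                 strict = TRUE, quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required for format = 'biom'")
    b <- biomformat::read_biom(path)
    tab <- as.matrix(biomformat::biom_data(b))
  } else {
    raw <- tryCatch(
      utils::read.delim(path, header = TRUE, sep = "\t",
                        check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (nrow(raw) == 0L || ncol(raw) < 2L)
      stop("parse error: no data rows/sample columns in ", path)
    ids <- as.character(raw[[1L]])
    tab <- as.matrix(raw[, -1L, drop = FALSE])
    if (!is.numeric(tab)) {
      bad <- which(!apply(raw[, -1L, drop = FALSE], 1L,
                          function(r) all(!is.na(suppressWarnings(as.numeric(r))))))
      stop("parse error: non-numeric count at data line ",
           if (length(bad)) bad[1L] else NA)
    }
    rownames(tab) <- ids
  }
  if (anyNA(tab)) stop("validation error: missing counts")
  if (any(tab < 0)) stop("validation error: negative counts")
  if (any(tab != round(tab))) {
    if (strict)
      stop("validation error: fractional counts (set strict = FALSE to round)")
    tab <- round(tab)
  }
  storage.mode(tab) <- "integer"
  if (!quiet)
    message("read abundance table: ", nrow(tab), " taxa x ", ncol(tab),
            " samples from ", path)
  tab
}

#' Group a count table into metacommunities
#'
#' Splits a taxa-by-samples table into per-subject metacommunities using a
#' sample-to-metacommunity map.  All-zero sample columns are dropped with a
#' warning; taxa absent from a metacommunity are dropped from its index;
#' metacommunities left with fewer than two sites are excluded (the
#' multisite models do not apply) and recorded in the `excluded` attribute.
#'
#' @param table Integer matrix from [read_abundance_table()].
#' @param metadata Either a named character vector (names = sample ids,
#'   values = metacommunity ids) or a data.frame whose first two columns are
#'   sample id and metacommunity id.
#' @param dataset_label Label stored on the collection.
#' @return An object of class `study_collection`: a list with
#'   `metacommunities` (named list of [metacommunity()]) and
#'   `dataset_label`, plus an `excluded` attribute naming metacommunities
#'   dropped for having fewer than two usable sites.
#' @export
group_into_metacommunities <- function(table, metadata,
                                       dataset_label = "study") {
  if (is.data.frame(metadata)) {
    map <- stats::setNames(as.character(metadata[[2L]]),
                           as.character(metadata[[1L]]))
  } else map <- metadata
  samples <- colnames(table)
  missing <- setdiff(samples, names(map))
  if (length(missing))
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
  zero <- samples[colSums(table) == 0L]
  if (length(zero)) {
    warning("dropping all-zero sample(s): ", paste(zero, collapse = ", "))
    table <- table[, setdiff(samples, zero), drop = FALSE]
    samples <- colnames(table)
  }
  metas <- list()
  excluded <- character()
  for (id in unique(map[samples])) {
    cols <- samples[map[samples] == id]
    if (length(cols) < 2L) {
      message("excluding metacommunity ", id,
              ": fewer than 2 usable sites")
      excluded <- c(excluded, id)
      next
    }
    metas[[id]] <- metacommunity(id, table[, cols, drop = FALSE])
  }
  structure(list(metacommunities = metas, dataset_label = dataset_label),
            class = "study_collection", excluded = excluded)
}

#' @export
print.study_collection <- function(x, ...) {
  cat("Study collection '", x$dataset_label, "': ",
      length(x$metacommunities), " metacommunities\n", sep = "")
  invisible(x)
}

#' Write a study collection to per-metacommunity TSV matrices
#'
#' Writes one `<meta_id>.tsv` count matrix per metacommunity plus a
#' `manifest.tsv` of metacommunity id, number of sites, and per-site J.
#'
#' @param x A `study_collection`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_study_collection <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(x$metacommunities, function(m) {
    out <- data.frame(taxon = rownames(m$n_matrix), m$n_matrix,
                      check.names = FALSE)
    utils::write.table(out, file.path(dir, paste0(m$meta_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    data.frame(meta_id = m$meta_id, n_sites = ncol(m$n_matrix),
               J = paste(m$J, collapse = ","))
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Pool a study collection back into one table and metadata map
#'
#' Inverse of [group_into_metacommunities()] over the union taxon index:
#' useful for round-tripping through TSV.
#'
#' @param x A `study_collection`.
#' @return List with `table` (taxa x all samples integer matrix) and
#'   `metadata` (named vector sample -> meta_id).
#' @export
pool_study_collection <- function(x) {
  taxa <- sort(unique(unlist(lapply(x$metacommunities,
                                    function(m) rownames(m$n_matrix)))))
  cols <- list()
  map <- character()
  for (m in x$metacommunities) {
    block <- matrix(0L, length(taxa), ncol(m$n_matrix),
                    dimnames = list(taxa, colnames(m$n_matrix)))
    block[rownames(m$n_matrix), ] <- m$n_matrix
    cols[[m$meta_id]] <- block
    map[colnames(m$n_matrix)] <- m$meta_id
  }
  list(table = do.call(cbind, cols), metadata = map)
}
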