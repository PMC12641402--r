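#' Read / write delimited time-series and metadata tables
#'
#' Time series are stored as tab-separated text, rows = timepoints,
#' columns = regions (header row of region ids). Region metadata is a
#' tab-separated table with columns `region_id`, `hemisphere`, `network`,
#' `x`, `y`, `z`, `parcel_id`.
#'
#' @param ts Timepoints-by-regions matrix.
#' @param path File path.
#' @return `write_timeseries` invisibly returns `path`;
#'   `read_timeseries` returns a numeric matrix with region-id colnames.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !is.null(colnames(ts)))
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
}

#' @rdname write_timeseries
#' @param meta Region metadata data frame.
#' @export
write_region_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_region_meta <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Reading delegates to [fgsea::gmtPathways()].
#'
#' @param gene_sets Named list of character vectors.
#' @param path File path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return `write_gmt` invisibly returns `path`; `read_gmt` returns a
#'   named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path, descriptions = names(gene_sets)) {
  stopifnot(length(descriptions) == length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a connectivity matrix with a JSON sidecar
#'
#' The matrix goes to `<path>.tsv` (tab-separated, region ids as header
#' and first column); acquisition and processing parameters go to
#' `<path>.json`.
#'
#' @param z Symmetric Fisher-z matrix with region-id dimnames.
#' @param path Path stem (no extension).
#' @param hemisphere `"L"` or `"R"`.
#' @param params Named list of extra parameters for the sidecar.
#' @return Invisibly, the two file paths.
#' @export
write_connectivity <- function(z, path, hemisphere, params = list()) {
  tsv <- paste0(path, ".tsv")
  js <- paste0(path, ".json")
  utils::write.table(z, tsv, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  side <- c(list(hemisphere = hemisphere, region_ids = colnames(z),
                 transform = "fisher-z", clip = 1 - 1e-6), params)
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv, js))
}

#' Export a synthetic study to a directory of delimited text files
#'
#' Writes per-subject time series (`ref_*.tsv`, `<subject>_<session>.tsv`),
#' the region metadata (`regions.tsv`), patient covariates
#' (`covariates.tsv`) and the planted ground truth (`truth.json`).
#'
#' @param study A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_region_meta(study$spec$meta, file.path(dir, "regions.tsv"))
  utils::write.table(study$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(study$reference)) {
    write_timeseries(study$reference[[i]],
                     file.path(dir, sprintf("ref_%03d.tsv", i)))
  }
  for (id in names(study$patients)) {
    for (sess in names(study$patients[[id]])) {
      write_timeseries(study$patients[[id]][[sess]],
                       file.path(dir, paste0(id, "_", sess, ".tsv")))
    }
  }
  truth <- lapply(seq_along(study$effects), function(k) {
    e <- study$effects[[k]]
    list(target = if (is.character(e$target)) e$target else "explicit",
         baseline_shift = e$baseline_shift, attenuation = e$attenuation,
         direction = e$direction,
         connections = study$truth[[k]][, c("region_a", "region_b",
                                            "hemisphere")])
  })
  jsonlite::write_json(
    list(effects = truth, log = study$log,
         tr_seconds = study$spec$tr_seconds),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
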