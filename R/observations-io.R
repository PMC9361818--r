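#' @include AllClasses.R
NULL

#' Read pooled-sample observations from TSV
#'
#' Long format, one row per allele call:
#' `read_id  sample_id  site_index  allele_index` (tab-separated, with
#' header).  `site_index` is 0-based into the panel's site list (converted to
#' 1-based internally); `allele_index` is the 0-based observed allele.
#'
#' @param path observations TSV.
#' @param metadata optional data.frame keyed by `sample_id` whose remaining
#'   columns become each sample's metadata.
#' @return Named list of [PooledSample-class] objects, one per `sample_id`,
#'   in order of first appearance.
#' @export
readObservations <- function(path, metadata = NULL) {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed observations TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("read_id", "sample_id", "site_index", "allele_index")
  if (!all(need %in% names(tab)))
    stop("observations TSV '", path, "' must have columns ",
         paste(need, collapse = ", "))
  sampleIds <- unique(tab$sample_id)
  out <- lapply(sampleIds, function(sid) {
    sub <- tab[tab$sample_id == sid, , drop = FALSE]
    md <- list()
    if (!is.null(metadata)) {
      row <- metadata[metadata$sample_id == sid, , drop = FALSE]
      if (nrow(row) == 1L)
        md <- as.list(row[, setdiff(names(row), "sample_id"), drop = FALSE])
    }
    pooledSample(sid,
                 data.frame(read = sub$read_id,
                            site = sub$site_index + 1L,
                            allele = sub$allele_index),
                 metadata = md)
  })
  names(out) <- sampleIds
  out
}

#' Write pooled-sample observations to TSV
#'
#' Inverse of [readObservations()] (same long format, 0-based
#' `site_index`).
#'
#' @param samples a [PooledSample-class] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeObservations <- function(samples, path) {
  if (is(samples, "PooledSample")) samples <- list(samples)
  parts <- lapply(samples, function(s)
    data.frame(read_id = s@readIds[s@calls$read],
               sample_id = s@sampleId,
               site_index = s@calls$site - 1L,
               allele_index = s@calls$allele))
  utils::write.table(do.call(rbind, parts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
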