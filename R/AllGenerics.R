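#' @include AllClasses.R
NULL

#' Accessors for nodpool classes
#'
#' `strainIds()` returns strain names; `nStrains()` / `nSites()` the panel
#' dimensions; `siteInfo()` the per-site metadata; `alleleMatrix()` the
#' strains x sites matrix of 0-based allele indices; `frequencies()` the
#' estimated strain frequency vector; `converged()` the EM convergence flag;
#' `nReads()` the number of reads in a pooled sample.
#'
#' @param x a [StrainPanel-class], [PooledSample-class] or
#'   [FrequencyEstimate-class] object as appropriate.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("strainIds", function(x) standardGeneric("strainIds"))
#' @rdname accessors
#' @export
setGeneric("nStrains", function(x) standardGeneric("nStrains"))
#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))
#' @rdname accessors
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setMethod("strainIds", "StrainPanel", function(x) x@strainIds)
#' @rdname accessors
#' @export
setMethod("nStrains", "StrainPanel", function(x) length(x@strainIds))
#' @rdname accessors
#' @export
setMethod("nSites", "StrainPanel", function(x) nrow(x@sites))
#' @rdname accessors
#' @export
setMethod("siteInfo", "StrainPanel", function(x) x@sites)
#' @rdname accessors
#' @export
setMethod("alleleMatrix", "StrainPanel", function(x) x@alleles)
#' @rdname accessors
#' @export
setMethod("nReads", "PooledSample", function(x) length(x@readIds))
#' @rdname accessors
#' @export
setMethod("sampleId", "PooledSample", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("sampleId", "FrequencyEstimate", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("frequencies", "FrequencyEstimate", function(x) x@frequencies)
#' @rdname accessors
#' @export
setMethod("converged", "FrequencyEstimate", function(x) x@converged)

setMethod("show", "StrainPanel", function(object) {
  nNA <- sum(is.na(object@alleles))
  cat("StrainPanel:", nStrains(object), "strains x", nSites(object),
      "SNP sites\n")
  if (nNA) cat("  ", nNA, "missing/ambiguous calls (run filterUnambiguous)\n")
  cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "PooledSample", function(object) {
  cat("PooledSample", object@sampleId, ":", nReads(object), "reads,",
      nrow(object@calls), "allele calls\n")
  if (length(object@metadata)) {
    md <- vapply(object@metadata, function(v) paste(v, collapse = ","), "")
    cat("  ", paste(names(md), md, sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "FrequencyEstimate", function(object) {
  f <- object@frequencies
  shown <- ifelse(f < 1e-6, 0, f)  # display floor only; slot keeps exact values
  top <- sort(shown, decreasing = TRUE)[seq_len(min(5L, length(f)))]
  cat("FrequencyEstimate for sample", object@sampleId, "\n")
  cat("  ", length(f), " strains, ", object@nReadsUsed, " reads, loglik ",
      format(object@loglik), ", ", object@nIter, " EM iterations (",
      if (object@converged) "converged" else "not converged", ")\n", sep = "")
  cat("  top strains:",
      paste(names(top), format(top, digits = 3), sep = "=", collapse = " "),
      "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nStrains, "strains,", object@nSites,
      "sites,", object@readsPerSample, "reads/sample, error rate",
      object@errorRate, ", seed", object@seed, "\n")
  cat("  communities:",
      paste(names(object@communities), lengths(object@communities),
            sep = "=", collapse = " "), "\n")
})
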