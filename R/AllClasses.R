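#' @import methods
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' StrainPanel: a strain x SNP-site haplotype reference
#'
#' Holds the haplotypes of a set of reference strains at segregating SNP
#' sites.  This is the panel against which pooled reads are scored.  Allele
#' values are 0-based indices into the site's allele list (0 = REF, k = k-th
#' ALT); `NA` marks a missing or ambiguous (heterozygous) call, to be removed
#' with [filterUnambiguous()] before estimation.
#'
#' @slot strainIds character vector of unique strain names (rows).
#' @slot sites data.frame with columns `chrom`, `pos` (1-based), `ref`
#'   (single base) and `alt` (comma-separated ALT bases), one row per site.
#' @slot alleles integer matrix, strains x sites, of 0-based allele indices
#'   (`NA` = missing/ambiguous).
#' @slot provenance free-text description of where the panel came from.
#'
#' @seealso [loadPanel()], [filterUnambiguous()], [validatePanel()]
#' @exportClass StrainPanel
setClass("StrainPanel",
  representation(
    strainIds  = "character",
    sites      = "data.frame",
    alleles    = "matrix",
    provenance = "character"
  )
)

setValidity("StrainPanel", function(object) {
  msgs <- character()
  n <- length(object@strainIds)
  L <- nrow(object@sites)
  if (anyDuplicated(object@strainIds))
    msgs <- c(msgs, "strain ids must be unique")
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(object@sites)))
    msgs <- c(msgs, "sites must have columns chrom, pos, ref, alt")
  if (nrow(object@alleles) != n)
    msgs <- c(msgs, "allele matrix rows must match strainIds")
  if (ncol(object@alleles) != L)
    msgs <- c(msgs, "allele matrix columns must match sites")
  if (!is.integer(object@alleles) && !all(is.na(object@alleles)))
    msgs <- c(msgs, "allele matrix must be integer")
  if (L > 0) {
    if (any(object@sites$pos < 1))
      msgs <- c(msgs, "site positions must be >= 1 (1-based, VCF convention)")
    if (!all(object@sites$ref %in% VALID_BASES))
      msgs <- c(msgs, "ref alleles must be single bases A/C/G/T")
    altList <- strsplit(object@sites$alt, ",", fixed = TRUE)
    if (any(lengths(altList) < 1L) ||
        !all(unlist(altList) %in% VALID_BASES))
      msgs <- c(msgs, "each site needs >= 1 alt allele from A/C/G/T")
    nAlt <- lengths(altList)
    bad <- object@alleles > rep(nAlt, each = n) | object@alleles < 0L
    if (any(bad, na.rm = TRUE))
      msgs <- c(msgs, "allele indices must lie in 0..(number of alt alleles)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a StrainPanel
#'
#' @param strainIds character vector of unique strain names.
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @param alleles strains x sites matrix of 0-based allele indices
#'   (coerced to integer); `NA` = missing/ambiguous.
#' @param provenance free-text source description.
#' @return A [StrainPanel-class] object.
#' @export
strainPanel <- function(strainIds, sites, alleles,
                        provenance = "constructed in R") {
  alleles <- matrix(as.integer(alleles), nrow = length(strainIds),
                    dimnames = list(strainIds, NULL))
  sites <- as.data.frame(sites)
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  rownames(sites) <- NULL
  new("StrainPanel", strainIds = as.character(strainIds), sites = sites,
      alleles = alleles, provenance = provenance)
}

#' PooledSample: reads from one pooled-sequencing sample
#'
#' A pooled DNA sample reduced to per-read allele calls at the panel's SNP
#' sites.  Reads covering zero panel sites carry no information and are
#' excluded upstream.
#'
#' @slot sampleId sample identifier, unique within an experiment.
#' @slot readIds character vector, one id per read.
#' @slot calls data.frame with integer columns `read` (1-based index into
#'   `readIds`), `site` (1-based index into the panel's sites) and `allele`
#'   (0-based observed allele index).  Within a read, site indices are
#'   strictly increasing.
#' @slot metadata named list of factor levels (host, nitrogen, density,
#'   community, replicate); may be empty.
#' @exportClass PooledSample
setClass("PooledSample",
  representation(
    sampleId = "character",
    readIds  = "character",
    calls    = "data.frame",
    metadata = "list"
  )
)

setValidity("PooledSample", function(object) {
  msgs <- character()
  cl <- object@calls
  if (!all(c("read", "site", "allele") %in% names(cl)))
    return("calls must have columns read, site, allele")
  if (length(object@sampleId) != 1L)
    msgs <- c(msgs, "sampleId must be a single string")
  nr <- length(object@readIds)
  if (nrow(cl)) {
    if (min(cl$read) < 1L || max(cl$read) > nr)
      msgs <- c(msgs, "call read indices out of range")
    if (any(cl$site < 1L))
      msgs <- c(msgs, "site indices must be >= 1")
    if (any(cl$allele < 0L))
      msgs <- c(msgs, "allele indices must be >= 0")
    d <- diff(cl$site)
    sameRead <- diff(cl$read) == 0L
    if (any(sameRead & d <= 0L))
      msgs <- c(msgs, "site indices must be strictly increasing within a read")
    if (!all(seq_len(nr) %in% cl$read))
      msgs <- c(msgs, "every read must have >= 1 call")
  } else if (nr > 0L) {
    msgs <- c(msgs, "every read must have >= 1 call")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PooledSample
#'
#' @param sampleId sample identifier.
#' @param calls data.frame with columns `read` (read index or read id),
#'   `site` (1-based panel site index) and `allele` (0-based allele index).
#'   Rows are sorted by read then site.
#' @param readIds optional character vector of read ids; derived from
#'   `calls$read` when that column is character.
#' @param metadata named list of factor levels.
#' @return A [PooledSample-class] object.
#' @export
pooledSample <- function(sampleId, calls, readIds = NULL, metadata = list()) {
  calls <- as.data.frame(calls)
  if (is.character(calls$read) || is.factor(calls$read)) {
    ids <- as.character(calls$read)
    if (is.null(readIds)) readIds <- unique(ids)
    calls$read <- match(ids, readIds)
    if (anyNA(calls$read)) stop("calls reference read ids absent from readIds")
  } else if (is.null(readIds)) {
    readIds <- paste0("read", seq_len(max(calls$read, 0L)))
  }
  calls$read <- as.integer(calls$read)
  calls$site <- as.integer(calls$site)
  calls$allele <- as.integer(calls$allele)
  calls <- calls[order(calls$read, calls$site), , drop = FALSE]
  rownames(calls) <- NULL
  new("PooledSample", sampleId = as.character(sampleId),
      readIds = as.character(readIds), calls = calls, metadata = metadata)
}

#' FrequencyEstimate: estimated strain frequencies for one sample
#'
#' Result of [emEstimate()]: the maximum-likelihood strain frequency vector
#' for a pooled sample under the finite-mixture read model, with convergence
#' diagnostics.
#'
#' @slot sampleId sample identifier.
#' @slot frequencies named numeric vector over panel strains; non-negative,
#'   summing to 1.
#' @slot loglik final mixture log-likelihood.
#' @slot loglikTrace log-likelihood after each EM iteration (non-decreasing).
#' @slot nReadsUsed number of reads entering the likelihood.
#' @slot nIter number of EM iterations run.
#' @slot converged whether the tolerance was reached before `maxIter`.
#' @slot errorRate per-site sequencing error rate used.
#' @exportClass FrequencyEstimate
setClass("FrequencyEstimate",
  representation(
    sampleId    = "character",
    frequencies = "numeric",
    loglik      = "numeric",
    loglikTrace = "numeric",
    nReadsUsed  = "integer",
    nIter       = "integer",
    converged   = "logical",
    errorRate   = "numeric"
  )
)

setValidity("FrequencyEstimate", function(object) {
  f <- object@frequencies
  msgs <- character()
  if (any(f < 0)) msgs <- c(msgs, "frequencies must be non-negative")
  if (length(f) && abs(sum(f) - 1) > 1e-9)
    msgs <- c(msgs, "frequencies must sum to 1 within 1e-9")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of a simulated select-and-resequence study
#'
#' Defaults mirror the study design the package analyses: 68 strains at
#' near-equal initial frequencies, nested communities (C68 > C8 > C3 > all
#' pairs of the C3 members), two host genotypes differing in selectivity and
#' nodule number, a 100-fold density contrast, low-level nitrogen addition,
#' finite nodule pools, and pooled short-read sequencing at ~65x mean depth.
#'
#' @slot nStrains number of strains in the panel (default 68).
#' @slot nSites number of unambiguous SNP sites (default 1000).
#' @slot pairwiseDiffProb per-site probability that two random strains differ
#'   (default 0.5).
#' @slot communities named list of strain index vectors; must be nested
#'   subsets for the complexity comparisons to be meaningful.
#' @slot inoculumJitterSd sd of lognormal jitter around equal inoculum
#'   frequencies (default 0.2, giving a spread comparable to mixing equal
#'   culture volumes).
#' @slot nInitialSeqReplicates sequencing replicates of each initial
#'   community (default 4).
#' @slot selectionSd per-host sd of strain selection coefficients (log
#'   scale); A17 is the more selective host.
#' @slot densityMultiplier per-host multiplier applied to selection
#'   coefficients in the high-density treatment.
#' @slot nitrogenMultiplier per-host multiplier applied in the N-addition
#'   treatment.
#' @slot noduleRange named list host -> c(min, max) nodules per pool
#'   (defaults A17 300-500, R108 100-200).
#' @slot nReplicatePots named numeric: replicate pots per community type
#'   (C68 6, C8 5, C3 5, pairwise 4).
#' @slot readsPerSample reads per pooled sample (default 21667, i.e. ~65x
#'   depth at 1000 sites with 3 sites per read).
#' @slot sitesPerRead panel sites covered by one read (default 3).
#' @slot errorRate per-site sequencing error rate (default 0.005).
#' @slot seed RNG seed (mandatory).
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nStrains             = "integer",
    nSites               = "integer",
    pairwiseDiffProb     = "numeric",
    communities          = "list",
    inoculumJitterSd     = "numeric",
    nInitialSeqReplicates = "integer",
    selectionSd          = "numeric",
    densityMultiplier    = "numeric",
    nitrogenMultiplier   = "numeric",
    noduleRange          = "list",
    nReplicatePots       = "numeric",
    readsPerSample       = "integer",
    sitesPerRead         = "integer",
    errorRate            = "numeric",
    seed                 = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@nStrains < 1L || object@nSites < 1L ||
      object@readsPerSample < 1L || object@sitesPerRead < 1L)
    msgs <- c(msgs, "all counts must be positive")
  if (object@pairwiseDiffProb <= 0 || object@pairwiseDiffProb > 1)
    msgs <- c(msgs, "pairwiseDiffProb must be in (0, 1]")
  if (object@errorRate < 0 || object@errorRate > 1)
    msgs <- c(msgs, "errorRate must be in [0, 1]")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed is mandatory")
  comm <- object@communities
  if (any(vapply(comm, function(m) any(m < 1L | m > object@nStrains), TRUE)))
    msgs <- c(msgs, "community members out of strain range")
  # nesting: every non-pairwise community must be a subset of every larger one
  core <- comm[order(-lengths(comm))]
  core <- core[!grepl("^P", names(core))]
  if (length(core) > 1L)
    for (i in seq_len(length(core) - 1L))
      if (!all(core[[i + 1L]] %in% core[[i]]))
        msgs <- c(msgs, "communities must be nested subsets")
  if (length(msgs)) unique(msgs) else TRUE
})
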