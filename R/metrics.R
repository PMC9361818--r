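#' @include AllClasses.R
NULL

#' Define an initial (inoculum) community
#'
#' Mean strain frequencies of a defined inoculum across its sequencing
#' replicates.  Member frequencies must be strictly positive and sum to 1
#' (within 1e-6; renormalised internally).
#'
#' @param communityId community label (e.g. "C68").
#' @param qInitial named numeric vector of per-strain mean frequencies.
#' @param nReplicates number of sequencing replicates averaged (default 4).
#' @return list of class `"initialCommunity"`.
#' @export
initialCommunity <- function(communityId, qInitial, nReplicates = 4L) {
  if (is.null(names(qInitial))) stop("qInitial must be named by strain")
  if (any(qInitial <= 0))
    stop("every member strain must have qInitial > 0")
  if (abs(sum(qInitial) - 1) > 1e-6)
    stop("qInitial must sum to 1 within 1e-6")
  structure(list(communityId = as.character(communityId),
                 qInitial = qInitial / sum(qInitial),
                 nReplicates = as.integer(nReplicates)),
            class = "initialCommunity")
}

#' @export
print.initialCommunity <- function(x, ...) {
  cat("Initial community", x$communityId, ":", length(x$qInitial),
      "strains,", x$nReplicates, "sequencing replicates\n")
  invisible(x)
}

#' Strain relative fitness as log2 fold change in frequency
#'
#' `fitness_x = log2((q_selected_x + zeroPseudo) / q_initial_x)` for every
#' member strain of the community.  Strains absent from the community are
#' excluded (not zero-filled); a warning reports sample strains above the
#' contamination threshold that are not declared community members.
#'
#' `zeroPseudo = "auto"` (the default) uses 0 when every member strain was
#' detected, otherwise half the smallest nonzero selected frequency in the
#' sample, so fitness stays finite and exactly equals 0 when selected and
#' initial frequencies coincide.  `zeroPseudo = 0` yields `-Inf` for
#' undetected strains (sensitivity checks).
#'
#' @param qSelected named frequency vector for the selected (nodule) pool.
#' @param community an [initialCommunity()].
#' @param zeroPseudo `"auto"`, or a non-negative number added to every
#'   selected frequency.
#' @param contaminationThreshold frequency above which a non-member strain
#'   triggers the warning (default 0.001).
#' @return Named fitness vector over community strains, with attribute
#'   `"zeroPseudo"` recording the pseudo-frequency used.
#' @export
strainFitness <- function(qSelected, community, zeroPseudo = "auto",
                          contaminationThreshold = 0.001) {
  if (any(qSelected < 0)) stop("negative frequencies")
  members <- names(community$qInitial)
  extra <- setdiff(names(qSelected), members)
  nContam <- sum(qSelected[extra] > contaminationThreshold)
  if (nContam)
    warning(nContam, " non-member strain(s) above the contamination ",
            "threshold ", contaminationThreshold, call. = FALSE)
  q <- qSelected[members]
  q[is.na(q)] <- 0
  names(q) <- members
  if (identical(zeroPseudo, "auto"))
    zeroPseudo <- if (all(q > 0)) 0 else min(q[q > 0]) / 2
  fit <- log2((q + zeroPseudo) / community$qInitial)
  attr(fit, "zeroPseudo") <- zeroPseudo
  fit
}

#' Effective strain number: the exponent of Shannon diversity
#'
#' The Hill number of order 1, `exp(-sum p_x log p_x)` over nonzero
#' frequencies (`0 log 0 = 0`): the number of equally frequent strains that
#' would give the same entropy.  Input is renormalised to sum to 1.
#'
#' @param p non-negative frequency vector summing to 1 within 1e-6.
#' @return Effective strain number in `[1, number of nonzero entries]`.
#' @export
shannonExponent <- function(p) {
  if (any(p < 0)) stop("frequencies must be non-negative")
  s <- sum(p)
  if (s == 0) stop("all-zero frequency vector")
  if (abs(s - 1) > 1e-6)
    stop("frequencies must sum to 1 within 1e-6")
  p <- p[p > 0] / s
  exp(-sum(p * log(p)))
}

#' Single-strain plant-weight table for one host
#'
#' Dry plant weights from single-strain inoculations, min-max scaled per
#' host so 0 is the least and 1 the most beneficial strain.  Strains without
#' a weight estimate are recorded as missing and excluded from scaling.
#'
#' @param hostId host genotype label.
#' @param weights named numeric vector of dry plant weights (g); `NA` =
#'   missing.
#' @return list of class `"strainWeights"` with `hostId`, `weights` (raw,
#'   non-missing), `scaledWeights` (in `[0, 1]`) and `missing` (strain
#'   names).
#' @export
strainWeights <- function(hostId, weights) {
  if (is.null(names(weights))) stop("weights must be named by strain")
  missing <- names(weights)[is.na(weights)]
  w <- weights[!is.na(weights)]
  if (!length(w)) stop("no non-missing weights")
  rng <- range(w)
  scaled <- if (rng[1] == rng[2]) stats::setNames(rep(1, length(w)), names(w))
            else (w - rng[1]) / (rng[2] - rng[1])
  structure(list(hostId = as.character(hostId), weights = w,
                 scaledWeights = scaled, missing = missing),
            class = "strainWeights")
}

#' Predicted host benefit of a nodule community
#'
#' Frequency-weighted mean of the host-specific scaled single-strain plant
#' weights: `sum_x q_x w'_x / sum_x q_x` over strains with a weight
#' estimate.  By construction 0 means full occupancy by the least beneficial
#' strain and 1 by the most beneficial; scores are host-specific and not
#' comparable across hosts.
#'
#' @param q named strain frequency vector (any positive scale; the score is
#'   self-normalising).
#' @param weights a [strainWeights()] object for the sample's host.
#' @return Benefit score in `[0, 1]`.
#' @export
hostBenefit <- function(q, weights) {
  if (any(q < 0)) stop("negative frequencies")
  keep <- intersect(names(q), names(weights$scaledWeights))
  qk <- q[keep]
  if (!length(qk) || sum(qk) == 0)
    stop("all sample mass is on strains without weight estimates; ",
         "benefit undefined")
  sum(qk * weights$scaledWeights[keep]) / sum(qk)
}

#' Build a fitness table from per-sample frequency estimates
#'
#' Applies [strainFitness()] to each sample and assembles the samples x
#' strains matrix of log2 fold-change fitness with metadata columns — the
#' response matrix for [rdaFit()].
#'
#' @param freqs data.frame with columns `sample_id`, `strain_id`,
#'   `frequency` (long format, e.g. from [estimateFrequencies()]).
#' @param community an [initialCommunity()].
#' @param metadata data.frame keyed by `sample_id` with factor columns.
#' @param zeroPseudo passed to [strainFitness()].
#' @return data.frame: metadata columns then one column per member strain;
#'   attribute `"strains"` lists the strain columns, `"zero_policy"` the
#'   per-sample pseudo-frequencies used.
#' @export
fitnessTable <- function(freqs, community, metadata = NULL,
                         zeroPseudo = "auto") {
  samples <- unique(freqs$sample_id)
  members <- names(community$qInitial)
  rows <- matrix(NA_real_, length(samples), length(members),
                 dimnames = list(samples, members))
  pseudo <- stats::setNames(numeric(length(samples)), samples)
  for (sid in samples) {
    sub <- freqs[freqs$sample_id == sid, ]
    q <- stats::setNames(sub$frequency, sub$strain_id)
    fit <- strainFitness(q, community, zeroPseudo = zeroPseudo)
    rows[sid, ] <- fit
    pseudo[sid] <- attr(fit, "zeroPseudo")
  }
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  if (!is.null(metadata))
    out <- merge(out, metadata, by = "sample_id", sort = FALSE)
  out <- cbind(out, as.data.frame(rows)[match(out$sample_id, samples), ,
                                        drop = FALSE])
  rownames(out) <- NULL
  attr(out, "strains") <- members
  attr(out, "zero_policy") <- pseudo
  out
}
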