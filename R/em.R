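#' @include AllClasses.R
NULL

#' Log-likelihood of one read under one strain
#'
#' Per-site independent error model: a call contributes `log(1 - e)` when the
#' observed allele equals the strain's allele and `log(e / 3)` otherwise
#' (errors uniform over the three other bases).  With `e = 0` a mismatch
#' yields `-Inf`.
#'
#' @param read a [PooledSample-class] holding the read (first read used), or
#'   a data.frame with columns `site` (1-based) and `allele` (0-based).
#' @param strainRow the strain's allele vector over all panel sites.
#' @param errorRate per-site error probability `e`, `0 <= e < 0.75`.
#' @return The log-probability of the read's calls given the strain.
#' @export
readStrainLoglik <- function(read, strainRow, errorRate) {
  if (errorRate < 0 || errorRate >= 0.75)
    stop("errorRate must be in [0, 0.75)")
  if (is(read, "PooledSample")) read <- read@calls[read@calls$read == 1L, ]
  if (any(read$site < 1L) || any(read$site > length(strainRow)))
    stop("call site index out of range")
  match <- strainRow[read$site] == read$allele
  sum(ifelse(match, log1p(-errorRate), log(errorRate / 3)))
}

# reads x strains matrix of per-read log-likelihoods.
# calls: data.frame(read, site, allele); alleles: strains x sites (no NA).
.readLoglikMatrix <- function(calls, alleles, errorRate) {
  S <- nrow(alleles)
  R <- max(calls$read)
  # per-call match indicator for every strain: strains x calls
  obs <- alleles[, calls$site, drop = FALSE]
  match <- obs == rep(calls$allele, each = S)
  logMatch <- log1p(-errorRate)
  logMis <- log(errorRate / 3)  # -Inf when errorRate == 0
  perCall <- matrix(logMis, nrow = S, ncol = nrow(calls))
  perCall[match] <- logMatch
  if (errorRate == 0) perCall[!match] <- -Inf
  # sum calls within each read: calls x strains -> reads x strains
  ll <- rowsum(t(perCall), group = calls$read, reorder = TRUE)
  dimnames(ll) <- list(NULL, rownames(alleles))
  if (nrow(ll) != R) stop("reads without calls encountered")
  ll
}

# EM core on a precomputed log-likelihood matrix.
# Returns list(f, loglik, trace, nIter, converged).
.emCore <- function(ll, tol = 1e-8, maxIter = 1000L, fInit = NULL) {
  R <- nrow(ll); S <- ncol(ll)
  rowMax <- apply(ll, 1L, max)
  P <- exp(ll - rowMax)               # row-scaled likelihoods, max = 1 per row
  f <- if (is.null(fInit)) rep(1 / S, S) else fInit / sum(fInit)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    denom <- as.vector(P %*% f)       # scaled mixture likelihood per read
    cur <- sum(log(denom)) + sum(rowMax)
    # E-step responsibilities r_is = P_is f_s / denom_i; M-step: column means
    w <- as.vector(crossprod(P, 1 / denom))
    f <- f * w / R
    f <- f / sum(f)                   # guard against FP drift; sums to 1 exactly
    trace <- c(trace, cur)
    if (is.finite(prev) && cur - prev < tol) { converged <- TRUE; break }
    prev <- cur
  }
  # log-likelihood at the final frequencies
  final <- sum(log(as.vector(P %*% f))) + sum(rowMax)
  list(f = f, loglik = final, trace = trace, nIter = it,
       converged = converged)
}

#' Estimate strain frequencies by EM over a finite mixture of haplotypes
#'
#' Maximises `sum_reads log sum_s f_s P(read | strain s)` over the frequency
#' simplex.  The E-step computes per-read strain responsibilities; the M-step
#' sets each `f_s` to the mean responsibility.  Iteration stops when the
#' log-likelihood improves by less than `tol` or after `maxIter` iterations.
#' Initialisation is uniform (deterministic) unless `nRestarts > 0`, in which
#' case seeded random Dirichlet(1) restarts are added and the best optimum
#' kept.
#'
#' Reads whose likelihood is zero under every strain (possible when
#' `errorRate = 0`) carry no usable signal and are excluded with a message.
#'
#' @param sample a [PooledSample-class].
#' @param panel a filtered [StrainPanel-class] (no missing calls).
#' @param errorRate per-site sequencing error rate (default 0.005, typical
#'   post-trimming Illumina).
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param maxIter maximum EM iterations (default 1000).
#' @param nRestarts number of additional random restarts (default 0).
#' @param seed RNG seed used only when `nRestarts > 0`.
#' @return A [FrequencyEstimate-class].
#' @export
emEstimate <- function(sample, panel, errorRate = 0.005, tol = 1e-8,
                       maxIter = 1000L, nRestarts = 0L, seed = NULL) {
  al <- alleleMatrix(panel)
  if (anyNA(al))
    stop("panel contains ambiguous calls; run filterUnambiguous() first")
  calls <- sample@calls
  if (!nrow(calls)) stop("sample has no usable reads")
  if (max(calls$site) > nSites(panel)) stop("call site index out of range")
  ll <- .readLoglikMatrix(calls, al, errorRate)
  usable <- is.finite(apply(ll, 1L, max))
  if (!all(usable)) {
    message("excluded ", sum(!usable),
            " read(s) with zero likelihood under all strains")
    ll <- ll[usable, , drop = FALSE]
  }
  if (!nrow(ll)) stop("no usable reads remain for sample ", sample@sampleId)
  fit <- .emCore(ll, tol = tol, maxIter = as.integer(maxIter))
  if (nRestarts > 0L) {
    if (!is.null(seed)) set.seed(seed)
    S <- ncol(ll)
    for (r in seq_len(nRestarts)) {
      g <- stats::rexp(S)
      alt <- .emCore(ll, tol = tol, maxIter = as.integer(maxIter),
                     fInit = g / sum(g))
      if (alt$loglik > fit$loglik) fit <- alt
    }
  }
  f <- stats::setNames(fit$f, strainIds(panel))
  new("FrequencyEstimate", sampleId = sample@sampleId, frequencies = f,
      loglik = fit$loglik, loglikTrace = fit$trace,
      nReadsUsed = nrow(ll), nIter = fit$nIter,
      converged = fit$converged, errorRate = errorRate)
}

#' Exhaustive simplex-grid likelihood maximisation (test oracle)
#'
#' Evaluates the mixture log-likelihood on every lattice point of the
#' frequency simplex at the given resolution and returns the maximising
#' point.  Intended solely as an independent check of [emEstimate()] on tiny
#' problems; refuses panels with more than 3 strains.  Ties are broken by the
#' lexicographically smallest frequency vector.
#'
#' @param sample a [PooledSample-class].
#' @param panel a filtered [StrainPanel-class] with at most 3 strains.
#' @param errorRate per-site error rate.
#' @param resolution lattice step; must divide 1.
#' @return list with `frequencies` (named vector) and `loglik`.
#' @export
gridOracle <- function(sample, panel, errorRate, resolution = 0.01) {
  S <- nStrains(panel)
  if (S > 3L) stop("gridOracle supports at most 3 strains")
  k <- round(1 / resolution)
  if (abs(k * resolution - 1) > 1e-9) stop("resolution must divide 1")
  al <- alleleMatrix(panel)
  if (anyNA(al)) stop("panel contains ambiguous calls")
  ll <- .readLoglikMatrix(sample@calls, al, errorRate)
  rowMax <- apply(ll, 1L, max)
  P <- exp(ll - rowMax)
  grid <- if (S == 1L) {
    matrix(1, 1, 1)
  } else if (S == 2L) {
    f1 <- seq(0L, k) / k
    cbind(f1, 1 - f1)
  } else {
    g <- expand.grid(i = 0:k, j = 0:k)
    g <- g[g$i + g$j <= k, ]
    g <- g[order(g$i, g$j), ]
    cbind(g$i / k, g$j / k, (k - g$i - g$j) / k)
  }
  # grid rows are in lexicographic order; which.max takes the first maximum
  objective <- colSums(log(P %*% t(grid)))
  best <- which.max(objective)
  list(frequencies = stats::setNames(grid[best, ], strainIds(panel)),
       loglik = objective[best] + sum(rowMax))
}

#' Bootstrap confidence intervals for strain frequencies
#'
#' Resamples reads with replacement, re-runs the EM on each replicate, and
#' returns percentile intervals per strain.  Replicates on which estimation
#' fails are logged and skipped.
#'
#' @param sample a [PooledSample-class].
#' @param panel a filtered [StrainPanel-class].
#' @param errorRate per-site error rate.
#' @param nBoot number of bootstrap replicates (>= 1).
#' @param seed RNG seed (reproducible intervals).
#' @param probs interval quantiles (default 2.5 and 97.5 percentiles).
#' @param tol,maxIter passed to the EM.
#' @return data.frame: strain, lower, upper, plus attribute `"estimates"`
#'   (replicates x strains matrix).
#' @export
bootstrapCI <- function(sample, panel, errorRate = 0.005, nBoot = 200L,
                        seed = 1L, probs = c(0.025, 0.975), tol = 1e-8,
                        maxIter = 1000L) {
  if (nBoot < 1L) stop("nBoot must be >= 1")
  al <- alleleMatrix(panel)
  if (anyNA(al)) stop("panel contains ambiguous calls")
  ll <- .readLoglikMatrix(sample@calls, al, errorRate)
  usable <- is.finite(apply(ll, 1L, max))
  ll <- ll[usable, , drop = FALSE]
  if (!nrow(ll)) stop("no usable reads for sample ", sample@sampleId)
  R <- nrow(ll)
  set.seed(seed)
  ests <- matrix(NA_real_, nBoot, nStrains(panel),
                 dimnames = list(NULL, strainIds(panel)))
  nFail <- 0L
  for (b in seq_len(nBoot)) {
    idx <- sample.int(R, R, replace = TRUE)
    fit <- tryCatch(.emCore(ll[idx, , drop = FALSE], tol = tol,
                            maxIter = as.integer(maxIter)),
                    error = function(e) NULL)
    if (is.null(fit)) nFail <- nFail + 1L else ests[b, ] <- fit$f
  }
  if (nFail) message("skipped ", nFail, " failed bootstrap replicate(s)")
  ok <- stats::complete.cases(ests)
  qs <- apply(ests[ok, , drop = FALSE], 2L, stats::quantile, probs = probs,
              names = FALSE)
  out <- data.frame(strain = strainIds(panel), lower = qs[1L, ],
                    upper = qs[2L, ], row.names = NULL)
  attr(out, "estimates") <- ests
  out
}
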