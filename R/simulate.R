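#' @include AllClasses.R
NULL

#' Construct a simulation configuration
#'
#' Builds a [SimulationConfig-class] with defaults matching the experimental
#' design the package analyses: 68 strains with >= 1 segregating difference
#' expected at half of 1000 SNP sites, nested communities (the full
#' community, an 8-strain and a 3-strain subset, and all pairs of the
#' 3-strain members), near-equal inoculum frequencies, host-specific
#' selection and nodule numbers (A17 more selective, 300-500 nodules; R108
#' less selective, 100-200 nodules), a high/low density contrast modulating
#' selection, and pooled sequencing at ~65x depth with 0.5% per-site error.
#'
#' @param nStrains,nSites panel dimensions (defaults 68, 1000).
#' @param pairwiseDiffProb per-site probability two strains differ (0.5).
#' @param communities named list of strain index vectors; the default builds
#'   nested subsets `C<n> > C8 > C3` plus pairs `P12`, `P13`, `P23` of the
#'   C3 members.
#' @param inoculumJitterSd lognormal jitter sd around equal frequencies
#'   (0.2).
#' @param nInitialSeqReplicates sequencing replicates of each inoculum (4).
#' @param selectionSd named per-host sd of strain selection coefficients
#'   (A17 = 1, R108 = 0.5).
#' @param densityMultiplier named per-host multiplier on selection
#'   coefficients at high density (A17 = 1.3, R108 = 0.8).
#' @param nitrogenMultiplier named per-host multiplier under N addition
#'   (A17 = 1.05, R108 = 1).
#' @param noduleRange named list host -> c(min, max) nodules per pool.
#' @param nReplicatePots named replicate pots per community; default 6 for
#'   the full community, 5 for C8/C3, 4 per pairwise community.
#' @param readsPerSample reads per pooled sample (21667, ~65x at 1000 sites
#'   with 3-site reads).
#' @param sitesPerRead contiguous panel sites covered by a read (3).
#' @param errorRate per-site sequencing error rate (0.005).
#' @param seed RNG seed (mandatory).
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(nStrains = 68L, nSites = 1000L,
                             pairwiseDiffProb = 0.5,
                             communities = NULL,
                             inoculumJitterSd = 0.2,
                             nInitialSeqReplicates = 4L,
                             selectionSd = c(A17 = 1, R108 = 0.5),
                             densityMultiplier = c(A17 = 1.3, R108 = 0.8),
                             nitrogenMultiplier = c(A17 = 1.05, R108 = 1),
                             noduleRange = list(A17 = c(300L, 500L),
                                                R108 = c(100L, 200L)),
                             nReplicatePots = NULL,
                             readsPerSample = 21667L,
                             sitesPerRead = 3L,
                             errorRate = 0.005,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  nStrains <- as.integer(nStrains)
  if (is.null(communities)) {
    sizes <- unique(pmin(c(nStrains, 8L, 3L), nStrains))
    communities <- stats::setNames(lapply(sizes, seq_len),
                                   paste0("C", sizes))
    if (nStrains >= 3L) {
      prs <- utils::combn(1:3, 2L, simplify = FALSE)
      names(prs) <- vapply(prs, function(p) paste0("P", p[1L], p[2L]), "")
      communities <- c(communities, prs)
    }
  }
  if (is.null(nReplicatePots)) {
    sz <- lengths(communities)
    nReplicatePots <- ifelse(sz == max(sz), 6, ifelse(sz == 2L, 4, 5))
    names(nReplicatePots) <- names(communities)
  }
  new("SimulationConfig", nStrains = nStrains, nSites = as.integer(nSites),
      pairwiseDiffProb = pairwiseDiffProb, communities = communities,
      inoculumJitterSd = inoculumJitterSd,
      nInitialSeqReplicates = as.integer(nInitialSeqReplicates),
      selectionSd = selectionSd, densityMultiplier = densityMultiplier,
      nitrogenMultiplier = nitrogenMultiplier, noduleRange = noduleRange,
      nReplicatePots = nReplicatePots,
      readsPerSample = as.integer(readsPerSample),
      sitesPerRead = as.integer(sitesPerRead), errorRate = errorRate,
      seed = as.integer(seed))
}

.strainNames <- function(n) sprintf("strain%02d", seq_len(n))

#' Simulate a strain haplotype panel
#'
#' Random biallelic haplotypes with expected pairwise Hamming distance
#' `nSites * pairwiseDiffProb`.  For two strains the difference is drawn
#' per-site with exactly that probability (so `pairwiseDiffProb = 1` forces
#' every site to differ); for more strains, per-strain alleles are iid
#' Bernoulli with the marginal chosen so two random strains differ with the
#' requested probability (attainable up to 0.5).
#'
#' @param config a [SimulationConfig-class].
#' @param seed RNG seed; defaults to the config seed.  Pass `NA` to draw
#'   from the current RNG state.
#' @return A [StrainPanel-class]; deterministic under a fixed seed.
#' @export
simulatePanel <- function(config, seed = config@seed) {
  if (!is.na(seed)) set.seed(seed)
  n <- config@nStrains
  L <- config@nSites
  p <- config@pairwiseDiffProb
  if (n == 2L) {
    s2 <- stats::rbinom(L, 1L, p)
    al <- rbind(integer(L), as.integer(s2))
  } else {
    if (p > 0.5)
      stop("pairwiseDiffProb > 0.5 is only attainable with 2 strains")
    theta <- (1 - sqrt(1 - 2 * p)) / 2
    al <- matrix(stats::rbinom(n * L, 1L, theta), nrow = n)
  }
  sites <- data.frame(chrom = "chr1", pos = seq_len(L) * 10L,
                      ref = "A", alt = "C", stringsAsFactors = FALSE)
  strainPanel(.strainNames(n), sites, al, provenance = "simulated panel")
}

#' Simulate an inoculum community
#'
#' Equal member frequencies perturbed by lognormal jitter (equal culture
#' volumes mixed with pipetting/growth noise), renormalised, plus noisy
#' sequencing-replicate estimates (multinomial read sampling at the
#' configured depth) from which the initial-community means are taken.
#'
#' @param config a [SimulationConfig-class].
#' @param communityId name of a community in `config`.
#' @param seed optional RNG seed (default: current RNG state).
#' @return list: `q` (true member frequencies, named, summing to 1),
#'   `replicates` (members x nInitialSeqReplicates matrix of estimated
#'   frequencies), `community` (an [initialCommunity()] built from the
#'   replicate means).
#' @export
simulateInoculum <- function(config, communityId, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!communityId %in% names(config@communities))
    stop("unknown community: ", communityId)
  members <- config@communities[[communityId]]
  ids <- .strainNames(config@nStrains)[members]
  k <- length(members)
  jitter <- if (config@inoculumJitterSd > 0)
    exp(stats::rnorm(k, 0, config@inoculumJitterSd)) else rep(1, k)
  q <- jitter / sum(jitter)
  names(q) <- ids
  reps <- vapply(seq_len(config@nInitialSeqReplicates), function(i) {
    counts <- stats::rmultinom(1L, config@readsPerSample, q)[, 1L]
    counts / sum(counts)
  }, numeric(k))
  reps <- matrix(reps, nrow = k, dimnames = list(ids, NULL))
  qhat <- rowMeans(reps)
  list(q = q, replicates = reps,
       community = initialCommunity(communityId, qhat / sum(qhat),
                                    config@nInitialSeqReplicates))
}

#' Simulate host selection into a finite nodule pool
#'
#' Nodule occupancy is multinomial with probabilities proportional to
#' `inoculum_x * exp(s_x)` (selection as a single exponential tilt at nodule
#' formation), one strain per nodule; the pool frequency is the occupancy
#' count divided by the number of nodules.  Finite `nNodules` is the source
#' of drift: fewer nodules (the less selective host) means noisier pools.
#'
#' @param inoculum named member frequency vector (sums to 1).
#' @param selection named (or aligned) per-strain selection coefficients.
#' @param nNodules number of nodules sampled (>= 1).
#' @param seed optional RNG seed.
#' @return Named pool frequency vector summing to 1.
#' @export
simulateNodulePool <- function(inoculum, selection, nNodules, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nNodules < 1L) stop("nNodules must be >= 1")
  if (!is.null(names(selection)) && !is.null(names(inoculum)))
    selection <- selection[names(inoculum)]
  pr <- inoculum * exp(selection)
  pr <- pr / sum(pr)
  counts <- stats::rmultinom(1L, nNodules, pr)[, 1L]
  out <- counts / nNodules
  names(out) <- names(inoculum)
  out
}

#' Simulate pooled sequencing reads from a nodule pool
#'
#' Each read draws a source strain from the pool frequencies and a random
#' contiguous block of `sitesPerRead` panel sites (a read-length surrogate);
#' each call is flipped to a uniformly chosen wrong allele of its site with
#' probability `errorRate`.
#'
#' @param poolFreqs named frequency vector over a subset of panel strains.
#' @param panel a [StrainPanel-class].
#' @param readsPerSample number of reads.
#' @param sitesPerRead sites per read (<= panel sites).
#' @param errorRate per-site error probability.
#' @param sampleId id for the resulting sample.
#' @param metadata metadata list for the sample.
#' @param seed optional RNG seed.
#' @return A [PooledSample-class].
#' @export
simulateReads <- function(poolFreqs, panel, readsPerSample, sitesPerRead,
                          errorRate, sampleId = "sim", metadata = list(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nSites(panel)
  if (sitesPerRead > L) stop("sitesPerRead exceeds panel sites")
  al <- alleleMatrix(panel)
  rows <- match(names(poolFreqs), strainIds(panel))
  if (anyNA(rows)) stop("pool strains missing from panel")
  R <- as.integer(readsPerSample)
  src <- rows[sample.int(length(rows), R, replace = TRUE, prob = poolFreqs)]
  start <- sample.int(L - sitesPerRead + 1L, R, replace = TRUE)
  siteMat <- outer(start, 0:(sitesPerRead - 1L), `+`)
  sitesVec <- as.vector(siteMat)
  readVec <- rep(seq_len(R), times = sitesPerRead)
  obs <- al[cbind(rep(src, times = sitesPerRead), sitesVec)]
  if (errorRate > 0) {
    nAlt <- lengths(strsplit(siteInfo(panel)$alt, ",", fixed = TRUE))
    err <- stats::runif(length(obs)) < errorRate
    if (any(err)) {
      k <- nAlt[sitesVec[err]]             # number of wrong choices per call
      u <- floor(stats::runif(sum(err)) * k)
      obs[err] <- u + (u >= obs[err])      # uniform over alleles != truth
    }
  }
  pooledSample(sampleId,
               data.frame(read = readVec, site = sitesVec, allele = obs),
               readIds = paste0(sampleId, "_r", seq_len(R)),
               metadata = metadata)
}

#' Simulate a full select-and-resequence experiment
#'
#' Generates the complete study: a haplotype panel; true and
#' replicate-sequenced inoculum frequencies for every community; a full
#' Host x Density x Nitrogen factorial with replicate pots for the full
#' community (2 x 2 x 2 cells x 6 reps = 48 samples by default) and
#' replicate pots at the reference condition (high density, no added N) for
#' the complexity communities; host selection into finite nodule pools; and,
#' optionally, pooled reads per sample.  Host-specific single-strain plant
#' weights (with host-specific missing fractions) are drawn for
#' benefit-score testing.  Deterministic under the config seed.
#'
#' @param config a [SimulationConfig-class].
#' @param sequencing simulate reads per sample (`TRUE`) or stop at the true
#'   pool frequencies (`FALSE`; much faster, for design-level checks).
#' @param selection optional planted selection coefficients: a matrix with
#'   strain rownames and host colnames whose entries replace the
#'   corresponding drawn coefficients (planted-scenario studies).
#' @return list of class `"nodpoolExperiment"`: `panel`, `samples` (named
#'   list of [PooledSample-class], `NULL` when `sequencing = FALSE`),
#'   `metadata` (data.frame), `truth` (list: `inocula`, `pools`,
#'   `selection`), `initialCommunities`, `weights` (per host
#'   [strainWeights()]), `config`.
#' @export
simulateExperiment <- function(config, sequencing = TRUE, selection = NULL) {
  panel <- simulatePanel(config)           # sets the seed; later draws follow
  ids <- strainIds(panel)
  hosts <- names(config@selectionSd)
  planted <- selection
  selection <- vapply(hosts, function(h)
    stats::rnorm(config@nStrains, 0, config@selectionSd[[h]]),
    numeric(config@nStrains))
  rownames(selection) <- ids
  if (!is.null(planted)) {
    rows <- intersect(rownames(planted), ids)
    cols <- intersect(colnames(planted), hosts)
    selection[rows, cols] <- planted[rows, cols]
  }

  weights <- lapply(hosts, function(h) {
    w <- stats::rlnorm(config@nStrains, meanlog = log(0.8), sdlog = 0.4)
    names(w) <- ids
    missFrac <- c(A17 = 9 / 68, R108 = 29 / 68)[h]
    if (is.na(missFrac)) missFrac <- 0.15
    nMiss <- min(config@nStrains - 1L, round(missFrac * config@nStrains))
    if (nMiss > 0) w[sample.int(config@nStrains, nMiss)] <- NA
    strainWeights(h, w)
  })
  names(weights) <- hosts

  inocula <- lapply(names(config@communities), function(cc)
    simulateInoculum(config, cc))
  names(inocula) <- names(config@communities)

  fullComm <- names(config@communities)[
    which.max(lengths(config@communities))]
  md <- list(); pools <- list(); samples <- list()
  for (cc in names(config@communities)) {
    isFull <- cc == fullComm
    cells <- if (isFull)
      expand.grid(host = hosts, density = c("low", "high"),
                  nitrogen = c("N-", "N+"), stringsAsFactors = FALSE)
    else
      expand.grid(host = hosts, density = "high", nitrogen = "N-",
                  stringsAsFactors = FALSE)
    reps <- config@nReplicatePots[[cc]]
    members <- config@communities[[cc]]
    for (i in seq_len(nrow(cells))) for (r in seq_len(reps)) {
      h <- cells$host[i]; dens <- cells$density[i]; nit <- cells$nitrogen[i]
      sid <- sprintf("%s_%s_%s_%s_rep%d", cc, h, dens, nit, r)
      rng <- config@noduleRange[[h]]
      nNod <- if (rng[1L] == rng[2L]) rng[1L] else
        sample(seq.int(rng[1L], rng[2L]), 1L)
      s <- selection[members, h] *
        (if (dens == "high") config@densityMultiplier[[h]] else 1) *
        (if (nit == "N+") config@nitrogenMultiplier[[h]] else 1)
      pool <- simulateNodulePool(inocula[[cc]]$q, s, nNod)
      pools[[sid]] <- pool
      md[[sid]] <- data.frame(sample_id = sid, host = h, density = dens,
                              nitrogen = nit, community = cc, replicate = r,
                              nNodules = nNod, stringsAsFactors = FALSE)
      if (sequencing)
        samples[[sid]] <- simulateReads(
          pool, panel, config@readsPerSample, config@sitesPerRead,
          config@errorRate, sampleId = sid,
          metadata = list(host = h, density = dens, nitrogen = nit,
                          community = cc, replicate = r))
    }
  }
  structure(list(
    panel = panel,
    samples = if (sequencing) samples else NULL,
    metadata = do.call(rbind, c(md, list(make.row.names = FALSE))),
    truth = list(inocula = lapply(inocula, `[[`, "q"), pools = pools,
                 selection = selection),
    initialCommunities = lapply(inocula, `[[`, "community"),
    weights = weights,
    config = config), class = "nodpoolExperiment")
}

#' @export
print.nodpoolExperiment <- function(x, ...) {
  cat("Simulated select-and-resequence experiment:",
      nrow(x$metadata), "samples,", x$config@nStrains, "strains,",
      length(x$truth$inocula), "communities",
      if (is.null(x$samples)) "(no reads simulated)" else "", "\n")
  invisible(x)
}

#' Write a simulated experiment's pipeline input files
#'
#' Writes `panel.tsv`, `obs.tsv` (when reads were simulated), `init.csv`
#' (community_id, strain_id, q_initial), `comm.csv` (community_id,
#' strain_id), `weights.csv` (host_id, strain_id, dry_weight_g),
#' `truth.csv` (sample_id, strain_id, true_freq) and `metadata.csv`.
#'
#' @param experiment result of [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeExperiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePanel(experiment$panel, file.path(dir, "panel.tsv"))
  if (!is.null(experiment$samples))
    writeObservations(experiment$samples, file.path(dir, "obs.tsv"))
  init <- do.call(rbind, lapply(experiment$initialCommunities, function(ic)
    data.frame(community_id = ic$communityId,
               strain_id = names(ic$qInitial),
               q_initial = unname(ic$qInitial))))
  utils::write.csv(init, file.path(dir, "init.csv"), row.names = FALSE)
  comm <- do.call(rbind, lapply(names(experiment$truth$inocula), function(cc)
    data.frame(community_id = cc,
               strain_id = names(experiment$truth$inocula[[cc]]))))
  utils::write.csv(comm, file.path(dir, "comm.csv"), row.names = FALSE)
  wts <- do.call(rbind, lapply(experiment$weights, function(w)
    data.frame(host_id = w$hostId, strain_id = names(w$weights),
               dry_weight_g = unname(w$weights))))
  utils::write.csv(wts, file.path(dir, "weights.csv"), row.names = FALSE)
  truth <- do.call(rbind, lapply(names(experiment$truth$pools), function(sid)
    data.frame(sample_id = sid,
               strain_id = names(experiment$truth$pools[[sid]]),
               true_freq = unname(experiment$truth$pools[[sid]]))))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(experiment$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read/write a simulation config as a flat key-value file
#'
#' The file holds `key = value` lines for the scalar and per-host fields
#' (`selectionSd.A17 = 1`, `noduleMin.R108 = 100`, ...).  Communities and
#' replicate counts use the constructor defaults derived from `nStrains`.
#'
#' @param path config file path.
#' @return `readSimConfig`: a [SimulationConfig-class];
#'   `writeSimConfig`: `path`, invisibly.
#' @export
readSimConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  names(vals) <- keys
  g <- function(k, d) if (k %in% keys) vals[[k]] else d
  perHost <- function(stem, d) {
    hs <- sub(paste0("^", stem, "\\."), "", keys[startsWith(keys, paste0(stem, "."))])
    if (!length(hs)) return(d)
    stats::setNames(vals[paste0(stem, ".", hs)], hs)
  }
  hostsN <- names(perHost("noduleMin", c(A17 = 300, R108 = 100)))
  simulationConfig(
    nStrains = g("nStrains", 68), nSites = g("nSites", 1000),
    pairwiseDiffProb = g("pairwiseDiffProb", 0.5),
    inoculumJitterSd = g("inoculumJitterSd", 0.2),
    nInitialSeqReplicates = g("nInitialSeqReplicates", 4),
    selectionSd = perHost("selectionSd", c(A17 = 1, R108 = 0.5)),
    densityMultiplier = perHost("densityMultiplier",
                                c(A17 = 1.3, R108 = 0.8)),
    nitrogenMultiplier = perHost("nitrogenMultiplier",
                                 c(A17 = 1.05, R108 = 1)),
    noduleRange = stats::setNames(lapply(hostsN, function(h)
      c(as.integer(g(paste0("noduleMin.", h), 100)),
        as.integer(g(paste0("noduleMax.", h), 500)))), hostsN),
    readsPerSample = g("readsPerSample", 21667),
    sitesPerRead = g("sitesPerRead", 3),
    errorRate = g("errorRate", 0.005),
    seed = g("seed", NA))
}

#' @rdname readSimConfig
#' @param config a [SimulationConfig-class] to serialise.
#' @export
writeSimConfig <- function(config, path) {
  ln <- c(
    paste("nStrains =", config@nStrains),
    paste("nSites =", config@nSites),
    paste("pairwiseDiffProb =", config@pairwiseDiffProb),
    paste("inoculumJitterSd =", config@inoculumJitterSd),
    paste("nInitialSeqReplicates =", config@nInitialSeqReplicates),
    paste0("selectionSd.", names(config@selectionSd), " = ",
           config@selectionSd),
    paste0("densityMultiplier.", names(config@densityMultiplier), " = ",
           config@densityMultiplier),
    paste0("nitrogenMultiplier.", names(config@nitrogenMultiplier), " = ",
           config@nitrogenMultiplier),
    unlist(lapply(names(config@noduleRange), function(h)
      c(paste0("noduleMin.", h, " = ", config@noduleRange[[h]][1L]),
        paste0("noduleMax.", h, " = ", config@noduleRange[[h]][2L])))),
    paste("readsPerSample =", config@readsPerSample),
    paste("sitesPerRead =", config@sitesPerRead),
    paste("errorRate =", config@errorRate),
    paste("seed =", config@seed))
  writeLines(ln, path)
  invisible(path)
}
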