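#' @include AllClasses.R
NULL

#' Estimate frequencies for a set of pooled samples
#'
#' Runs [emEstimate()] on each sample and returns tidy results.
#'
#' @param samples list of [PooledSample-class] objects.
#' @param panel a filtered [StrainPanel-class].
#' @param errorRate,tol,maxIter passed to [emEstimate()].
#' @return list: `freqs` (data.frame `sample_id`, `strain_id`, `frequency`),
#'   `diagnostics` (data.frame `sample_id`, `loglik`, `n_reads_used`,
#'   `n_iter`, `converged`, `error_rate`), `estimates` (the
#'   [FrequencyEstimate-class] objects).
#' @export
estimateFrequencies <- function(samples, panel, errorRate = 0.005,
                                tol = 1e-8, maxIter = 1000L) {
  ests <- lapply(samples, emEstimate, panel = panel, errorRate = errorRate,
                 tol = tol, maxIter = maxIter)
  freqs <- do.call(rbind, lapply(ests, function(e)
    data.frame(sample_id = e@sampleId, strain_id = names(e@frequencies),
               frequency = unname(e@frequencies))))
  rownames(freqs) <- NULL
  diag <- do.call(rbind, lapply(ests, function(e)
    data.frame(sample_id = e@sampleId, loglik = e@loglik,
               n_reads_used = e@nReadsUsed, n_iter = e@nIter,
               converged = e@converged, error_rate = e@errorRate)))
  rownames(diag) <- NULL
  list(freqs = freqs, diagnostics = diag, estimates = ests)
}

#' Read initial communities from init.csv
#'
#' @param path CSV with columns `community_id`, `strain_id`, `q_initial`.
#' @param nReplicates replicate count recorded on each community.
#' @return Named list of [initialCommunity()] objects.
#' @export
loadInitialCommunities <- function(path, nReplicates = 4L) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$community_id), function(sub)
    initialCommunity(sub$community_id[1L],
                     stats::setNames(sub$q_initial, sub$strain_id),
                     nReplicates))
  out[unique(tab$community_id)]
}

#' Read single-strain plant weights from weights.csv
#'
#' @param path CSV with columns `host_id`, `strain_id`, `dry_weight_g`.
#' @param allStrains optional character vector; strains absent from a host's
#'   rows are recorded as missing.
#' @return Named list of [strainWeights()] per host.
#' @export
loadWeights <- function(path, allStrains = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$host_id), function(sub) {
    w <- stats::setNames(sub$dry_weight_g, sub$strain_id)
    if (!is.null(allStrains)) {
      miss <- setdiff(allStrains, names(w))
      w <- c(w, stats::setNames(rep(NA_real_, length(miss)), miss))
    }
    strainWeights(sub$host_id[1L], w)
  })
  out[unique(tab$host_id)]
}

.stamp <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

#' Run the full pipeline: simulate, estimate, metrics, rda, ranks
#'
#' Orchestrates the five stages on a simulated experiment and writes every
#' intermediate and final file plus a run manifest (`manifest.json`) holding
#' the package version, the config, per-stage wall times and md5 checksums
#' of all outputs.  Deterministic stages reproduce identical checksums under
#' identical config and seed.  A stage failure aborts with the stage name;
#' earlier outputs are preserved.
#'
#' @param config a [SimulationConfig-class] or path to a key-value config
#'   file ([readSimConfig()]).
#' @param outDir output directory.
#' @param nPerm permutations for the RDA stage (default 999).
#' @param verbose print stage progress.
#' @return The manifest, invisibly (list; also written as JSON).
#' @export
runAll <- function(config, outDir, nPerm = 999L, verbose = TRUE) {
  if (is.character(config)) config <- readSimConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  note <- function(...) {
    msg <- paste0("[", .stamp(), "] ", ...)
    cat(msg, "\n", file = logFile, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  times <- c()
  stage <- function(name, expr) {
    note("stage ", name, " started")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    note("stage ", name, " finished in ", times[[name]], "s")
    res
  }

  exp <- stage("simulate", {
    e <- simulateExperiment(config)
    writeExperiment(e, outDir)
    e
  })

  est <- stage("estimate", {
    panel <- loadPanel(file.path(outDir, "panel.tsv"))
    samples <- readObservations(file.path(outDir, "obs.tsv"),
                                metadata = exp$metadata)
    r <- estimateFrequencies(samples, panel, errorRate = config@errorRate)
    utils::write.csv(r$freqs, file.path(outDir, "freqs.csv"),
                     row.names = FALSE)
    jsonlite::write_json(r$diagnostics,
                         file.path(outDir, "freqs_diagnostics.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    r
  })

  metricsRes <- stage("metrics", {
    inits <- loadInitialCommunities(file.path(outDir, "init.csv"),
                                    config@nInitialSeqReplicates)
    weights <- loadWeights(file.path(outDir, "weights.csv"),
                           allStrains = strainIds(exp$panel))
    md <- exp$metadata
    fullComm <- names(which.max(lengths(exp$truth$inocula)))
    fullIds <- md$sample_id[md$community == fullComm]
    fitTab <- fitnessTable(est$freqs[est$freqs$sample_id %in% fullIds, ],
                           inits[[fullComm]],
                           metadata = md[md$community == fullComm, ])
    utils::write.csv(fitTab, file.path(outDir, "fitness.csv"),
                     row.names = FALSE)
    perSample <- do.call(rbind, lapply(unique(est$freqs$sample_id),
      function(sid) {
        sub <- est$freqs[est$freqs$sample_id == sid, ]
        q <- stats::setNames(sub$frequency, sub$strain_id)
        h <- md$host[md$sample_id == sid]
        data.frame(sample_id = sid,
                   shannon_exponent = shannonExponent(q),
                   host_benefit = hostBenefit(q, weights[[h]]))
      }))
    utils::write.csv(perSample, file.path(outDir, "metrics.csv"),
                     row.names = FALSE)
    list(fitness = fitTab, perSample = perSample)
  })

  rdaRes <- stage("rda", {
    fitTab <- metricsRes$fitness
    strains <- attr(fitTab, "strains")
    Y <- as.matrix(fitTab[, strains, drop = FALSE])
    d <- designMatrix(fitTab, ~ host * density * nitrogen)
    res <- suppressWarnings(
      permutationTest(Y, d, nPerm = nPerm, seed = config@seed))
    writeRdaTable(res, file.path(outDir, "table1.csv"))
    sub <- suppressWarnings(
      perHostSubmodels(Y, fitTab, nPerm = nPerm, seed = config@seed))
    for (h in names(sub))
      writeRdaTable(sub[[h]], file.path(outDir,
                                        paste0("table1_", h, ".csv")))
    utils::write.csv(
      data.frame(sample_id = fitTab$sample_id, res$siteScores),
      file.path(outDir, "rda_scores.csv"), row.names = FALSE)
    res
  })

  ranksRes <- stage("ranks", {
    md <- exp$metadata
    freqTables <- list()
    for (h in unique(md$host)) {
      freqTables[[h]] <- list()
      for (cc in unique(md$community)) {
        # complexity comparisons use the reference condition shared by all
        # communities (high density, no added N)
        ids <- md$sample_id[md$host == h & md$community == cc &
                              md$density == "high" & md$nitrogen == "N-"]
        if (!length(ids)) next
        members <- names(exp$truth$inocula[[cc]])
        sub <- est$freqs[est$freqs$sample_id %in% ids &
                           est$freqs$strain_id %in% members, ]
        m <- matrix(NA_real_, length(ids), length(members),
                    dimnames = list(ids, members))
        m[cbind(sub$sample_id, sub$strain_id)] <- sub$frequency
        freqTables[[h]][[cc]] <- m
      }
    }
    rep <- rankReport(freqTables)
    writeRankReport(rep, file.path(outDir, "table2.csv"),
                    file.path(outDir, "rankings.csv"))
    rep
  })

  outputs <- list.files(outDir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% c("manifest.json", "run.log")]
  manifest <- list(
    tool = "nodpool",
    version = as.character(utils::packageVersion("nodpool")),
    timestamp = .stamp(),
    seed = config@seed,
    nPerm = nPerm,
    configChecksum = {
      tmp <- tempfile(); writeSimConfig(config, tmp)
      unname(tools::md5sum(tmp))
    },
    stageSeconds = as.list(times),
    fileChecksums = as.list(tools::md5sum(outputs))
  )
  names(manifest$fileChecksums) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
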