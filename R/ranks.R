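#' @include AllClasses.R
NULL

# replicate frequency tables are data.frames / matrices with one column per
# strain and one row per replicate; values are (relative) frequencies.

#' Winner of a pairwise competition
#'
#' The strain with the higher mean frequency across replicates of a
#' two-strain community.  An exact tie of the means is flagged and leaves
#' the winner undefined.
#'
#' @param freqs replicates x 2 strains table of frequencies.
#' @return list: `winner` (strain name or `NA` on a tie), `loser`,
#'   `meanFreqs` (named, normalised to the pair), `tie` flag.
#' @export
pairwiseWinner <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != 2L) stop("pairwise community must have exactly 2 strains")
  if (nrow(freqs) < 1L) stop("need >= 1 replicate")
  m <- colMeans(freqs)
  m <- m / sum(m)
  if (m[1L] == m[2L])
    return(list(winner = NA_character_, loser = NA_character_,
                meanFreqs = m, tie = TRUE))
  w <- which.max(m)
  list(winner = colnames(freqs)[w], loser = colnames(freqs)[-w],
       meanFreqs = m, tie = FALSE)
}

#' Proportion of replicates in which a pairwise winner stays ahead
#'
#' For each replicate of a more complex community, compares the focal pair's
#' relative frequencies (`freq_w / (freq_w + freq_l)`, equivalent to the raw
#' comparison but robust to the other strains' mass) and reports the
#' proportion of replicates with the winner ahead.  An exact within-replicate
#' tie contributes 0.5.
#'
#' @param winner,loser strain names of the focal pair.
#' @param complexFreqs replicates x strains frequency table of the larger
#'   community; must contain both strains.
#' @return Proportion in `[0, 1]`.
#' @export
consistencyProportion <- function(winner, loser, complexFreqs) {
  complexFreqs <- as.matrix(complexFreqs)
  if (!all(c(winner, loser) %in% colnames(complexFreqs)))
    stop("strain missing from the complex community: ",
         paste(setdiff(c(winner, loser), colnames(complexFreqs)),
               collapse = ", "))
  w <- complexFreqs[, winner]
  l <- complexFreqs[, loser]
  mean(ifelse(w > l, 1, ifelse(w < l, 0, 0.5)))
}

#' Rank strains by mean frequency across replicates
#'
#' @param freqs replicates x strains frequency table.
#' @param members optional subset of strains to rank (e.g. restrict a C68
#'   table to the C3 members); defaults to all columns.
#' @return data.frame ordered by decreasing mean frequency: `rank`,
#'   `strain`, `meanFreq`, `tied` (exact mean ties, broken
#'   lexicographically).
#' @export
communityRanking <- function(freqs, members = NULL) {
  freqs <- as.matrix(freqs)
  if (nrow(freqs) < 1L) stop("need >= 1 replicate")
  if (!is.null(members)) {
    if (!all(members %in% colnames(freqs)))
      stop("member strain(s) missing from table")
    freqs <- freqs[, members, drop = FALSE]
  }
  m <- colMeans(freqs)
  ord <- order(-m, colnames(freqs))  # ties broken lexicographically
  tied <- duplicated(m[ord]) | duplicated(m[ord], fromLast = TRUE)
  data.frame(rank = seq_along(ord), strain = colnames(freqs)[ord],
             meanFreq = unname(m[ord]), tied = tied,
             stringsAsFactors = FALSE)
}

#' Rank-consistency report across community complexities
#'
#' For every host and every pairwise community, identifies the pairwise
#' winner and reports, for each more complex community, the proportion of
#' replicates in which that winner also had the higher relative frequency —
#' the shape of the study question "does strain A always beat strain B
#' regardless of how many other strains are present?".
#'
#' @param freqTables nested list: `freqTables[[host]][[community]]` is a
#'   replicates x strains frequency table.  Two-column tables are treated as
#'   the pairwise communities; the others as complex communities.
#' @param complexOrder optional character vector ordering the complex
#'   community columns in the output (default: increasing strain count).
#' @return list of class `"rankReport"`: `pairs` (data.frame: host, pair,
#'   winner, pairwise mean frequencies, one consistency column per complex
#'   community) and `rankings` (per host x community [communityRanking()]
#'   results).
#' @export
rankReport <- function(freqTables, complexOrder = NULL) {
  pairsOut <- list()
  rankings <- list()
  for (h in names(freqTables)) {
    tabs <- freqTables[[h]]
    nStr <- vapply(tabs, ncol, 0L)
    pairComms <- names(tabs)[nStr == 2L]
    complexComms <- names(tabs)[nStr > 2L]
    complexComms <- complexComms[order(nStr[complexComms])]
    if (!is.null(complexOrder))
      complexComms <- intersect(complexOrder, complexComms)
    for (pc in pairComms) {
      pw <- pairwiseWinner(tabs[[pc]])
      row <- data.frame(host = h, pair = pc,
                        winner = pw$winner,
                        winnerFreq = if (pw$tie) NA else
                          unname(pw$meanFreqs[pw$winner]),
                        tie = pw$tie, stringsAsFactors = FALSE)
      for (cc in complexComms)
        row[[cc]] <- if (pw$tie) NA_real_ else
          consistencyProportion(pw$winner, pw$loser, tabs[[cc]])
      pairsOut[[paste(h, pc)]] <- row
    }
    rankings[[h]] <- lapply(tabs[complexComms], communityRanking)
  }
  structure(list(pairs = do.call(rbind, pairsOut), rankings = rankings),
            class = "rankReport")
}

#' @export
print.rankReport <- function(x, ...) {
  cat("Rank-consistency report\n")
  tab <- x$pairs
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a rank report to CSV files
#'
#' @param report a [rankReport()].
#' @param pairsPath CSV for the pairwise-consistency table.
#' @param rankingsPath optional CSV for the per-community rankings (long
#'   format: host, community, rank, strain, meanFreq).
#' @return `pairsPath`, invisibly.
#' @export
writeRankReport <- function(report, pairsPath, rankingsPath = NULL) {
  utils::write.csv(report$pairs, pairsPath, row.names = FALSE)
  if (!is.null(rankingsPath)) {
    rows <- list()
    for (h in names(report$rankings))
      for (cc in names(report$rankings[[h]])) {
        r <- report$rankings[[h]][[cc]]
        rows[[paste(h, cc)]] <- cbind(host = h, community = cc, r)
      }
    utils::write.csv(do.call(rbind, rows), rankingsPath, row.names = FALSE)
  }
  invisible(pairsPath)
}
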