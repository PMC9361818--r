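#' @include AllClasses.R
NULL

#' Load a strain haplotype panel
#'
#' Reads a reference panel from either a multi-sample VCF (one haploid, or
#' homozygous-diploid, genotype column per strain) or the package's plain
#' allele-matrix TSV dialect (header `chrom pos ref alt strain1 ... strainN`,
#' cells are 0-based allele indices, `.` = missing).
#'
#' All SNP records are returned, with missing or heterozygous genotypes
#' encoded as `NA`; run [filterUnambiguous()] before estimation.  Indel and
#' other non-SNP records are skipped with a message.  Strain order follows
#' the file's column order.
#'
#' @param path path to the VCF (plain or bgzipped) or TSV file.
#' @param format `"vcf"` or `"tsv"`; guessed from the file extension by
#'   default.
#' @return A [StrainPanel-class] object.
#' @export
loadPanel <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "vcf") .loadPanelVcf(path) else .loadPanelTsv(path)
}

.loadPanelVcf <- function(path) {
  vcf <- tryCatch(
    suppressMessages(suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- colnames(vcf@gt)[-1L]
  if (anyDuplicated(ids))
    stop("duplicate strain names in VCF: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  altList <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  isSnp <- nchar(ref) == 1L & ref %in% VALID_BASES &
    lengths(altList) >= 1L &
    vapply(altList, function(a) all(nchar(a) == 1L & a %in% VALID_BASES), TRUE)
  nSkip <- sum(!isSnp)
  if (nSkip) message("skipped ", nSkip, " non-SNP record(s)")
  if (!any(isSnp)) stop("no SNP records in VCF '", path, "'")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[isSnp, , drop = FALSE]
  parsed <- vapply(gt, .parseGenotype, integer(1L))  # column-major over sites x strains
  alleles <- t(matrix(parsed, nrow = nrow(gt), ncol = ncol(gt)))
  dimnames(alleles) <- list(ids, NULL)
  sites <- data.frame(chrom = fix[isSnp, "CHROM"],
                      pos = as.integer(fix[isSnp, "POS"]),
                      ref = ref[isSnp],
                      alt = alt[isSnp],
                      stringsAsFactors = FALSE)
  strainPanel(ids, sites, alleles,
              provenance = paste0("VCF: ", path))
}

# one GT string -> 0-based allele index, or NA for missing/heterozygous
.parseGenotype <- function(g) {
  if (is.na(g) || g == "." || g == "./." || g == ".|.") return(NA_integer_)
  parts <- strsplit(g, "[/|]")[[1L]]
  if (any(parts == ".")) return(NA_integer_)
  vals <- suppressWarnings(as.integer(parts))
  if (anyNA(vals)) return(NA_integer_)
  if (length(unique(vals)) > 1L) return(NA_integer_)  # heterozygous: ambiguous
  vals[1L]
}

.loadPanelTsv <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character"),
    error = function(e) stop("malformed panel TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab)[1:4]))
    stop("panel TSV '", path,
         "' must start with columns chrom, pos, ref, alt")
  ids <- names(tab)[-(1:4)]
  if (length(ids) < 1L) stop("panel TSV has no strain columns")
  if (anyDuplicated(ids))
    stop("duplicate strain names in TSV: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- as.matrix(tab[, -(1:4), drop = FALSE])
  cells[cells == "."] <- NA
  vals <- suppressWarnings(as.integer(cells))
  if (any(is.na(vals) & !is.na(cells)))
    stop("non-numeric allele cell in panel TSV '", path, "'")
  alleles <- t(matrix(vals, nrow = nrow(tab), dimnames = list(NULL, ids)))
  sites <- data.frame(chrom = tab$chrom, pos = as.integer(tab$pos),
                      ref = tab$ref, alt = tab$alt, stringsAsFactors = FALSE)
  strainPanel(ids, sites, alleles, provenance = paste0("TSV: ", path))
}

#' Write a strain panel to TSV
#'
#' Writes the panel in the TSV dialect read by [loadPanel()]; a
#' load -> write -> load round trip reproduces the allele matrix exactly.
#'
#' @param panel a [StrainPanel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path) {
  cells <- t(panel@alleles)
  cells[is.na(cells)] <- "."
  tab <- cbind(siteInfo(panel), as.data.frame(cells))
  names(tab) <- c("chrom", "pos", "ref", "alt", strainIds(panel))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep only sites with an unambiguous call in every strain
#'
#' Restricts the panel to SNP sites where every strain has a definite
#' single-allele call (no missing, no heterozygous genotypes), then drops
#' sites that are no longer segregating among the panel strains.  Site order
#' is preserved.  The operation is idempotent.
#'
#' @param panel a [StrainPanel-class], possibly containing `NA` sentinels.
#' @return The filtered [StrainPanel-class].
#' @export
filterUnambiguous <- function(panel) {
  al <- panel@alleles
  complete <- !apply(is.na(al), 2L, any)
  seg <- complete
  if (any(complete)) {
    sub <- al[, complete, drop = FALSE]
    segOk <- apply(sub, 2L, function(col) length(unique(col)) >= 2L)
    seg[complete] <- segOk
  }
  if (!any(seg))
    stop("no sites survive filtering: panel is unusable for estimation")
  strainPanel(strainIds(panel), siteInfo(panel)[seg, , drop = FALSE],
              al[, seg, drop = FALSE],
              provenance = paste0(panel@provenance, " [filtered]"))
}

#' Pairwise differing-site counts between panel strains
#'
#' Computes the n x n matrix of pairwise Hamming distances (number of sites
#' with differing alleles) over the panel's sites and flags strain pairs that
#' differ at fewer than `minPairwiseSnps` sites with a warning.  Well
#' separated strains (the study's strains differ at >1000 SNPs) are what give
#' pooled reads their discriminating power.
#'
#' @param panel a filtered [StrainPanel-class].
#' @param minPairwiseSnps pairs below this distance are flagged
#'   (default 1000).
#' @return A list with `distances` (symmetric integer matrix with zero
#'   diagonal) and `flagged` (data.frame of under-separated pairs with their
#'   distances), plus `minPairwiseSnps`.  Class `"panelValidation"`.
#' @export
validatePanel <- function(panel, minPairwiseSnps = 1000) {
  al <- panel@alleles
  n <- nrow(al)
  D <- matrix(0L, n, n, dimnames = list(strainIds(panel), strainIds(panel)))
  for (i in seq_len(n)) {
    diffs <- sweep(al, 2L, al[i, ], FUN = "!=")
    D[i, ] <- as.integer(rowSums(diffs, na.rm = TRUE))
  }
  pairs <- which(upper.tri(D) & D < minPairwiseSnps, arr.ind = TRUE)
  flagged <- data.frame(strain1 = strainIds(panel)[pairs[, 1L]],
                        strain2 = strainIds(panel)[pairs[, 2L]],
                        nDiffSites = D[pairs],
                        stringsAsFactors = FALSE)
  if (nrow(flagged))
    warning(nrow(flagged), " strain pair(s) differ at fewer than ",
            minPairwiseSnps, " sites", call. = FALSE)
  structure(list(distances = D, flagged = flagged,
                 minPairwiseSnps = minPairwiseSnps),
            class = "panelValidation")
}

#' @export
print.panelValidation <- function(x, ...) {
  n <- nrow(x$distances)
  off <- x$distances[upper.tri(x$distances)]
  cat("Panel validation:", n, "strains;",
      "pairwise differing sites median", stats::median(off),
      "range", min(off), "-", max(off), "\n")
  if (nrow(x$flagged))
    cat("  ", nrow(x$flagged), "pair(s) below", x$minPairwiseSnps, "sites\n")
  else
    cat("  all pairs at or above", x$minPairwiseSnps, "sites\n")
  invisible(x)
}

#' Write a panel validation report to CSV
#'
#' @param report result of [validatePanel()].
#' @param path output CSV path (long format: strain1, strain2, nDiffSites,
#'   flagged).
#' @return `path`, invisibly.
#' @export
writeValidationReport <- function(report, path) {
  D <- report$distances
  idx <- which(upper.tri(D), arr.ind = TRUE)
  out <- data.frame(strain1 = rownames(D)[idx[, 1L]],
                    strain2 = colnames(D)[idx[, 2L]],
                    nDiffSites = D[idx],
                    flagged = D[idx] < report$minPairwiseSnps)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
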