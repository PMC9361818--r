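# Fixtures are built in code: no binary files, everything seeded.

# A tiny fully-called panel: `n` strains, `L` biallelic sites, alleles given
# row-wise or drawn at random.
toyPanel <- function(alleles, ids = NULL) {
  alleles <- as.matrix(alleles)
  n <- nrow(alleles); L <- ncol(alleles)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  sites <- data.frame(chrom = "chr1", pos = seq_len(L), ref = "A", alt = "C")
  strainPanel(ids, sites, alleles)
}

# Two strains complementary at every site: reads are unambiguous.
distinctPairPanel <- function(L = 10) toyPanel(rbind(rep(0L, L), rep(1L, L)))

# A PooledSample with one read per row of `mat` (sites = columns, values =
# observed alleles; NA = site not covered).
sampleFromReads <- function(mat, sampleId = "s1") {
  calls <- do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    sites <- which(!is.na(mat[i, ]))
    data.frame(read = i, site = sites, allele = mat[i, sites])
  }))
  pooledSample(sampleId, calls,
               readIds = paste0("r", seq_len(nrow(mat))))
}

# Minimal multi-sample VCF written as text; gts is a sites x strains
# character matrix of GT strings.
writeToyVcf <- function(path, chrom, pos, ref, alt, gts, ids) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(chrom)[1], ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i)
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t"), "")
  writeLines(c(hdr, body), path)
  path
}

# Independent sequential-SS oracle: explicit projection (hat) matrices,
# written without reference to the package's QR-based implementation.
projectionSSOracle <- function(Y, X, assign) {
  Y <- scale(Y)
  hats <- lapply(seq_len(max(assign)), function(j) {
    Xj <- scale(X[, assign <= j & assign > 0, drop = FALSE], scale = FALSE)
    Xj %*% solve(crossprod(Xj)) %*% t(Xj)
  })
  cum <- vapply(hats, function(H) sum((H %*% Y)^2), 0)
  c(cum[1], diff(cum))
}
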