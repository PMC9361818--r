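#' @include AllClasses.R
NULL

#' Build a treatment-coded design matrix
#'
#' Expands a model formula over experimental factors into a design matrix
#' with treatment contrasts and declared reference levels (A17, low density,
#' N-) when those levels are present, keeping the term structure needed for
#' sequential (Type I) tests.
#'
#' @param data data.frame of sample metadata, rows aligned with the response.
#' @param formula right-hand-side formula over columns of `data`, e.g.
#'   `~ host * density * nitrogen`.
#' @return list of class `"designMatrix"`: `X` (model matrix including
#'   intercept), `assign` (column -> term index), `termLabels`, `data`,
#'   `formula`.
#' @export
designMatrix <- function(data, formula) {
  data <- as.data.frame(data)
  refs <- c(host = "A17", density = "low", nitrogen = "N-")
  for (v in all.vars(formula)) {
    if (!v %in% names(data)) stop("factor '", v, "' not found in metadata")
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]]) && v %in% names(refs) &&
        refs[[v]] %in% levels(data[[v]]))
      data[[v]] <- stats::relevel(data[[v]], ref = refs[[v]])
  }
  old <- options(contrasts = c("contr.treatment", "contr.poly"))
  on.exit(options(old))
  X <- stats::model.matrix(formula, data)
  structure(list(X = X, assign = attr(X, "assign"),
                 termLabels = attr(stats::terms(formula), "term.labels"),
                 data = data, formula = formula),
            class = "designMatrix")
}

# Standardize response columns: center, unit variance; drop zero-variance
# columns with a warning.  Returns the matrix (possibly fewer columns).
.standardizeResponse <- function(Y) {
  Y <- as.matrix(Y)
  sds <- apply(Y, 2L, stats::sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero)) {
    warning("dropped ", sum(zero), " zero-variance response column(s): ",
            paste(colnames(Y)[zero], collapse = ", "), call. = FALSE)
    Y <- Y[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  scale(Y, center = TRUE, scale = sds)
}

# Sequential projections for the terms of a design.
# Returns list(H = list of cumulative hat matrices, df = rank increments,
# labels).  Errors on rank deficiency, naming the aliased term.
.sequentialProjections <- function(design, n) {
  Xc <- scale(design$X[, design$assign != 0L, drop = FALSE],
              center = TRUE, scale = FALSE)
  assign <- design$assign[design$assign != 0L]
  labels <- design$termLabels
  H <- vector("list", length(labels))
  df <- integer(length(labels))
  prevRank <- 0L
  for (j in seq_along(labels)) {
    cols <- which(assign <= j)
    qrj <- qr(Xc[, cols, drop = FALSE])
    nAdded <- sum(assign == j)
    dfj <- qrj$rank - prevRank
    if (dfj < nAdded)
      stop("rank-deficient design: term '", labels[j],
           "' is aliased with preceding terms")
    Q <- qr.Q(qrj)[, seq_len(qrj$rank), drop = FALSE]
    H[[j]] <- tcrossprod(Q)
    df[j] <- dfj
    prevRank <- qrj$rank
  }
  list(H = H, df = df, labels = labels)
}

# Per-term sequential SS of Y under the cumulative projections.
.termSS <- function(Y, proj) {
  cum <- vapply(proj$H, function(H) sum((H %*% Y)^2), 0)
  c(cum[1L], diff(cum))
}

#' Redundancy analysis with sequential variance partitioning
#'
#' Fits a multivariate linear regression of the column-centered,
#' unit-variance response matrix on the design, partitioning the total
#' variance into sequential (Type I) per-term components: each term's sum of
#' squares is the increment in fitted sum of squares when the term is added
#' after all preceding terms.  A PCA of the full-model fitted values gives
#' the constrained ordination axes.
#'
#' Pseudo-F per term is `(SS_term / df_term) / (SS_resid / df_resid)` with
#' the residual taken from the full model; `adjR2 = 1 - (1 - R2)(n - 1) /
#' (n - p - 1)` with `p` the total model df.  Use [permutationTest()] for
#' p-values.
#'
#' @param Y samples x variables response matrix (e.g. a fitness matrix);
#'   zero-variance columns are dropped with a warning.
#' @param design a [designMatrix()] with rows aligned to `Y`.
#' @return list of class `"rdaResult"`: `table` (term, df, propVar, F; plus
#'   Residual row), `adjR2`, `R2`, `eig` (eigenvalues of the constrained
#'   axes), `siteScores`, `n`, `modelDf`.
#' @export
rdaFit <- function(Y, design) {
  Ys <- .standardizeResponse(Y)
  n <- nrow(Ys)
  proj <- .sequentialProjections(design, n)
  p <- sum(proj$df)
  if (n <= p + 1L) stop("need more samples than model df")
  ssTotal <- sum(Ys^2)
  ss <- .termSS(Ys, proj)
  ssModel <- sum(ss)
  # guard against FP cancellation on (near-)perfect fits; F then = Inf
  ssRes <- max(ssTotal - ssModel, 0)
  dfRes <- n - 1L - p
  Fstat <- (ss / proj$df) / (ssRes / dfRes)
  R2 <- ssModel / ssTotal
  adjR2 <- 1 - (1 - R2) * (n - 1) / (n - p - 1)
  fitted <- proj$H[[length(proj$H)]] %*% Ys
  sv <- svd(fitted)
  nAxes <- sum(sv$d > max(sv$d) * 1e-8)
  scores <- sv$u[, seq_len(nAxes), drop = FALSE] %*%
    diag(sv$d[seq_len(nAxes)], nAxes)
  colnames(scores) <- paste0("RDA", seq_len(nAxes))
  tab <- data.frame(
    term = c(proj$labels, "Residual"),
    df = c(proj$df, dfRes),
    propVar = c(ss, ssRes) / ssTotal,
    F = c(Fstat, NA),
    stringsAsFactors = FALSE)
  stopifnot(abs(sum(tab$propVar) - 1) < 1e-9,
            sum(tab$df) == n - 1L)
  structure(list(table = tab, adjR2 = adjR2, R2 = R2,
                 eig = (sv$d[seq_len(nAxes)]^2) / (n - 1),
                 siteScores = scores, n = n, modelDf = p),
            class = "rdaResult")
}

#' @export
print.rdaResult <- function(x, ...) {
  cat("Redundancy analysis:", x$n, "samples, model df", x$modelDf,
      ", adjusted R2 =", round(x$adjR2, 3), "\n")
  tab <- x$table
  tab$propVar <- round(tab$propVar, 3)
  tab$F <- round(tab$F, 2)
  if (!is.null(tab$P)) tab$P <- signif(tab$P, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Permutation test of RDA terms
#'
#' Permutes the rows of the response as whole units (free permutation),
#' recomputes every term's sequential pseudo-F under each permutation (the
#' same permutation serves all terms in an iteration), and reports
#' `p = (1 + #{F_perm >= F_obs}) / (1 + nPerm)`, so the smallest attainable
#' p with 999 permutations is 0.001.
#'
#' @param Y response matrix.
#' @param design a [designMatrix()].
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed.
#' @return An `"rdaResult"` as from [rdaFit()] with a `P` column added to
#'   the table and `nPerm` recorded.
#' @export
permutationTest <- function(Y, design, nPerm = 999L, seed = 1L) {
  fit <- rdaFit(Y, design)
  Ys <- suppressWarnings(.standardizeResponse(Y))
  n <- nrow(Ys)
  proj <- .sequentialProjections(design, n)
  p <- sum(proj$df)
  dfRes <- n - 1L - p
  ssTotal <- sum(Ys^2)
  obsF <- fit$table$F[seq_along(proj$labels)]
  count <- integer(length(obsF))
  set.seed(seed)
  for (i in seq_len(nPerm)) {
    Yp <- Ys[sample.int(n), , drop = FALSE]
    ss <- .termSS(Yp, proj)
    ssRes <- max(ssTotal - sum(ss), 0)
    Fp <- (ss / proj$df) / (ssRes / dfRes)
    count <- count + (Fp >= obsF)
  }
  pvals <- (1L + count) / (1L + nPerm)
  fit$table$P <- c(pvals, NA)
  fit$nPerm <- nPerm
  fit
}

#' Sequential ANOVA of a scalar response
#'
#' Ordinary fixed-effects ANOVA with sequential (Type I) sums of squares via
#' `stats::lm()` + `stats::anova()`; F is tested against the residual mean
#' square with parametric F-distribution p-values.  A constant response
#' yields all-zero SS with `NA` statistics and a warning.
#'
#' @param y numeric response vector (e.g. diversity, benefit, a plant
#'   trait).
#' @param design a [designMatrix()].
#' @return data.frame: term, df, SS, F, P (with Residual row).
#' @export
anovaTerms <- function(y, design) {
  dat <- design$data
  dat$.y <- y
  form <- stats::update(design$formula, .y ~ .)
  fit <- stats::lm(form, data = dat)
  if (stats::df.residual(fit) == 0L) stop("zero residual degrees of freedom")
  a <- stats::anova(fit)
  out <- data.frame(term = rownames(a), df = a$Df, SS = a$`Sum Sq`,
                    F = a$`F value`, P = a$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  out$term[out$term == "Residuals"] <- "Residual"
  if (stats::sd(y) == 0) {
    warning("constant response: F undefined", call. = FALSE)
    out$F <- NA_real_
    out$P <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Per-host RDA submodels
#'
#' Splits samples by host genotype and fits
#' `~ density * nitrogen` (density + nitrogen + their interaction) within
#' each host, with permutation p-values.  Nitrogen is retained even when its
#' marginal effect is weak because host levels differ strongly in both mean
#' and variance.  Hosts with too few samples for the submodel are skipped
#' with a warning.
#'
#' @param Y response matrix.
#' @param metadata data.frame with a `host` column (plus `density`,
#'   `nitrogen`), rows aligned with `Y`.
#' @param nPerm permutations per submodel (default 999).
#' @param seed RNG seed.
#' @return Named list of `"rdaResult"` objects, one per host level.
#' @export
perHostSubmodels <- function(Y, metadata, nPerm = 999L, seed = 1L) {
  Y <- as.matrix(Y)
  hosts <- unique(as.character(metadata$host))
  out <- list()
  for (h in hosts) {
    idx <- which(metadata$host == h)
    sub <- droplevels(metadata[idx, , drop = FALSE])
    res <- tryCatch({
      d <- designMatrix(sub, ~ density * nitrogen)
      permutationTest(Y[idx, , drop = FALSE], d, nPerm = nPerm, seed = seed)
    }, error = function(e) {
      warning("host ", h, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(res)) out[[h]] <- res
  }
  out
}

#' Write an RDA result as a Table-1-shaped CSV
#'
#' @param result an `"rdaResult"`.
#' @param path output CSV (columns term, DF, Prop.Var, F, P).
#' @return `path`, invisibly.
#' @export
writeRdaTable <- function(result, path) {
  tab <- result$table
  out <- data.frame(term = tab$term, DF = tab$df,
                    Prop.Var = tab$propVar, F = tab$F,
                    P = if (!is.null(tab$P)) tab$P else NA)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
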