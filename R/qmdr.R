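#' @include gwas-io.R
NULL

# Align a named phenotype with the sample columns of a GenotypeData and
# check basic sanity.  Every genotyped sample must have a phenotype value.
.alignPhenotype <- function(genotypes, phenotype) {
  if (length(phenotype) == 0) stop("phenotype is empty")
  if (is.null(names(phenotype)))
    stop("phenotype must be named by sample id")
  ids <- sampleIds(genotypes)
  idx <- match(ids, names(phenotype))
  if (anyNA(idx))
    stop("phenotype missing for samples: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  y <- as.numeric(phenotype[idx])
  if (any(!is.finite(y))) stop("phenotype values must be finite")
  names(y) <- ids
  y
}

#' Build the multilocus genotype cell table for a SNP subset
#'
#' The constructive-induction step of QMDR: samples are grouped by their
#' joint genotype over \code{snpIds} (up to 3^k cells), recording each
#' cell's sample count and phenotype mean.  Samples with a missing genotype
#' at any subset SNP are excluded from the model; the global mean is taken
#' over the included samples only.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param phenotype named numeric vector covering all samples.
#' @param snpIds SNP subset of size 1 to \code{maxOrder}.
#' @param maxOrder largest admissible subset size (default 4).
#' @return a \linkS4class{CellTable}.
#' @export
buildCellTable <- function(genotypes, phenotype, snpIds, maxOrder = 4L) {
  k <- length(snpIds)
  if (k < 1 || k > maxOrder)
    stop(sprintf("subset size must be between 1 and %d", maxOrder))
  missing <- setdiff(snpIds, rownames(genotypes))
  if (length(missing))
    stop("unknown SNPs: ", paste(missing, collapse = ", "))
  y <- .alignPhenotype(genotypes, phenotype)
  g <- dosages(genotypes)[snpIds, , drop = FALSE]
  keep <- colSums(is.na(g)) == 0L
  if (sum(keep) < 2)
    stop("fewer than 2 samples with complete genotypes for this subset")
  g <- g[, keep, drop = FALSE]
  y <- y[keep]
  code <- as.integer(colSums(g * 3^((k - 1):0)))
  cells <- sort(unique(code))
  assign <- match(code, cells)
  n <- as.integer(tabulate(assign, nbins = length(cells)))
  csum <- vapply(seq_along(cells), function(i) sum(y[assign == i]),
                 numeric(1))
  geno <- t(vapply(cells, function(c) {
    out <- integer(k)
    for (j in k:1) { out[j] <- c %% 3L; c <- c %/% 3L }
    out
  }, integer(k)))
  if (k == 1L) geno <- matrix(as.integer(geno), ncol = 1L)
  colnames(geno) <- snpIds
  new("CellTable", snpIds = snpIds, genotypes = geno, n = n,
      mean = csum / n, globalMean = mean(y),
      assignment = as.integer(assign), phenotype = unname(y))
}

#' Label cells HIGH or LOW about the global mean
#'
#' A cell is HIGH iff its phenotype mean is greater than or equal to the
#' global mean of the included samples (ties go HIGH), else LOW.
#'
#' @param table a \linkS4class{CellTable}.
#' @return character vector of "HIGH"/"LOW", one per cell.
#' @export
assignCellLabels <- function(table) {
  stopifnot(is(table, "CellTable"))
  if (length(table@n) == 0) stop("cell table is empty")
  ifelse(table@mean >= table@globalMean, "HIGH", "LOW")
}

#' Welch two-sample t statistic of the high/low pooling
#'
#' \eqn{t = (\bar y_H - \bar y_L) / \sqrt{s_H^2/n_H + s_L^2/n_L}} with
#' unbiased group variances (a singleton group contributes zero spread).
#' If either group is empty, or the pooled spread is zero, the statistic is
#' undefined: a sentinel 0 is returned with attribute
#' \code{degenerate = TRUE} so exhaustive scans never abort.
#'
#' @param high,low phenotype values of the HIGH and LOW groups.
#' @return the t statistic, with a logical attribute \code{"degenerate"}.
#' @export
qmdrStatistic <- function(high, low) {
  deg <- function() structure(0, degenerate = TRUE)
  nh <- length(high); nl <- length(low)
  if (nh == 0 || nl == 0) return(deg())
  vh <- if (nh > 1) stats::var(high) else 0
  vl <- if (nl > 1) stats::var(low) else 0
  se2 <- vh / nh + vl / nl
  if (se2 <= 0) return(deg())
  structure((mean(high) - mean(low)) / sqrt(se2), degenerate = FALSE)
}

#' Fit a QMDR model for one SNP subset
#'
#' Composes [buildCellTable()], [assignCellLabels()] and [qmdrStatistic()].
#' By the labelling rule the statistic is non-negative up to tie effects;
#' larger is better.  With \code{cv = TRUE} an additional 10-fold
#' cross-validation consistency score is computed (cells labelled on the
#' training folds, Welch t evaluated on the held-out fold, averaged); this
#' is reporting only and never drives model selection.
#'
#' @inheritParams buildCellTable
#' @param cv compute the optional 10-fold consistency score (default
#'   FALSE; significance in this pipeline comes from permutation, not CV).
#' @param nFolds folds used when \code{cv = TRUE}.
#' @return a \linkS4class{QmdrModel}.
#' @export
fitQmdr <- function(genotypes, phenotype, snpIds, cv = FALSE, nFolds = 10L) {
  ct <- buildCellTable(genotypes, phenotype, snpIds)
  labels <- assignCellLabels(ct)
  sampleLabel <- labels[ct@assignment]
  t <- qmdrStatistic(ct@phenotype[sampleLabel == "HIGH"],
                     ct@phenotype[sampleLabel == "LOW"])
  cvStat <- NA_real_
  if (cv) cvStat <- .qmdrCvScore(ct, nFolds)
  new("QmdrModel", snpIds = snpIds, cellTable = ct,
      labels = unname(labels), tStatistic = as.numeric(t),
      nHigh = sum(sampleLabel == "HIGH"),
      nLow = sum(sampleLabel == "LOW"),
      degenerate = attr(t, "degenerate"),
      pValue = NA_real_, cvStatistic = cvStat)
}

# 10-fold CV consistency: per fold, cell means and the global mean are
# recomputed on the training samples, held-out samples are pooled by the
# training labels, and the testing Welch t recorded.  Cells unseen in
# training send their test samples to LOW.
.qmdrCvScore <- function(ct, nFolds = 10L) {
  n <- length(ct@phenotype)
  if (n < nFolds) return(NA_real_)
  fold <- rep(seq_len(nFolds), length.out = n)
  ts <- vapply(seq_len(nFolds), function(f) {
    tr <- fold != f
    if (sum(tr) < 2) return(NA_real_)
    ytr <- ct@phenotype[tr]
    atr <- ct@assignment[tr]
    gm <- mean(ytr)
    cm <- vapply(seq_along(ct@n), function(i) {
      v <- ytr[atr == i]
      if (length(v)) mean(v) else -Inf  # unseen cell -> LOW
    }, numeric(1))
    lab <- ifelse(cm >= gm, "HIGH", "LOW")
    te <- !tr
    sl <- lab[ct@assignment[te]]
    yte <- ct@phenotype[te]
    as.numeric(qmdrStatistic(yte[sl == "HIGH"], yte[sl == "LOW"]))
  }, numeric(1))
  mean(ts, na.rm = TRUE)
}

#' @rdname QmdrModel-class
#' @export
setMethod("tStatistic", "QmdrModel", function(x) x@tStatistic)

#' @rdname QmdrModel-class
#' @export
setMethod("cellLabels", "QmdrModel", function(x)
  stats::setNames(x@labels,
                  apply(x@cellTable@genotypes, 1, paste, collapse = "/")))

#' @rdname QmdrModel-class
#' @export
setMethod("isDegenerate", "QmdrModel", function(x) x@degenerate)

#' @rdname QmdrModel-class
#' @export
setMethod("snpIds", "QmdrModel", function(x) x@snpIds)

#' @rdname PermutationResult-class
#' @export
setMethod("empiricalP", "QmdrModel", function(x) x@pValue)

setMethod("show", "QmdrModel", function(object) {
  cat("QmdrModel over", paste(object@snpIds, collapse = ", "), "\n")
  cat(sprintf("  t = %.4f (HIGH n=%d, LOW n=%d)%s\n", object@tStatistic,
              object@nHigh, object@nLow,
              if (object@degenerate) " [degenerate]" else ""))
  if (!is.na(object@pValue))
    cat(sprintf("  permutation p = %.6g\n", object@pValue))
})

#' Serialize a QmdrModel to JSON
#'
#' Emits the SNP subset, every cell (genotype tuple, n, mean, label), the
#' t statistic, group sizes, and the permutation p when present.
#'
#' @param model a \linkS4class{QmdrModel}.
#' @param path optional output path; when NULL the JSON string is returned.
#' @export
qmdrModelJson <- function(model, path = NULL) {
  ct <- model@cellTable
  obj <- list(
    snp_ids = ct@snpIds,
    cells = lapply(seq_along(ct@n), function(i) list(
      genotypes = as.integer(ct@genotypes[i, ]),
      n = ct@n[i], mean = ct@mean[i], label = model@labels[i])),
    global_mean = ct@globalMean,
    t = model@tStatistic, n_high = model@nHigh, n_low = model@nLow,
    degenerate = model@degenerate,
    p = if (is.na(model@pValue)) NULL else model@pValue)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

# Fast exhaustive scoring used by the screens: QMDR t for each subset
# (list of SNP-id character vectors) via the compiled kernel.
.scoreSubsets <- function(genotypes, y, subsets) {
  g <- dosages(genotypes)
  idx <- lapply(subsets, function(s) match(s, rownames(g)))
  cpp_qmdr_scores(g, as.numeric(y), idx)
}

#' Build a fast exhaustive-search closure
#'
#' Returns a function \code{(genotypes, phenotype) -> max t} over the
#' given subsets, with the dosage matrix and row indices resolved once so
#' the closure is cheap enough to call inside permutation loops (it is
#' what [permutationTest()] expects as its \code{search}).
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param subsets list of SNP-id vectors to score (e.g. from
#'   [enumerateModels()]).
#' @return a function of (genotypes, phenotype) returning the best score.
#' @export
makeExhaustiveSearch <- function(genotypes, subsets) {
  g <- dosages(genotypes)
  idx <- lapply(subsets, function(s) {
    i <- match(s, rownames(g))
    if (anyNA(i)) stop("unknown SNPs: ", paste(s[is.na(i)], collapse = ", "))
    i
  })
  function(genotypes, phenotype)
    max(cpp_qmdr_scores(g, as.numeric(phenotype), idx))
}

#' Score many QMDR models at once
#'
#' The QMDR t statistic for each SNP subset, computed by the same kernel
#' the exhaustive searches use.  Degenerate models score 0.
#'
#' @inheritParams buildCellTable
#' @param subsets list of SNP-id vectors (sizes 1--4).
#' @return numeric vector of t statistics, one per subset.
#' @export
scoreModels <- function(genotypes, phenotype, subsets) {
  y <- .alignPhenotype(genotypes, phenotype)
  bad <- setdiff(unique(unlist(subsets)), rownames(genotypes))
  if (length(bad)) stop("unknown SNPs: ", paste(bad, collapse = ", "))
  .scoreSubsets(genotypes, y, subsets)
}
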