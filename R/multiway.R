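#' @include functional-filter.R
NULL

#' Enumerate SNP subsets for the final exhaustive search
#'
#' Deterministic enumeration: orders ascending, subsets within an order in
#' lexicographic order of the sorted SNP ids; no duplicates.
#'
#' @param snpIds ordered candidate SNP set.
#' @param orders model orders (default 2, 3 and 4: all pairwise,
#'   three-way and four-way models).
#' @return list of character vectors.
#' @export
enumerateModels <- function(snpIds, orders = c(2L, 3L, 4L)) {
  snpIds <- sort(unique(as.character(snpIds)))
  orders <- sort(unique(as.integer(orders)))
  if (any(orders < 1)) stop("orders must be >= 1")
  if (max(orders) > length(snpIds))
    stop(sprintf("order %d exceeds the number of candidate SNPs (%d)",
                 max(orders), length(snpIds)))
  unlist(lapply(orders, function(k)
    utils::combn(snpIds, k, simplify = FALSE)), recursive = FALSE)
}

#' Exhaustive multi-way QMDR search with permutation significance
#'
#' Scores every enumerated subset, selects the maximum t (within a 1e-9
#' score tolerance the smaller order, then the lexicographically first
#' subset, wins), and attaches an empirical p-value from a permutation
#' test that re-runs the full enumeration on each shuffled phenotype.
#' Every evaluated score is kept for audit.  The reported p is conditional
#' on the upstream screening that produced the candidate set.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param phenotype named numeric vector.
#' @param snpIds candidate SNPs.
#' @param orders model orders searched (default 2:4).
#' @param nPermutations permutations (default 1000).
#' @param seed master seed for the permutation stream.
#' @return a \linkS4class{SearchReport}.
#' @export
searchBestModel <- function(genotypes, phenotype, snpIds,
                            orders = c(2L, 3L, 4L), nPermutations = 1000L,
                            seed = 1L) {
  y <- .alignPhenotype(genotypes, phenotype)
  if (stats::sd(y) == 0) stop("phenotype is degenerate (constant)")
  m <- length(unique(snpIds))
  if (m < min(orders)) stop("fewer candidate SNPs than the smallest order")
  if (any(orders > m)) {
    message("dropping orders above the candidate count: ",
            paste(orders[orders > m], collapse = ", "))
    orders <- orders[orders <= m]
  }
  subsets <- enumerateModels(snpIds, orders)
  g <- dosages(genotypes)
  idx <- lapply(subsets, function(s) match(s, rownames(g)))
  scores <- cpp_qmdr_scores(g, as.numeric(y), idx)
  best <- which(scores >= max(scores) - 1e-9)[1]  # smaller order first
  search <- function(genotypes, yy)
    max(cpp_qmdr_scores(g, as.numeric(yy), idx))
  perm <- permutationTest(search, genotypes, y, nPermutations, seed)
  model <- fitQmdr(genotypes, y, subsets[[best]])
  model@pValue <- empiricalP(perm)
  evaluated <- data.frame(
    snp_ids = vapply(subsets, paste, character(1), collapse = "/"),
    order = lengths(subsets), t = as.numeric(scores),
    stringsAsFactors = FALSE)
  new("SearchReport", candidateSnps = sort(unique(as.character(snpIds))),
      evaluated = evaluated, bestModel = model, permutation = perm,
      orders = sort(unique(as.integer(orders))))
}

#' @rdname SearchReport-class
#' @export
setMethod("bestModel", "SearchReport", function(x) x@bestModel)

#' @rdname SearchReport-class
#' @export
setMethod("evaluatedModels", "SearchReport", function(x) x@evaluated)

#' @rdname SearchReport-class
#' @export
setMethod("empiricalP", "SearchReport",
          function(x) empiricalP(x@permutation))

setMethod("show", "SearchReport", function(object) {
  cat("SearchReport:", nrow(object@evaluated), "models over",
      length(object@candidateSnps), "SNPs (orders",
      paste(object@orders, collapse = ","), ")\n")
  cat("  best:", paste(snpIds(object@bestModel), collapse = ", "),
      sprintf("t = %.4f, p = %.6g\n", tStatistic(object@bestModel),
              empiricalP(object)))
})

#' Serialize a SearchReport
#'
#' JSON for the report (candidates, best model, permutation summary) and
#' optionally a TSV of every evaluated model.
#'
#' @param report a \linkS4class{SearchReport}.
#' @param path JSON output path.
#' @param tsvPath optional TSV of evaluated models.
#' @export
writeSearchReport <- function(report, path, tsvPath = NULL) {
  perm <- report@permutation
  obj <- list(
    candidate_snps = report@candidateSnps,
    orders = report@orders,
    n_models = nrow(report@evaluated),
    best_model = jsonlite::fromJSON(qmdrModelJson(report@bestModel),
                                    simplifyVector = FALSE),
    permutation = list(observed = perm@observed,
                       n_permutations = perm@nPermutations,
                       empirical_p = perm@empiricalP, seed = perm@seed,
                       note = paste("p-value conditional on upstream",
                                    "screening of the candidate set")))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  if (!is.null(tsvPath))
    utils::write.table(report@evaluated, tsvPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
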