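#' @include permutation.R
NULL

# All unordered pairs of a sorted SNP id vector, in lexicographic order.
.snpPairs <- function(snpIds) {
  s <- sort(snpIds)
  if (length(s) < 2) return(list())
  pairs <- utils::combn(s, 2, simplify = FALSE)
  pairs
}

# Exhaustive best-pair search closure for one gene: returns the max QMDR t
# over all pairs.  Precomputes row indices so repeated permutation calls
# only pay the kernel cost.
.makePairSearch <- function(genotypes, snpIds) {
  g <- dosages(genotypes)
  pairs <- .snpPairs(snpIds)
  idx <- lapply(pairs, function(p) match(p, rownames(g)))
  function(genotypes, y) max(cpp_qmdr_scores(g, as.numeric(y), idx))
}

#' Screen one gene: exhaustive pairwise QMDR with permutation p
#'
#' Evaluates all \eqn{C(m, 2)} SNP pairs mapped to the gene, selects the
#' pair with maximal t (ties: lexicographically smallest pair), and
#' attaches an empirical p-value from a permutation test that re-runs the
#' same exhaustive search on each shuffled phenotype.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param phenotype named numeric vector.
#' @param snpIds SNPs mapped to the gene (>= 2).
#' @param nPermutations permutations for the gene p-value (default 1000).
#' @param seed seed for the permutation stream.
#' @param geneId gene identifier recorded in the result.
#' @return a one-row \link[S4Vectors]{DataFrame} with columns gene_id,
#'   snp_a, snp_b, t, p, n_pairs_tested, n_snps.
#' @export
screenGene <- function(genotypes, phenotype, snpIds, nPermutations = 1000L,
                       seed = 1L, geneId = "gene") {
  if (length(snpIds) < 2) stop("screenGene needs at least 2 SNPs")
  y <- .alignPhenotype(genotypes, phenotype)
  pairs <- .snpPairs(snpIds)
  scores <- .scoreSubsets(genotypes, y, pairs)
  best <- which.max(scores)  # first max = lexicographically smallest pair
  perm <- permutationTest(.makePairSearch(genotypes, snpIds),
                          genotypes, y, nPermutations, seed)
  DataFrame(gene_id = geneId, snp_a = pairs[[best]][1],
            snp_b = pairs[[best]][2], t = scores[best],
            p = empiricalP(perm), n_pairs_tested = length(pairs),
            n_snps = length(snpIds))
}

#' Screen every gene in a SNP-to-gene map
#'
#' One [screenGene()] result per gene with >= 2 mapped SNPs, in
#' deterministic gene_id order.  Genes with fewer mapped SNPs are skipped
#' with a message.  Each gene's permutation stream is seeded from the
#' master seed and its gene id, so adding or removing genes never perturbs
#' the others' p-values.
#'
#' @inheritParams screenGene
#' @param map a \linkS4class{SnpGeneMap}.
#' @param minSnps minimum mapped SNPs for a gene to be screened.
#' @return a \link[S4Vectors]{DataFrame}, one row per screened gene.
#' @export
screenAllGenes <- function(genotypes, phenotype, map, nPermutations = 1000L,
                           seed = 1L, minSnps = 2L) {
  stopifnot(is(map, "SnpGeneMap"))
  if (nrow(mapTable(map)) == 0) stop("the SNP-to-gene map is empty")
  y <- .alignPhenotype(genotypes, phenotype)
  genes <- geneIds(map)
  rows <- lapply(genes, function(gid) {
    snps <- snpsOfGene(map, gid)
    snps <- intersect(snps, rownames(genotypes))
    if (length(snps) < minSnps) {
      message("skipping gene ", gid, ": fewer than ", minSnps,
              " mapped SNPs")
      return(NULL)
    }
    screenGene(genotypes, y, snps, nPermutations,
               seed = .deriveSeed(seed, gid), geneId = gid)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(DataFrame(gene_id = character(), snp_a = character(),
                     snp_b = character(), t = numeric(), p = numeric(),
                     n_pairs_tested = integer(), n_snps = integer()))
  out <- do.call(rbind, rows)
  out[order(out$gene_id), ]
}

#' Select genes passing the screening threshold
#'
#' Keeps genes with empirical p strictly below \code{alpha} (the screening
#' convention "p < alpha") and reports the union of their best-pair SNPs
#' with duplicates collapsed.  Optionally applies Benjamini-Hochberg
#' correction first (off by default: the screen deliberately trades type I
#' for type II error and defers false-positive control to the functional
#' filter).
#'
#' @param results DataFrame from [screenAllGenes()].
#' @param alpha significance level (default 0.001, strict inequality).
#' @param adjust apply BH adjustment before thresholding (default FALSE).
#' @return list with elements \code{genes} (the passing rows) and
#'   \code{snpIds} (sorted unique best-pair SNPs).
#' @export
selectSignificantGenes <- function(results, alpha = 0.001, adjust = FALSE) {
  p <- results$p
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  keep <- !is.na(p) & p < alpha
  genes <- results[keep, ]
  list(genes = genes,
       snpIds = sort(unique(c(genes$snp_a, genes$snp_b))))
}

#' Write Phase I gene results as TSV
#' @param results DataFrame from [screenAllGenes()].
#' @param path output TSV.
#' @export
writeGeneResults <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
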