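#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GenotypeData: a dosage matrix with SNP coordinates
#'
#' Container for a biallelic SNP panel, stored as a
#' \linkS4class{RangedSummarizedExperiment} with one assay \code{"dosage"}
#' (SNPs as rows, samples as columns).  Dosages are minor-allele counts in
#' \{0, 1, 2\} with \code{NA} for missing genotypes.  SNP identifiers and
#' 1-based positions live in \code{rowRanges}; the generating minor allele
#' frequency is kept in \code{rowData(x)$maf} when the object comes from the
#' simulator.
#'
#' @seealso [readGenotypes()], [simulateGenotypes()], [mapSnpsToGenes()]
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

.validGenotypeData <- function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!is.integer(d) && !is.numeric(d))
      msg <- c(msg, "dosage must be numeric")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
      msg <- c(msg, "non-missing dosages must be 0, 1 or 2")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "SNP ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeData", .validGenotypeData)

#' SnpGeneMap: bidirectional SNP-to-gene window assignment
#'
#' One row per (gene, SNP) pair produced by [mapSnpsToGenes()], together
#' with the base-pair distance from the SNP to the gene span (0 when the
#' SNP lies inside the gene).  Both lookup directions are derived from the
#' same table, so they are mutually consistent by construction.
#'
#' @slot table data.frame with columns \code{gene_id}, \code{snp_id},
#'   \code{distance_bp}.
#' @slot windowBp window size (bp) used on each side of the gene span.
#' @export
setClass("SnpGeneMap",
  representation(table = "data.frame", windowBp = "numeric"))

.validSnpGeneMap <- function(object) {
  tb <- object@table
  msg <- character()
  need <- c("gene_id", "snp_id", "distance_bp")
  if (!all(need %in% names(tb)))
    msg <- c(msg, "table needs columns gene_id, snp_id, distance_bp")
  else {
    if (anyDuplicated(tb[c("gene_id", "snp_id")]))
      msg <- c(msg, "duplicate (gene, SNP) pairs")
    if (nrow(tb) && any(tb$distance_bp < 0))
      msg <- c(msg, "distances must be >= 0")
  }
  if (length(object@windowBp) != 1 || object@windowBp < 0)
    msg <- c(msg, "windowBp must be a single non-negative number")
  if (length(msg)) msg else TRUE
}
setValidity("SnpGeneMap", .validSnpGeneMap)

#' CellTable: multilocus genotype cells of a QMDR model
#'
#' The constructive-induction table for one SNP subset: every observed
#' genotype combination (cell) with its sample count and phenotype mean,
#' plus the global phenotype mean over the samples included in the model.
#' Samples with a missing genotype at any subset SNP are excluded.
#'
#' @slot snpIds ordered SNP subset (size 1--4).
#' @slot genotypes integer matrix, one row per cell, one column per SNP.
#' @slot n integer sample count per cell.
#' @slot mean numeric phenotype mean per cell.
#' @slot globalMean mean phenotype over included samples.
#' @slot assignment integer cell row per included sample.
#' @slot phenotype phenotype values of the included samples.
#' @export
setClass("CellTable",
  representation(snpIds = "character", genotypes = "matrix",
                 n = "integer", mean = "numeric",
                 globalMean = "numeric", assignment = "integer",
                 phenotype = "numeric"))

.validCellTable <- function(object) {
  msg <- character()
  if (nrow(object@genotypes) != length(object@n) ||
      length(object@n) != length(object@mean))
    msg <- c(msg, "cell table fields differ in length")
  if (ncol(object@genotypes) != length(object@snpIds))
    msg <- c(msg, "genotype columns must match snpIds")
  if (any(object@n < 1L)) msg <- c(msg, "empty cells must not be stored")
  if (length(object@assignment) != length(object@phenotype))
    msg <- c(msg, "assignment and phenotype must align")
  if (length(msg)) msg else TRUE
}
setValidity("CellTable", .validCellTable)

#' QmdrModel: a fitted QMDR model for one SNP subset
#'
#' High/low cell labels about the global phenotype mean and the Welch
#' two-sample t statistic comparing the two pooled groups.  Degenerate
#' poolings (an empty group or zero pooled spread) carry a score of 0 and
#' \code{degenerate = TRUE}.
#'
#' @slot snpIds ordered SNP subset.
#' @slot cellTable the companion \linkS4class{CellTable}.
#' @slot labels character "HIGH"/"LOW" per cell.
#' @slot tStatistic Welch t of HIGH vs LOW phenotype values.
#' @slot nHigh,nLow group sample counts.
#' @slot degenerate TRUE when the statistic is the 0 sentinel.
#' @slot pValue permutation p-value when attached, else NA.
#' @slot cvStatistic mean 10-fold testing t when fitted with cv = TRUE.
#' @export
setClass("QmdrModel",
  representation(snpIds = "character", cellTable = "CellTable",
                 labels = "character", tStatistic = "numeric",
                 nHigh = "integer", nLow = "integer",
                 degenerate = "logical", pValue = "numeric",
                 cvStatistic = "numeric"))

.validQmdrModel <- function(object) {
  msg <- character()
  ct <- object@cellTable
  if (length(object@labels) != length(ct@n))
    msg <- c(msg, "one label per cell required")
  if (!all(object@labels %in% c("HIGH", "LOW")))
    msg <- c(msg, "labels must be HIGH or LOW")
  if (object@nHigh + object@nLow != length(ct@phenotype))
    msg <- c(msg, "group sizes must sum to the included sample count")
  if (length(msg)) msg else TRUE
}
setValidity("QmdrModel", .validQmdrModel)

#' PermutationResult: empirical significance of a search score
#'
#' @slot observed observed best score.
#' @slot permuted scores from re-running the full search on each permuted
#'   phenotype.
#' @slot empiricalP (r + 1) / (N + 1) with r the number of permuted scores
#'   >= observed (ties counted).
#' @slot nPermutations N.
#' @slot seed master seed used to derive the permutation streams.
#' @export
setClass("PermutationResult",
  representation(observed = "numeric", permuted = "numeric",
                 empiricalP = "numeric", nPermutations = "integer",
                 seed = "integer"))

.validPermutationResult <- function(object) {
  msg <- character()
  N <- object@nPermutations
  if (length(object@permuted) != N)
    msg <- c(msg, "permuted scores must have length nPermutations")
  r <- sum(object@permuted >= object@observed)
  if (N >= 1 && abs(object@empiricalP - (r + 1) / (N + 1)) > 1e-12)
    msg <- c(msg, "empiricalP must equal (r+1)/(N+1)")
  if (length(msg)) msg else TRUE
}
setValidity("PermutationResult", .validPermutationResult)

#' FunctionalNetwork: confidence-weighted undirected gene network
#'
#' An edge list \code{(gene_a, gene_b, confidence)} with confidences in
#' [0, 1], no self-loops, and each unordered pair stored once with
#' \code{gene_a < gene_b} lexicographically.  Stands in for the output of a
#' Bayesian functional-genomics integration service.
#'
#' @slot edges data.frame(gene_a, gene_b, confidence).
#' @export
setClass("FunctionalNetwork", representation(edges = "data.frame"))

.validFunctionalNetwork <- function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("gene_a", "gene_b", "confidence") %in% names(e)))
    msg <- c(msg, "edges need gene_a, gene_b, confidence")
  else if (nrow(e)) {
    if (any(e$confidence < 0 | e$confidence > 1))
      msg <- c(msg, "confidence must lie in [0, 1]")
    if (any(e$gene_a == e$gene_b)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$gene_a > e$gene_b))
      msg <- c(msg, "pairs must be stored with gene_a < gene_b")
    if (anyDuplicated(e[c("gene_a", "gene_b")]))
      msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
}
setValidity("FunctionalNetwork", .validFunctionalNetwork)

#' GeneSets: named gene sets over a gene universe
#'
#' @slot sets named list of character vectors, each a subset of the
#'   universe.
#' @slot universe character vector of all gene ids eligible for
#'   enrichment.
#' @export
setClass("GeneSets",
  representation(sets = "list", universe = "character"))

.validGeneSets <- function(object) {
  msg <- character()
  if (anyDuplicated(object@universe)) msg <- c(msg, "universe has duplicates")
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "sets must be uniquely named")
    outside <- vapply(object@sets,
                      function(s) any(!s %in% object@universe), logical(1))
    if (any(outside))
      msg <- c(msg, paste("sets outside the universe:",
                          paste(names(object@sets)[outside], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}
setValidity("GeneSets", .validGeneSets)

#' SearchReport: exhaustive multi-way QMDR search result
#'
#' @slot candidateSnps ordered candidate SNP set.
#' @slot evaluated data.frame of every evaluated subset (columns
#'   \code{snp_ids} (slash-separated), \code{order}, \code{t}).
#' @slot bestModel the winning \linkS4class{QmdrModel} (permutation p
#'   attached).
#' @slot permutation the \linkS4class{PermutationResult} for the full
#'   search.
#' @slot orders model orders searched.
#' @export
setClass("SearchReport",
  representation(candidateSnps = "character", evaluated = "data.frame",
                 bestModel = "QmdrModel", permutation = "PermutationResult",
                 orders = "integer"))

#' InteractionNetwork: entropy-based SNP interaction decomposition
#'
#' All quantities are in bits (log base 2) and computed against the trait
#' binarized at the global phenotype mean: node weights are single-SNP
#' mutual informations with the trait, edges the pairwise information gain
#' (synergy when positive, redundancy when negative), triangles the pure
#' three-way information gain, and \code{redundancy} the inter-SNP mutual
#' information (a linkage-disequilibrium measure).
#'
#' @slot nodes data.frame(snp_id, main_effect_bits).
#' @slot edges data.frame(snp_a, snp_b, synergy_bits, class).
#' @slot triangles data.frame(snp_a, snp_b, snp_c, synergy_bits).
#' @slot redundancy data.frame(snp_a, snp_b, mi_bits).
#' @slot traitEntropy entropy of the binarized trait, bits.
#' @slot epsilon |IG| below which a pair is labelled "independent".
#' @export
setClass("InteractionNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 triangles = "data.frame", redundancy = "data.frame",
                 traitEntropy = "numeric", epsilon = "numeric"))

#' EffectSpec: one planted phenotype effect
#'
#' Additive effects add \code{effectSize} times the standardized dosage.
#' Epistatic effects add a cell-pattern offset (default: a parity
#' "checkerboard") that is orthogonalized against all single-SNP margins
#' under the generating genotype frequencies and scaled to a standard
#' deviation of \code{effectSize}, so the planted interaction carries no
#' marginal effect.
#'
#' @slot kind one of "additive", "epistatic_pair", "epistatic_triple".
#' @slot snpIds the SNPs carrying the effect (1, 2 or 3 of them).
#' @slot effectSize effect magnitude in phenotype-noise SD units.
#' @slot pattern optional numeric array of cell offsets (3^k values); NULL
#'   selects the parity checkerboard.
#' @export
setClass("EffectSpec",
  representation(kind = "character", snpIds = "character",
                 effectSize = "numeric", pattern = "numericOrNULL"))

.validEffectSpec <- function(object) {
  msg <- character()
  kinds <- c(additive = 1L, epistatic_pair = 2L, epistatic_triple = 3L)
  if (!object@kind %in% names(kinds))
    msg <- c(msg, "unknown effect kind")
  else if (length(object@snpIds) != kinds[[object@kind]])
    msg <- c(msg, sprintf("%s needs %d SNP id(s)", object@kind,
                          kinds[[object@kind]]))
  if (length(object@effectSize) != 1 || !is.finite(object@effectSize))
    msg <- c(msg, "effectSize must be a single finite number")
  if (!is.null(object@pattern) && object@kind != "additive" &&
      length(object@pattern) != 3^length(object@snpIds))
    msg <- c(msg, "pattern must have 3^k entries")
  if (length(msg)) msg else TRUE
}
setValidity("EffectSpec", .validEffectSpec)

#' SimulationConfig: full recipe for one synthetic dataset
#'
#' The seed fully determines every generated object (genotypes, phenotype,
#' annotations, functional fixtures).
#'
#' @slot nSamples number of samples.
#' @slot nSnps number of SNPs.
#' @slot mafRange minor allele frequency range, a subset of (0, 0.5].
#' @slot snpSpacingBp distance between consecutive SNP positions.
#' @slot chromosome chromosome name for the default geometry.
#' @slot genes list describing gene geometry: \code{n}, \code{spanBp},
#'   \code{spacingBp}, and optionally \code{clusters}, a list of integer
#'   vectors of gene indices to be placed inside one shared window.
#' @slot effects list of \linkS4class{EffectSpec}.
#' @slot noiseSd Gaussian noise SD (> 0).
#' @slot ldBlocks optional list(blocks = list of SNP index vectors,
#'   rho = latent allele correlation); empty means linkage equilibrium.
#' @slot seed master seed.
#' @export
setClass("SimulationConfig",
  representation(nSamples = "integer", nSnps = "integer",
                 mafRange = "numeric", snpSpacingBp = "integer",
                 chromosome = "character", genes = "list",
                 effects = "list", noiseSd = "numeric",
                 ldBlocks = "list", seed = "integer"))

.validSimulationConfig <- function(object) {
  msg <- character()
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  mr <- object@mafRange
  if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    msg <- c(msg, "mafRange must satisfy 0 < low <= high <= 0.5")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  bad <- vapply(object@effects, function(e) !is(e, "EffectSpec"), logical(1))
  if (length(bad) && any(bad)) msg <- c(msg, "effects must be EffectSpec objects")
  if (length(msg)) msg else TRUE
}
setValidity("SimulationConfig", .validSimulationConfig)
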