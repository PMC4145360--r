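#' @include AllClasses.R
NULL

#' @rdname GenotypeData-class
#' @param x a GenotypeData object.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-class
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname GenotypeData-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SnpGeneMap-class
#' @param x a SnpGeneMap object.
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))

#' @rdname SnpGeneMap-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname SnpGeneMap-class
#' @param gene a gene id.
#' @export
setGeneric("snpsOfGene", function(x, gene) standardGeneric("snpsOfGene"))

#' @rdname SnpGeneMap-class
#' @param snp a SNP id.
#' @export
setGeneric("genesOfSnp", function(x, snp) standardGeneric("genesOfSnp"))

#' @rdname QmdrModel-class
#' @param x a QmdrModel object.
#' @export
setGeneric("tStatistic", function(x) standardGeneric("tStatistic"))

#' @rdname QmdrModel-class
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname QmdrModel-class
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname PermutationResult-class
#' @param x an object carrying an empirical p-value.
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))

#' @rdname FunctionalNetwork-class
#' @param x a FunctionalNetwork object.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname FunctionalNetwork-class
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

#' @rdname GeneSets-class
#' @param x a GeneSets object.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSets-class
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname SearchReport-class
#' @param x a SearchReport object.
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))

#' @rdname SearchReport-class
#' @export
setGeneric("evaluatedModels", function(x) standardGeneric("evaluatedModels"))
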