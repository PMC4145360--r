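#' @include simulate.R
NULL

.pipelineDefaults <- function() {
  list(window_bp = 500000L, n_permutations = 1000L, alpha1 = 0.001,
       min_confidence = 0.9, alpha2 = 0.05, max_added = 20L,
       orders = c(2L, 3L, 4L), combine = "and", epsilon = 0.005)
}

.md5 <- function(paths) unname(tools::md5sum(paths))

#' Run the full two-phase pipeline
#'
#' Stages: (optional) simulate the planted demonstration dataset, map
#' SNPs to genes, Phase I exhaustive pairwise screening, functional
#' filtering with enrichment, exhaustive multi-way search, and the entropy
#' network — writing fixed-name outputs under \code{outDir} and a JSON run
#' manifest with input/output digests.  Thresholds default to the
#' pipeline's conventional values (window 500 kb, 1000 permutations,
#' alpha 0.001, confidence 0.9, enrichment alpha 0.05, up to 20 added
#' genes, orders 2--4).  Re-running with the same config and seed
#' reproduces identical output digests.
#'
#' @param config either a YAML file path or a list.  Recognized entries:
#'   \code{seed}; \code{simulate} (logical, or a list of arguments to
#'   [simulateStudyFixture()]); input paths \code{genotypes} (dosage TSV),
#'   \code{map_file}, \code{phenotype}, \code{genes} (BED),
#'   \code{network}, \code{gene_sets} (GMT) when not simulating;
#'   \code{stages} (subset of map, phase1, filter, phase2, entropy);
#'   and any of the threshold names window_bp, n_permutations, alpha1,
#'   min_confidence, alpha2, max_added, orders, combine, epsilon.
#' @param outDir output directory (created if needed).
#' @return the run manifest, invisibly (also written as manifest.json).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  opts <- utils::modifyList(.pipelineDefaults(), config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (is.null(config$stages))
    c("map", "phase1", "filter", "phase2", "entropy") else config$stages
  manifest <- list(tool = "epiQMDR",
                   version = as.character(utils::packageVersion("epiQMDR")),
                   seed = seed,
                   parameters = opts[names(.pipelineDefaults())],
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  outputs <- character()
  mark <- function(stage, files, counts = NULL) {
    manifest$stages[[stage]] <<- list(
      status = "done", outputs = as.list(stats::setNames(.md5(files),
                                                         basename(files))),
      counts = counts)
    outputs <<- c(outputs, files)
  }

  if (isTRUE(config$simulate) || is.list(config$simulate)) {
    args <- if (is.list(config$simulate)) config$simulate else list()
    args$seed <- seed
    fx <- do.call(simulateStudyFixture, args)
    genoPaths <- writeGenotypes(fx$genotypes, file.path(outDir, "genotypes"))
    phenoPath <- writePhenotype(fx$phenotype,
                                file.path(outDir, "phenotype.tsv"))
    bedPath <- writeGeneAnnotation(fx$genes, file.path(outDir, "genes.bed"))
    netPath <- writeFunctionalNetwork(fx$network,
                                      file.path(outDir, "network.tsv"))
    gmtPath <- writeGmt(fx$geneSets, file.path(outDir, "gene_sets.gmt"))
    truthPath <- file.path(outDir, "truth.json")
    writeLines(jsonlite::toJSON(
      fx$truth[c("significantGenes", "moduleGenes", "satellites",
                 "headlinePair", "mainEffectSnp", "candidateSnps",
                 "uniqueSignificantSnps")],
      auto_unbox = FALSE), truthPath)
    mark("simulate", c(genoPaths, phenoPath, bedPath, netPath, gmtPath,
                       truthPath))
    genotypes <- fx$genotypes
    phenotype <- fx$phenotype
    genes <- fx$genes
    network <- fx$network
    sets <- fx$geneSets
  } else {
    need <- c("genotypes", "phenotype")
    miss <- need[!vapply(need, function(x) !is.null(config[[x]]),
                         logical(1))]
    if (length(miss))
      stop("missing input for stage map/phase1: ",
           paste(miss, collapse = ", "))
    genotypes <- readGenotypes(config$genotypes, format = "dosage",
                               mapPath = config$map_file)
    phenotype <- readPhenotype(config$phenotype)
    genes <- if (!is.null(config$genes)) readGeneAnnotation(config$genes)
    network <- if (!is.null(config$network))
      readFunctionalNetwork(config$network)
    sets <- if (!is.null(config$gene_sets)) readGmt(config$gene_sets)
  }

  map <- NULL; phase1 <- NULL; selected <- NULL; cand <- NULL
  if ("map" %in% stages) {
    if (is.null(genes)) stop("stage map: gene annotation input is missing")
    map <- mapSnpsToGenes(genotypes, genes, opts$window_bp)
    p <- writeSnpGeneMap(map, file.path(outDir, "snp_gene_map.tsv"))
    mark("map", p, counts = list(genes = length(geneIds(map)),
                                 snps = length(snpIds(map))))
  }
  if ("phase1" %in% stages) {
    if (is.null(map)) stop("stage phase1: the map stage must run first")
    phase1 <- screenAllGenes(genotypes, phenotype, map,
                             nPermutations = opts$n_permutations,
                             seed = .deriveSeed(seed, "phase1"))
    selected <- selectSignificantGenes(phase1, opts$alpha1)
    p <- writeGeneResults(phase1, file.path(outDir, "phase1_genes.tsv"))
    message(sprintf("phase1: %d genes screened -> %d significant (%d SNPs)",
                    nrow(phase1), nrow(selected$genes),
                    length(selected$snpIds)))
    mark("phase1", p,
         counts = list(screened = nrow(phase1),
                       significant = nrow(selected$genes),
                       unique_snps = length(selected$snpIds)))
  }
  if ("filter" %in% stages) {
    if (is.null(selected)) stop("stage filter: phase1 must run first")
    if (is.null(network) || is.null(sets))
      stop("stage filter: network/gene_sets inputs are missing")
    cand <- selectCandidates(selected$genes, network, sets,
                             minConfidence = opts$min_confidence,
                             alpha = opts$alpha2,
                             maxAdded = opts$max_added,
                             combine = opts$combine)
    cpath <- file.path(outDir, "candidates.tsv")
    utils::write.table(
      data.frame(gene_id = cand$genes,
                 source = ifelse(cand$genes %in% cand$keptPhase1,
                                 "phase1", "network_added")),
      cpath, sep = "\t", quote = FALSE, row.names = FALSE)
    epath <- file.path(outDir, "enrichment.tsv")
    utils::write.table(cand$enrichment, epath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    message(sprintf(
      "filter: %d genes in -> %d kept + %d added; %d candidate SNPs",
      nrow(selected$genes), length(cand$keptPhase1),
      length(cand$genes) - length(cand$keptPhase1), length(cand$snpIds)))
    mark("filter", c(cpath, epath),
         counts = list(genes_in = nrow(selected$genes),
                       kept = length(cand$keptPhase1),
                       total = length(cand$genes),
                       snps = length(cand$snpIds)))
  }
  report <- NULL
  if ("phase2" %in% stages) {
    if (is.null(cand)) stop("stage phase2: filter must run first")
    report <- searchBestModel(genotypes, phenotype, cand$snpIds,
                              orders = opts$orders,
                              nPermutations = opts$n_permutations,
                              seed = .deriveSeed(seed, "phase2"))
    p1 <- file.path(outDir, "best_model.json")
    p2 <- file.path(outDir, "evaluated_models.tsv")
    writeSearchReport(report, p1, p2)
    mark("phase2", c(p1, p2),
         counts = list(models = nrow(evaluatedModels(report))))
  }
  if ("entropy" %in% stages) {
    if (is.null(cand)) stop("stage entropy: filter must run first")
    net <- buildInteractionNetwork(genotypes, phenotype, cand$snpIds,
                                   epsilon = opts$epsilon)
    p1 <- file.path(outDir, "interaction_network.json")
    p2 <- file.path(outDir, "interaction_network.graphml")
    exportInteractionJson(net, p1)
    exportGraphML(net, p2)
    mark("entropy", c(p1, p2),
         counts = list(edges = nrow(net@edges),
                       triangles = nrow(net@triangles)))
  }
  skipped <- setdiff(c("map", "phase1", "filter", "phase2", "entropy"),
                     stages)
  for (s in skipped) manifest$stages[[s]] <- list(status = "skipped")
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(outDir, "manifest.json"))
  invisible(manifest)
}
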