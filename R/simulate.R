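#' @include entropy.R
NULL

#' @rdname EffectSpec-class
#' @param kind "additive", "epistatic_pair" or "epistatic_triple".
#' @param snpIds SNPs carrying the effect.
#' @param effectSize magnitude in phenotype-noise SD units.
#' @param pattern optional cell-offset array (3^k values, cells in base-3
#'   order); NULL selects the parity checkerboard.
#' @export
EffectSpec <- function(kind, snpIds, effectSize, pattern = NULL) {
  new("EffectSpec", kind = kind, snpIds = as.character(snpIds),
      effectSize = as.numeric(effectSize), pattern = pattern)
}

#' @rdname SimulationConfig-class
#' @param nSamples,nSnps,mafRange,snpSpacingBp,chromosome,genes,effects,noiseSd,ldBlocks,seed
#'   see the class slots.
#' @export
SimulationConfig <- function(nSamples, nSnps, mafRange = c(0.05, 0.5),
                             snpSpacingBp = 5000L, chromosome = "1",
                             genes = list(), effects = list(),
                             noiseSd = 1, ldBlocks = list(), seed = 1L) {
  new("SimulationConfig", nSamples = as.integer(nSamples),
      nSnps = as.integer(nSnps), mafRange = as.numeric(mafRange),
      snpSpacingBp = as.integer(snpSpacingBp),
      chromosome = as.character(chromosome), genes = genes,
      effects = effects, noiseSd = as.numeric(noiseSd),
      ldBlocks = ldBlocks, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSamples, "samples,", object@nSnps,
      "SNPs, MAF U(", object@mafRange[1], ",", object@mafRange[2],
      "),", length(object@effects), "effects, seed", object@seed, "\n")
})

# Default deterministic SNP coordinates: evenly spaced on one chromosome.
.configSnpInfo <- function(config) {
  data.frame(snp_id = sprintf("rs%05d", seq_len(config@nSnps)),
             chromosome = config@chromosome,
             position = as.integer(seq_len(config@nSnps)) *
               config@snpSpacingBp,
             stringsAsFactors = FALSE)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each SNP draws its minor allele frequency uniformly from
#' \code{mafRange}; genotypes are minor-allele counts from two independent
#' allele draws, i.e. Hardy-Weinberg proportions (q^2, 2pq, p^2 for codes
#' 2/1/0).  SNPs are in linkage equilibrium unless \code{ldBlocks} is set,
#' in which case alleles within a block share a latent Gaussian factor
#' with correlation \code{rho} (a Gaussian-copula haplotype model).  The
#' seed fully determines the output; generating MAFs are stored in
#' \code{rowData(x)$maf}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{GenotypeData}.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(.deriveSeed(config@seed, "genotypes"))
  n <- config@nSamples
  m <- config@nSnps
  mafs <- stats::runif(m, config@mafRange[1], config@mafRange[2])
  inLd <- integer(0)
  d <- matrix(NA_integer_, nrow = m, ncol = n)
  if (length(config@ldBlocks)) {
    rho <- config@ldBlocks$rho
    for (block in config@ldBlocks$blocks) {
      inLd <- c(inLd, block)
      for (hap in 1:2) {
        z0 <- stats::rnorm(n)
        for (j in block) {
          z <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(n)
          al <- as.integer(z < stats::qnorm(mafs[j]))
          d[j, ] <- if (hap == 1) al else d[j, ] + al
        }
      }
    }
  }
  for (j in setdiff(seq_len(m), inLd))
    d[j, ] <- as.integer(stats::rbinom(n, 1L, mafs[j]) +
                         stats::rbinom(n, 1L, mafs[j]))
  info <- .configSnpInfo(config)
  rownames(d) <- info$snp_id
  colnames(d) <- sprintf("S%05d", seq_len(n))
  x <- GenotypeData(d, info)
  SummarizedExperiment::rowData(x)$maf <- mafs
  x
}

# HWE cell probabilities for dosage codes 0/1/2 given the minor allele
# frequency q.
.hweProbs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

# Orthogonalize a k-way cell pattern against all single-SNP margins under
# independent genotype distributions (probs: list of length-3 vectors) and
# scale it to unit standard deviation under the cell distribution.  The
# resulting offsets carry no marginal (single-SNP) expected effect.
.orthogonalizePattern <- function(pattern, probs) {
  k <- length(probs)
  f <- array(pattern, dim = rep(3L, k))
  w <- Reduce(outer, probs)
  mu <- sum(w * f)
  centred <- f - mu
  for (j in seq_len(k)) {
    marg <- apply(w * centred, j, sum) / apply(w, j, sum)
    expand <- slice.index(f, j)
    centred <- centred - array(marg[expand], dim = dim(f))
  }
  s <- sqrt(sum(w * centred^2) - sum(w * centred)^2)
  if (s <= 0) stop("degenerate epistatic pattern")
  centred / s
}

# Parity checkerboard: +1 when the summed dosage over the subset is even,
# -1 when odd.  After orthogonalization this is a purely epistatic,
# zero-marginal pattern at any MAF.
.checkerboardPattern <- function(k) {
  cells <- as.matrix(expand.grid(rep(list(0:2), k)))
  (-1)^rowSums(cells)
}

# Generating genotype distributions for the effect SNPs: HWE at the stored
# generating MAF when available, else the empirical cell frequencies.
.effectProbs <- function(genotypes, snps) {
  maf <- SummarizedExperiment::rowData(genotypes)$maf
  lapply(snps, function(s) {
    i <- match(s, rownames(genotypes))
    if (!is.null(maf) && !is.na(maf[i])) .hweProbs(maf[i])
    else {
      g <- dosages(genotypes)[i, ]
      as.numeric(tabulate(g + 1L, 3L) / sum(!is.na(g)))
    }
  })
}

#' Simulate a quantitative phenotype with planted architecture
#'
#' \eqn{y = \sum \mathrm{additive} + \sum \mathrm{epistatic~offsets}
#' + N(0, \mathrm{noiseSd}^2)}.  Additive effects contribute
#' \code{effectSize} times the dosage standardized under its generating
#' MAF (mean 2q, variance 2q(1-q)).  Epistatic effects contribute a
#' cell-pattern offset orthogonalized against all single-SNP margins and
#' scaled to SD \code{effectSize}, so the interaction is purely epistatic:
#' marginal single-SNP tests stay null while the joint model carries the
#' signal.  With an empty effect list the phenotype is pure noise (the
#' null model).
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param effects list of \linkS4class{EffectSpec}.
#' @param noiseSd Gaussian noise SD (> 0).
#' @param seed seed for the noise draw.
#' @return named numeric phenotype over the genotyped samples.
#' @export
simulatePhenotype <- function(genotypes, effects = list(), noiseSd = 1,
                              seed = 1L) {
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  set.seed(.deriveSeed(seed, "phenotype"))
  n <- ncol(genotypes)
  y <- stats::rnorm(n, 0, noiseSd)
  d <- dosages(genotypes)
  for (e in effects) {
    stopifnot(is(e, "EffectSpec"))
    missing <- setdiff(e@snpIds, rownames(d))
    if (length(missing))
      stop("effect SNPs absent from the panel: ",
           paste(missing, collapse = ", "))
    if (e@kind == "additive") {
      probs <- .effectProbs(genotypes, e@snpIds)[[1]]
      mu <- sum(probs * 0:2)
      sd <- sqrt(sum(probs * (0:2)^2) - mu^2)
      g <- d[e@snpIds, ]
      z <- (g - mu) / sd
      z[is.na(z)] <- 0
      y <- y + e@effectSize * z
    } else {
      k <- length(e@snpIds)
      pat <- if (is.null(e@pattern)) .checkerboardPattern(k) else e@pattern
      probs <- .effectProbs(genotypes, e@snpIds)
      f <- .orthogonalizePattern(pat, probs) * e@effectSize
      g <- d[e@snpIds, , drop = FALSE]
      idx <- colSums(g * 3^(0:(k - 1))) + 1L  # base-3 cell, NA-propagating
      off <- f[idx]
      off[is.na(off)] <- 0
      y <- y + off
    }
  }
  stats::setNames(y, colnames(genotypes))
}

#' Generate gene annotations with a known SNP-to-gene truth map
#'
#' Places \code{config@genes$n} genes of span \code{spanBp} every
#' \code{spacingBp} bp along the chromosome.  Gene indices listed together
#' in \code{config@genes$clusters} are placed 60 kb apart so their mapping
#' windows overlap (emulating gene clusters whose windows share SNPs).
#' The expected SNP-to-gene map for the configured window is computed by a
#' direct interval scan and returned alongside, for use as ground truth in
#' tests.
#'
#' @param config a \linkS4class{SimulationConfig} whose \code{genes} list
#'   has \code{n}, and optionally \code{spanBp} (default 10000),
#'   \code{spacingBp} (default 2e6), \code{clusters} (list of integer
#'   vectors) and \code{windowBp} (default 500000).
#' @return list(genes = named GRanges, truth = \linkS4class{SnpGeneMap}).
#' @export
generateAnnotation <- function(config) {
  gspec <- config@genes
  nGenes <- gspec$n
  if (is.null(nGenes) || nGenes < 1) stop("config@genes$n is required")
  spanBp <- if (is.null(gspec$spanBp)) 10000L else gspec$spanBp
  spacingBp <- if (is.null(gspec$spacingBp)) 2000000L else gspec$spacingBp
  windowBp <- if (is.null(gspec$windowBp)) 500000L else gspec$windowBp
  clusters <- if (is.null(gspec$clusters)) list() else gspec$clusters
  start <- numeric(nGenes)
  base <- vapply(seq_len(nGenes), function(i) i * spacingBp, numeric(1))
  placed <- rep(FALSE, nGenes)
  for (cl in clusters) {
    anchor <- base[cl[1]]
    start[cl] <- anchor + (seq_along(cl) - 1) * 60000
    placed[cl] <- TRUE
  }
  start[!placed] <- base[!placed]
  genes <- GRanges(config@chromosome,
                   IRanges(start = pmax(1, start),
                           end = pmax(1, start) + spanBp - 1))
  names(genes) <- sprintf("G%03d", seq_len(nGenes))
  snps <- .configSnpInfo(config)
  truth <- .bruteForceMap(snps, genes, windowBp)
  list(genes = GenomicRanges::sort(genes, ignore.strand = TRUE),
       truth = truth)
}

# Direct interval scan: SNP maps to gene iff same chromosome and
# gene_start - window <= pos <= gene_end + window (1-based inclusive).
.bruteForceMap <- function(snpInfo, genes, windowBp) {
  rows <- list()
  gs <- GenomicRanges::start(genes)
  ge <- GenomicRanges::end(genes)
  gc <- as.character(seqnames(genes))
  for (i in seq_along(genes)) {
    hit <- snpInfo$chromosome == gc[i] &
      snpInfo$position >= gs[i] - windowBp &
      snpInfo$position <= ge[i] + windowBp
    if (any(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = names(genes)[i], snp_id = snpInfo$snp_id[hit],
        distance_bp = as.integer(pmax(0, gs[i] - snpInfo$position[hit],
                                      snpInfo$position[hit] - ge[i])),
        stringsAsFactors = FALSE)
  }
  tb <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), snp_id = character(),
               distance_bp = integer())
  tb <- tb[order(tb$gene_id, tb$snp_id), , drop = FALSE]
  rownames(tb) <- NULL
  new("SnpGeneMap", table = tb, windowBp = as.numeric(windowBp))
}

#' Generate functional-network and gene-set fixtures with a planted module
#'
#' Module genes receive mutual edges with confidence in [0.9, 0.99] and
#' share one gene set; each satellite gene is connected to two module
#' genes at the same confidence.  Background edges among all genes get
#' confidences in [0.2, 0.89] (below the conventional 0.9 filter) and
#' background sets are random draws from the universe.  Identical seeds
#' give identical fixtures.
#'
#' @param geneIds all annotated gene ids (the candidates' universe,
#'   possibly plus background genes).
#' @param plantedModule genes forming the high-confidence module.
#' @param satellites genes attached to the module at high confidence but
#'   absent from the input gene list.
#' @param seed seed.
#' @param nBackgroundSets number of random decoy gene sets.
#' @param nBackgroundEdges number of random low-confidence edges.
#' @return list(network = \linkS4class{FunctionalNetwork},
#'   sets = \linkS4class{GeneSets}).
#' @export
generateFunctionalFixtures <- function(geneIds, plantedModule,
                                       satellites = character(),
                                       seed = 1L, nBackgroundSets = 5L,
                                       nBackgroundEdges = 40L) {
  if (!all(plantedModule %in% geneIds))
    stop("plantedModule must be a subset of geneIds")
  set.seed(.deriveSeed(seed, "functional"))
  allGenes <- sort(unique(c(geneIds, satellites)))
  edges <- list()
  if (length(plantedModule) >= 2) {
    pm <- utils::combn(sort(plantedModule), 2)
    edges[[1]] <- data.frame(gene_a = pm[1, ], gene_b = pm[2, ],
                             confidence = stats::runif(ncol(pm), 0.9, 0.99),
                             stringsAsFactors = FALSE)
  }
  for (s in satellites) {
    anchors <- sample(plantedModule, min(2L, length(plantedModule)))
    edges[[length(edges) + 1L]] <- data.frame(
      gene_a = pmin(s, anchors), gene_b = pmax(s, anchors),
      confidence = stats::runif(length(anchors), 0.9, 0.99),
      stringsAsFactors = FALSE)
  }
  if (nBackgroundEdges > 0 && length(allGenes) >= 2) {
    a <- sample(allGenes, nBackgroundEdges, replace = TRUE)
    b <- sample(allGenes, nBackgroundEdges, replace = TRUE)
    keep <- a != b
    edges[[length(edges) + 1L]] <- data.frame(
      gene_a = pmin(a[keep], b[keep]), gene_b = pmax(a[keep], b[keep]),
      confidence = stats::runif(sum(keep), 0.2, 0.89),
      stringsAsFactors = FALSE)
  }
  net <- FunctionalNetwork(do.call(rbind, edges))
  sets <- list(planted_module = sort(plantedModule))
  for (i in seq_len(nBackgroundSets)) {
    size <- sample(8:15, 1)
    sets[[sprintf("background_set_%02d", i)]] <-
      sort(sample(allGenes, min(size, length(allGenes))))
  }
  list(network = net, sets = GeneSets(sets, universe = allGenes))
}

# ---- the end-to-end planted study fixture ---------------------------------

#' Simulate the full planted two-phase study fixture
#'
#' A seeded dataset shaped like a complete pipeline run: 28 annotated
#' genes with two mapped SNPs each, of which 20 carry planted effects (a
#' 2-gene and a 3-gene cluster share their SNP pair through overlapping
#' windows, so the 20 significant genes span 34 unique SNPs); a 6-gene
#' functional module (the two clustered genes plus four solo genes)
#' carrying 10 unique SNPs, with 4 high-confidence satellite genes; a
#' strong purely epistatic pair inside the module, a SNP with an
#' independent additive main effect, moderate background interactions for
#' the remaining planted genes, and 8 null genes.  The default study
#' conditions are 2000 samples, noise SD 1, MAF U(0.2, 0.4), background
#' epistatic size 0.7, headline pair 2.0 and additive SNP 1.0 noise-SD
#' units; the methods vignette motivates these sizes.
#'
#' @param seed master seed.
#' @param nSamples samples (default 2000).
#' @param backgroundEffect,headlineEffect,mainEffect effect sizes in
#'   noise-SD units.
#' @return list with genotypes, phenotype, genes (GRanges), network,
#'   geneSets, config, and truth (planted ground truth: module genes,
#'   satellites, significant genes, headline pair, main-effect SNP,
#'   expected candidate SNPs, expected map).
#' @export
simulateStudyFixture <- function(seed = 1L, nSamples = 2000L,
                                 backgroundEffect = 0.7,
                                 headlineEffect = 2.0, mainEffect = 1.0) {
  nGenes <- 28L
  cluster1 <- c(1L, 2L)        # module pair sharing one SNP pair
  cluster2 <- c(7L, 8L, 9L)    # non-module trio sharing one SNP pair
  moduleIdx <- 1:6
  effectIdx <- 1:20
  geneNames <- sprintf("G%03d", seq_len(nGenes))
  spacingBp <- 2000000L
  spanBp <- 10000L
  # gene starts: clusters 60 kb apart inside one window, others isolated
  start <- seq_len(nGenes) * spacingBp
  start[cluster1] <- start[cluster1[1]] + (seq_along(cluster1) - 1) * 60000
  start[cluster2] <- start[cluster2[1]] + (seq_along(cluster2) - 1) * 60000
  genes <- GRanges("1", IRanges(start = start, end = start + spanBp - 1))
  names(genes) <- geneNames

  # SNP placement: clusters get 2 SNPs in the inter-gene gaps (mapping to
  # every cluster member), solo genes 2 SNPs inside the gene body.
  snpPos <- list()
  snpGene <- list()   # per-SNP list of carrying genes (construction truth)
  addSnp <- function(pos, carriers) {
    snpPos[[length(snpPos) + 1L]] <<- pos
    snpGene[[length(snpGene) + 1L]] <<- carriers
  }
  addSnp(start[cluster1[1]] + 25000, geneNames[cluster1])
  addSnp(start[cluster1[1]] + 35000, geneNames[cluster1])
  addSnp(start[cluster2[1]] + 25000, geneNames[cluster2])
  addSnp(start[cluster2[1]] + 95000, geneNames[cluster2])
  solo <- setdiff(seq_len(nGenes), c(cluster1, cluster2))
  for (i in solo) {
    addSnp(start[i] + 2000, geneNames[i])
    addSnp(start[i] + 7000, geneNames[i])
  }
  m <- length(snpPos)
  snpIds <- sprintf("rs%05d", seq_len(m))
  snpInfo <- data.frame(snp_id = snpIds, chromosome = "1",
                        position = as.integer(unlist(snpPos)),
                        stringsAsFactors = FALSE)
  snpsOf <- function(gene) snpIds[vapply(snpGene, function(x)
    gene %in% x, logical(1))]

  config <- SimulationConfig(nSamples = nSamples, nSnps = m,
                             mafRange = c(0.2, 0.4), noiseSd = 1,
                             seed = seed)
  set.seed(.deriveSeed(seed, "fixture-genotypes"))
  mafs <- stats::runif(m, 0.2, 0.4)
  d <- matrix(
    as.integer(stats::rbinom(m * nSamples, 1L, rep(mafs, nSamples)) +
               stats::rbinom(m * nSamples, 1L, rep(mafs, nSamples))),
    nrow = m)
  rownames(d) <- snpIds
  colnames(d) <- sprintf("S%05d", seq_len(nSamples))
  genotypes <- GenotypeData(d, snpInfo)
  SummarizedExperiment::rowData(genotypes)$maf <- mafs

  headlinePair <- snpsOf("G003")
  mainSnp <- snpsOf("G004")[1]
  effects <- list(
    EffectSpec("epistatic_pair", snpsOf("G001"), backgroundEffect),
    EffectSpec("epistatic_pair", headlinePair, headlineEffect),
    EffectSpec("additive", mainSnp, mainEffect),
    EffectSpec("epistatic_pair", snpsOf("G007"), backgroundEffect))
  for (i in setdiff(effectIdx, c(cluster1, cluster2, 3L, 4L)))
    effects[[length(effects) + 1L]] <-
      EffectSpec("epistatic_pair", snpsOf(geneNames[i]), backgroundEffect)
  phenotype <- simulatePhenotype(genotypes, effects, noiseSd = 1,
                                 seed = .deriveSeed(seed, "fixture-trait"))

  satellites <- sprintf("SAT%02d", 1:4)
  background <- sprintf("BG%03d", 1:30)
  fx <- generateFunctionalFixtures(
    geneIds = c(geneNames, background),
    plantedModule = geneNames[moduleIdx], satellites = satellites,
    seed = .deriveSeed(seed, "fixture-functional"))

  moduleGenes <- geneNames[moduleIdx]
  truth <- list(
    significantGenes = geneNames[effectIdx],
    moduleGenes = moduleGenes,
    satellites = satellites,
    headlinePair = headlinePair,
    mainEffectSnp = mainSnp,
    candidateSnps = sort(unique(unlist(lapply(moduleGenes, snpsOf)))),
    uniqueSignificantSnps =
      sort(unique(unlist(lapply(geneNames[effectIdx], snpsOf)))),
    expectedMap = .bruteForceMap(snpInfo, genes, 500000L),
    effects = effects)
  list(genotypes = genotypes, phenotype = phenotype,
       genes = GenomicRanges::sort(genes, ignore.strand = TRUE),
       network = fx$network, geneSets = fx$sets, config = config,
       truth = truth)
}
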