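test_that("genotypes follow Hardy-Weinberg proportions and are seeded", {
  cfg <- SimulationConfig(nSamples = 10000, nSnps = 3,
                          mafRange = c(0.5, 0.5), seed = 11)
  g <- simulateGenotypes(cfg)
  d <- dosages(g)
  # chi-square GOF against 0.25/0.50/0.25 at MAF 0.5
  for (j in 1:3) {
    obs <- tabulate(d[j, ] + 1L, 3L)
    chi <- suppressWarnings(stats::chisq.test(obs, p = c(1, 2, 1) / 4))
    expect_gt(chi$p.value, 0.01)
  }
  # bitwise determinism
  g2 <- simulateGenotypes(cfg)
  expect_identical(dosages(g2), d)
  # stored generating MAFs
  expect_equal(unname(SummarizedExperiment::rowData(g)$maf), rep(0.5, 3))
  expect_error(SimulationConfig(10, 2, mafRange = c(0, 0.6)), "mafRange")
})

test_that("independent SNPs show no mutual information; LD blocks do", {
  cfg <- SimulationConfig(nSamples = 10000, nSnps = 2,
                          mafRange = c(0.3, 0.3), seed = 12)
  g <- simulateGenotypes(cfg)
  d <- dosages(g)
  expect_lt(mutualInformation(d[1, ], d[2, ]), 0.005)
  cfgLd <- SimulationConfig(nSamples = 5000, nSnps = 2,
                            mafRange = c(0.3, 0.3), seed = 12,
                            ldBlocks = list(blocks = list(1:2), rho = 0.9))
  gLd <- simulateGenotypes(cfgLd)
  dLd <- dosages(gLd)
  expect_gt(mutualInformation(dLd[1, ], dLd[2, ]), 0.1)
  expect_gt(cor(dLd[1, ], dLd[2, ]), 0.5)
})

test_that("the null phenotype model is pure noise", {
  cfg <- SimulationConfig(nSamples = 4000, nSnps = 2, seed = 13,
                          noiseSd = 2)
  g <- simulateGenotypes(cfg)
  y <- simulatePhenotype(g, effects = list(), noiseSd = 2, seed = 13)
  expect_identical(names(y), sampleIds(g))
  expect_lt(abs(mean(y)), 0.15)
  expect_equal(sd(y), 2, tolerance = 0.05)
  expect_error(simulatePhenotype(g, noiseSd = 0), "noiseSd")
})

test_that("checkerboard effects are marginally null but jointly strong", {
  cfg <- SimulationConfig(nSamples = 2000, nSnps = 4,
                          mafRange = c(0.3, 0.3), seed = 14)
  g <- simulateGenotypes(cfg)
  snps <- snpIds(g)
  y <- simulatePhenotype(
    g, list(EffectSpec("epistatic_pair", snps[1:2], 1.0)),
    noiseSd = 1, seed = 14)
  d <- dosages(g)
  # marginal single-SNP association is null-like at MAF 0.3 thanks to the
  # orthogonalized pattern
  expect_lt(abs(cor(y, d[1, ])), 0.06)
  expect_lt(abs(cor(y, d[2, ])), 0.06)
  # the joint QMDR model carries the signal
  singles <- scoreModels(g, y, as.list(snps[1:2]))
  joint <- scoreModels(g, y, list(snps[1:2]))
  expect_gt(joint, 10)
  expect_gt(joint, 4 * max(singles))
  # the planted offsets have SD ~ effect size
  y0 <- simulatePhenotype(g, list(), noiseSd = 1, seed = 14)
  expect_equal(sd(y - y0), 1.0, tolerance = 0.05)
})

test_that("additive effects match the closed-form correlation", {
  cfg <- SimulationConfig(nSamples = 6000, nSnps = 2,
                          mafRange = c(0.25, 0.25), seed = 15)
  g <- simulateGenotypes(cfg)
  beta <- 1.0
  y <- simulatePhenotype(
    g, list(EffectSpec("additive", snpIds(g)[1], beta)),
    noiseSd = 1, seed = 15)
  # standardized dosage: cor(y, g) = beta / sqrt(beta^2 + 1)
  expect_equal(cor(y, dosages(g)[1, ]), beta / sqrt(beta^2 + 1),
               tolerance = 0.03)
})

test_that("three-way parity effects have null margins and pairs", {
  cfg <- SimulationConfig(nSamples = 4000, nSnps = 3,
                          mafRange = c(0.4, 0.4), seed = 16)
  g <- simulateGenotypes(cfg)
  snps <- snpIds(g)
  y <- simulatePhenotype(
    g, list(EffectSpec("epistatic_triple", snps, 1.5)),
    noiseSd = 1, seed = 16)
  d <- dosages(g)
  for (j in 1:3) expect_lt(abs(cor(y, d[j, ])), 0.06)
  triple <- scoreModels(g, y, list(snps))
  expect_gt(triple, 10)
})

test_that("gene geometry produces the designed truth map", {
  cfg <- SimulationConfig(nSamples = 10, nSnps = 60, snpSpacingBp = 50000L,
                          seed = 17,
                          genes = list(n = 5, spanBp = 10000,
                                       spacingBp = 1000000,
                                       clusters = list(2:4)))
  ann <- generateAnnotation(cfg)
  expect_identical(length(ann$genes), 5L)
  g <- simulateGenotypes(cfg)
  got <- mapSnpsToGenes(g, ann$genes, 500000L)
  expect_identical(mapTable(got), mapTable(ann$truth))
  # clustered genes share SNPs: any SNP of gene 2 within the shared window
  shared <- intersect(snpsOfGene(got, "G002"), snpsOfGene(got, "G003"))
  expect_gt(length(shared), 0)
  # far-apart genes partition their SNPs
  expect_identical(intersect(snpsOfGene(got, "G001"),
                             snpsOfGene(got, "G005")), character(0))
})

test_that("windows underflowing coordinate 1 are clipped without error", {
  d <- matrix(0L, 1, 2, dimnames = list("s1", c("A", "B")))
  g <- GenotypeData(d, data.frame(snp_id = "s1", chromosome = "1",
                                  position = 5L))
  genes <- GenomicRanges::GRanges("1", IRanges::IRanges(1000, 2000))
  names(genes) <- "EDGE"
  map <- mapSnpsToGenes(g, genes, 500000L)
  expect_identical(snpsOfGene(map, "EDGE"), "s1")
})

test_that("functional fixtures plant a recoverable module", {
  genes <- sprintf("P%02d", 1:20)
  module <- genes[1:6]
  sats <- sprintf("SAT%d", 1:4)
  fx <- generateFunctionalFixtures(c(genes, sprintf("BG%02d", 1:30)),
                                   module, sats, seed = 18)
  phase1 <- S4Vectors::DataFrame(gene_id = genes,
                                 snp_a = sprintf("a%02d", 1:20),
                                 snp_b = sprintf("b%02d", 1:20))
  out <- selectCandidates(phase1, fx$network, fx$sets)
  expect_identical(out$keptPhase1, module)
  expect_setequal(out$genes, c(module, sats))
  # determinism
  fx2 <- generateFunctionalFixtures(c(genes, sprintf("BG%02d", 1:30)),
                                    module, sats, seed = 18)
  expect_identical(networkEdges(fx2$network), networkEdges(fx$network))
  expect_identical(geneSets(fx2$sets), geneSets(fx$sets))
  # empty module -> nothing survives
  fxE <- generateFunctionalFixtures(genes, character(), seed = 19)
  outE <- selectCandidates(phase1, fxE$network, fxE$sets)
  expect_identical(outE$genes, character())
})

test_that("the planted study fixture is deterministic with the documented shape", {
  fx <- simulateStudyFixture(seed = 3, nSamples = 400)
  expect_identical(dim(dosages(fx$genotypes)), c(50L, 400L))
  expect_identical(length(fx$genes), 28L)
  expect_identical(length(fx$truth$uniqueSignificantSnps), 34L)
  expect_identical(length(fx$truth$candidateSnps), 10L)
  expect_identical(length(fx$truth$significantGenes), 20L)
  map <- mapSnpsToGenes(fx$genotypes, fx$genes)
  expect_identical(mapTable(map), mapTable(fx$truth$expectedMap))
  fx2 <- simulateStudyFixture(seed = 3, nSamples = 400)
  expect_identical(dosages(fx2$genotypes), dosages(fx$genotypes))
  expect_identical(fx2$phenotype, fx$phenotype)
})
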