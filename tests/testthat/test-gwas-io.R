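test_that("ped/map parsing recodes to minor-allele dosage", {
  mapPath <- writeTempLines(c("1\tsnpA\t0\t100", "1\tsnpB\t0\t200",
                              "1\tsnpC\t0\t300"), ".map")
  # snpA: alleles A/G with G minor (3 G vs 5 A across 4 samples)
  ped <- c("F1 I1 0 0 0 -9 A A A A C C",
           "F2 I2 0 0 0 -9 A G A A C C",
           "F3 I3 0 0 0 -9 G G A A C T",
           "F4 I4 0 0 0 -9 A A 0 0 T T")
  pedPath <- writeTempLines(ped, ".ped")
  g <- readGenotypes(pedPath, format = "ped", mapPath = mapPath)
  expect_s4_class(g, "GenotypeData")
  expect_identical(dim(dosages(g)), c(3L, 4L))
  # allele-frequency count oracle: freq(G) = 3/8 < freq(A), so G is minor
  expect_identical(unname(dosages(g)["snpA", ]), c(0L, 1L, 2L, 0L))
  # "0 0" becomes missing
  expect_identical(unname(dosages(g)["snpB", ]), c(0L, 0L, 0L, NA))
  # positions come from the map
  expect_identical(GenomicRanges::start(rowRanges(g))[1], 100L)
})

test_that("ped parse errors name the offending line", {
  mapPath <- writeTempLines("1\tsnpA\t0\t100", ".map")
  pedPath <- writeTempLines(c("F1 I1 0 0 0 -9 A A",
                              "F2 I2 0 0 0 -9 A"), ".ped")
  expect_error(readGenotypes(pedPath, format = "ped", mapPath = mapPath),
               "line 2")
  dupPath <- writeTempLines(c("F1 I1 0 0 0 -9 A A",
                              "F2 I1 0 0 0 -9 A G"), ".ped")
  expect_error(readGenotypes(dupPath, format = "ped", mapPath = mapPath),
               "duplicate sample id")
})

test_that("dosage tables read NA cells as missing and reject junk", {
  path <- writeTempLines(c("sample_id\ts1\ts2",
                           "A\t0\t2", "B\tNA\t1"), ".tsv")
  g <- readGenotypes(path, format = "dosage")
  expect_identical(unname(dosages(g)["s1", ]), c(0L, NA))
  bad <- writeTempLines(c("sample_id\ts1", "A\t3"), ".tsv")
  expect_error(readGenotypes(bad, format = "dosage"), "malformed dosage")
})

test_that("write-then-read round-trips both genotype formats", {
  g <- randomGenotypeData(12, 5, seed = 3, missingRate = 0.1)
  pre <- file.path(tempdir(), "rt")
  writeGenotypes(g, pre, format = "dosage")
  g2 <- readGenotypes(paste0(pre, ".tsv"), format = "dosage",
                      mapPath = paste0(pre, ".map"))
  expect_identical(dosages(g2), dosages(g))
  expect_identical(GenomicRanges::start(rowRanges(g2)),
                   GenomicRanges::start(rowRanges(g)))
  writeGenotypes(g, pre, format = "ped")
  g3 <- readGenotypes(paste0(pre, ".ped"), format = "ped")
  expect_identical(dosages(g3), dosages(g))
})

test_that("phenotype reader enforces finiteness and unique ids", {
  ok <- writeTempLines(c("A\t1.5", "B\t-0.5", "C\t2"), ".tsv")
  y <- readPhenotype(ok)
  expect_length(y, 3)
  expect_identical(names(y), c("A", "B", "C"))
  inf <- writeTempLines(c("A\t1", "B\tinf"), ".tsv")
  expect_error(readPhenotype(inf), "non-finite")
  dup <- writeTempLines(c("A\t1", "A\t2"), ".tsv")
  expect_error(readPhenotype(dup), "A")
  # round trip with header
  p <- tempfile(fileext = ".tsv")
  writePhenotype(y, p)
  expect_equal(readPhenotype(p), y)
})

test_that("BED genes convert to 1-based, sort, and reject empty spans", {
  bed <- writeTempLines(c("chr11\t999999\t1010000\tGENE1",
                          "chr2\t100\t200\tGENE2"), ".bed")
  genes <- readGeneAnnotation(bed)
  # BED 0-based half-open -> 1-based inclusive
  expect_identical(GenomicRanges::start(genes["GENE1"]), 1000000L)
  expect_identical(GenomicRanges::end(genes["GENE1"]), 1010000L)
  # sorted by (chromosome, start) regardless of input order
  expect_identical(names(genes), c("GENE2", "GENE1"))
  zero <- writeTempLines("chr1\t100\t100\tEMPTY", ".bed")
  expect_error(readGeneAnnotation(zero), "EMPTY")
})

test_that("window mapping is inclusive at exactly the window distance", {
  d <- matrix(0L, nrow = 3, ncol = 2,
              dimnames = list(c("in", "edge", "out"), c("A", "B")))
  info <- data.frame(snp_id = c("in", "edge", "out"),
                     chromosome = c("1", "1", "1"),
                     position = c(1005000L, 500000L, 499999L))
  g <- GenotypeData(d, info)
  genes <- GenomicRanges::GRanges("1", IRanges::IRanges(1000000, 1010000))
  names(genes) <- "GENE1"
  map <- mapSnpsToGenes(g, genes, windowBp = 500000L)
  expect_setequal(snpsOfGene(map, "GENE1"), c("in", "edge"))
  tb <- mapTable(map)
  expect_identical(tb$distance_bp[tb$snp_id == "edge"], 500000L)
  expect_identical(tb$distance_bp[tb$snp_id == "in"], 0L)
  # same coordinate, different chromosome: unmapped
  info2 <- info
  info2$chromosome <- "2"
  g2 <- GenotypeData(d, info2)
  expect_identical(nrow(mapTable(mapSnpsToGenes(g2, genes))), 0L)
})

test_that("mapping matches a brute-force interval scan and is monotone", {
  g <- randomGenotypeData(4, 40, seed = 5, spacing = 90000L)
  set.seed(6)
  starts <- sort(sample(1:3500000, 6))
  genes <- GenomicRanges::GRanges("1",
    IRanges::IRanges(starts, starts + 50000))
  names(genes) <- sprintf("GN%02d", 1:6)
  info <- data.frame(snp_id = snpIds(g), chromosome = "1",
                     position = GenomicRanges::start(rowRanges(g)))
  for (w in c(0L, 120000L, 500000L)) {
    got <- mapTable(mapSnpsToGenes(g, genes, w))
    want <- do.call(rbind, lapply(names(genes), function(gid) {
      gs <- GenomicRanges::start(genes[gid])
      ge <- GenomicRanges::end(genes[gid])
      hit <- info$position >= gs - w & info$position <= ge + w
      if (!any(hit)) return(NULL)
      data.frame(gene_id = gid, snp_id = info$snp_id[hit],
                 distance_bp = as.integer(pmax(0, gs - info$position[hit],
                                               info$position[hit] - ge)))
    }))
    want <- want[order(want$gene_id, want$snp_id), ]
    rownames(want) <- NULL
    expect_identical(got, want)
  }
  # monotone: enlarging the window never removes a pair
  small <- mapTable(mapSnpsToGenes(g, genes, 100000L))
  large <- mapTable(mapSnpsToGenes(g, genes, 400000L))
  expect_true(all(paste(small$gene_id, small$snp_id) %in%
                    paste(large$gene_id, large$snp_id)))
  expect_error(mapSnpsToGenes(g, genes, -1), "windowBp")
})

test_that("one SNP inside overlapping windows maps to every cluster gene", {
  d <- matrix(0L, nrow = 1, ncol = 2,
              dimnames = list("shared", c("A", "B")))
  info <- data.frame(snp_id = "shared", chromosome = "1",
                     position = 1000000L)
  g <- GenotypeData(d, info)
  starts <- seq(900000, 1100000, length.out = 5)
  genes <- GenomicRanges::GRanges("1", IRanges::IRanges(starts, starts + 9999))
  names(genes) <- sprintf("OLF%d", 1:5)
  map <- mapSnpsToGenes(g, genes, 500000L)
  expect_setequal(genesOfSnp(map, "shared"), names(genes))
})

test_that("SnpGeneMap round-trips through TSV", {
  g <- randomGenotypeData(3, 10, seed = 2, spacing = 120000L)
  genes <- GenomicRanges::GRanges("1", IRanges::IRanges(c(1, 600000),
                                                        c(50000, 680000)))
  names(genes) <- c("GA", "GB")
  map <- mapSnpsToGenes(g, genes, 250000L)
  path <- tempfile(fileext = ".tsv")
  writeSnpGeneMap(map, path)
  map2 <- readSnpGeneMap(path, windowBp = 250000L)
  expect_identical(mapTable(map2), mapTable(map))
})
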