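toyNetwork <- function() {
  FunctionalNetwork(data.frame(
    gene_a = c("A", "A", "B", "C", "D"),
    gene_b = c("B", "C", "C", "E", "E"),
    confidence = c(0.95, 0.90, 0.8999, 0.99, 0.5)))
}

test_that("network construction normalizes pairs and rejects self-loops", {
  net <- FunctionalNetwork(data.frame(gene_a = c("B", "A"),
                                      gene_b = c("A", "B"),
                                      confidence = c(0.7, 0.9)))
  e <- networkEdges(net)
  expect_identical(nrow(e), 1L)       # duplicate unordered pair collapsed
  expect_identical(e$confidence, 0.9) # keeping the max confidence
  expect_true(all(e$gene_a < e$gene_b))
  expect_error(FunctionalNetwork(data.frame(gene_a = "A", gene_b = "A",
                                            confidence = 1)),
               "self-loops")
})

test_that("confidence filter is inclusive, idempotent and monotone", {
  net <- toyNetwork()
  f <- filterNetwork(net, 0.9)
  expect_setequal(networkEdges(f)$confidence, c(0.95, 0.90, 0.99))
  expect_identical(networkEdges(filterNetwork(f, 0.9)), networkEdges(f))
  expect_identical(networkEdges(filterNetwork(net, 0)), networkEdges(net))
  # raising the threshold never adds edges
  thresholds <- c(0, 0.5, 0.9, 0.95, 1)
  sizes <- vapply(thresholds, function(th)
    nrow(networkEdges(filterNetwork(net, th))), integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_identical(nrow(networkEdges(filterNetwork(net, 0.999))), 0L)
})

test_that("augmentation ranks by max confidence, neighbours, then id", {
  query <- c("Q1", "Q2")
  net <- FunctionalNetwork(data.frame(
    gene_a = c("Q1", "Q2", "Q1", "Q2", "Q1", "Q1"),
    gene_b = c("X1", "X1", "X2", "X3", "X4", "Q2"),
    confidence = c(0.92, 0.95, 0.95, 0.95, 0.91, 0.99)))
  # brute-force ranking oracle: X1 max 0.95 (2 query nbrs), X2 0.95 (1),
  # X3 0.95 (1), X4 0.91 -> order X1, X2, X3, X4
  expect_identical(augmentGeneList(query, net, maxAdded = 1),
                   sort(c(query, "X1")))
  expect_identical(augmentGeneList(query, net, maxAdded = 3),
                   sort(c(query, "X1", "X2", "X3")))
  expect_identical(augmentGeneList(query, net, maxAdded = 20),
                   sort(c(query, "X1", "X2", "X3", "X4")))
  expect_identical(augmentGeneList(query, net, maxAdded = 0), sort(query))
  expect_error(augmentGeneList(query, net, maxAdded = -1), "maxAdded")
})

test_that("augmentation caps additions under a large eligible pool", {
  set.seed(1)
  out <- sprintf("OUT%02d", 1:30)
  net <- FunctionalNetwork(data.frame(
    gene_a = "Q", gene_b = out,
    confidence = round(runif(30, 0.9, 0.99), 3)))
  got <- augmentGeneList("Q", net, maxAdded = 20)
  expect_identical(length(got), 21L)
  # matches an independent ranking by confidence then id
  e <- networkEdges(net)
  want <- e$gene_b[order(-e$confidence,
                         e$gene_b)][1:20]
  o <- ifelse(e$gene_a == "Q", e$gene_b, e$gene_a)
  conf <- e$confidence
  want <- o[order(-conf, o)][1:20]
  expect_setequal(setdiff(got, "Q"), want)
})

test_that("GMT parsing and the gene universe behave", {
  gmt <- writeTempLines(c("setA\tdesc\tG1\tG2\tG3",
                          "setB\tdesc\tG2\tG4"), ".gmt")
  sets <- readGmt(gmt)
  expect_identical(names(geneSets(sets)), c("setA", "setB"))
  expect_identical(geneUniverse(sets), sort(c("G1", "G2", "G3", "G4")))
  wide <- readGmt(gmt, universe = sprintf("G%d", 1:10))
  expect_identical(length(geneUniverse(wide)), 10L)
  bad <- writeTempLines("setC\tonlydesc", ".gmt")
  expect_error(readGmt(bad), "malformed GMT line 1")
  # round trip
  p <- tempfile(fileext = ".gmt")
  writeGmt(sets, p)
  expect_identical(geneSets(readGmt(p)), geneSets(sets))
})

test_that("hypergeometric enrichment matches exhaustive tail enumeration", {
  # worked instance: universe 20, set 5, query 5, overlap 3
  uni <- sprintf("U%02d", 1:20)
  sets <- GeneSets(list(S = uni[1:5]), universe = uni)
  query <- c(uni[1:3], uni[6:7])
  res <- hypergeometricEnrichment(query, sets)
  expect_identical(res$overlap, 3L)
  expect_equal(res$p_value, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$p_value, bfHyperTail(3, 5, 5, 20), tolerance = 1e-12)
  # degenerate bounds
  empty <- hypergeometricEnrichment(uni[6:10],
                                    GeneSets(list(S = uni[1:5]),
                                             universe = uni))
  expect_identical(empty$p_value, 1)  # overlap 0 -> P(X >= 0) = 1
  full <- hypergeometricEnrichment(uni[1:4],
                                   GeneSets(list(S = uni), universe = uni))
  expect_identical(full$overlap, 4L)
  expect_equal(full$p_value, 1)
  expect_error(hypergeometricEnrichment(c("U01", "ZZZ"), sets), "ZZZ")
})

test_that("hypergeometric p equals brute force across many instances", {
  set.seed(2)
  for (i in 1:50) {
    N <- sample(10:60, 1)
    uni <- sprintf("g%02d", seq_len(N))
    ss <- sample(seq_len(N - 1), 1)
    qs <- sample(seq_len(N - 1), 1)
    sets <- GeneSets(list(S = sample(uni, ss)), universe = uni)
    query <- sample(uni, qs)
    got <- hypergeometricEnrichment(query, sets)$p_value
    k <- length(intersect(query, geneSets(sets)$S))
    expect_equal(got, bfHyperTail(k, ss, qs, N), tolerance = 1e-12)
  }
})

test_that("candidate selection reproduces the planted 20 -> 6 (+4) -> 10 shape", {
  phase1 <- S4Vectors::DataFrame(
    gene_id = sprintf("P%02d", 1:20),
    snp_a = sprintf("sa%02d", 1:20),
    snp_b = sprintf("sb%02d", 1:20))
  # module: P01..P06 in the high-confidence network and one enriched set;
  # P01/P02 share their best pair (SNP dedup 12 -> 10)
  phase1$snp_a[2] <- phase1$snp_a[1]; phase1$snp_b[2] <- phase1$snp_b[1]
  module <- sprintf("P%02d", 1:6)
  sats <- sprintf("ADD%d", 1:4)
  edges <- rbind(
    data.frame(gene_a = module[1], gene_b = module[-1], confidence = 0.95),
    data.frame(gene_a = pmin(sats, module[2]),
               gene_b = pmax(sats, module[2]), confidence = 0.93),
    data.frame(gene_a = "P10", gene_b = "P11", confidence = 0.5))
  net <- FunctionalNetwork(edges)
  uni <- c(phase1$gene_id, sats, sprintf("BG%02d", 1:40))
  sets <- GeneSets(list(mod = module, decoy = sprintf("BG%02d", 1:10)),
                   universe = uni)
  out <- selectCandidates(phase1, net, sets)
  expect_identical(out$keptPhase1, module)
  expect_identical(length(out$genes), 10L)
  expect_setequal(setdiff(out$genes, module), sats)
  expect_identical(length(out$snpIds), 10L)
  # selected SNPs are a subset of the Phase I best-pair union
  expect_true(all(out$snpIds %in% c(phase1$snp_a, phase1$snp_b)))
  # enrichment for the module set is significant, the decoy is not
  enr <- out$enrichment
  expect_lt(enr$p_value[enr$set_name == "mod"], 0.05)
  expect_gt(enr$p_value[enr$set_name == "decoy"], 0.05)
})

test_that("degenerate filter inputs behave", {
  phase1 <- S4Vectors::DataFrame(gene_id = "P01", snp_a = "a", snp_b = "b")
  empty <- FunctionalNetwork(data.frame(gene_a = character(),
                                        gene_b = character(),
                                        confidence = numeric()))
  sets <- GeneSets(list(S = "P01"), universe = "P01")
  out <- selectCandidates(phase1, empty, sets)
  expect_identical(out$genes, character())
  expect_identical(out$snpIds, character())
  # complete network + universally enriched set retains everything
  net <- FunctionalNetwork(data.frame(gene_a = "P01", gene_b = "P02",
                                      confidence = 0.99))
  sets2 <- GeneSets(list(S = "P01"),
                    universe = c("P01", "P02", sprintf("Z%02d", 1:28)))
  out2 <- selectCandidates(phase1, net, sets2)
  expect_true("P01" %in% out2$genes)
})
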