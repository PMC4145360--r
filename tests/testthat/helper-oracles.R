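# Independent oracles and small fixture builders.  These deliberately use
# different code paths (paste/tapply grouping, explicit enumeration,
# joint-frequency tables, binomial-coefficient sums) than the package.

# Random genotype panel with named SNPs/samples and optional coordinates.
randomGenotypeData <- function(n, m, maf = 0.3, seed = 1,
                               missingRate = 0, spacing = 5000L) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2L, maf), nrow = m,
              dimnames = list(sprintf("snp%02d", seq_len(m)),
                              sprintf("S%03d", seq_len(n))))
  if (missingRate > 0)
    d[runif(length(d)) < missingRate] <- NA_integer_
  info <- data.frame(snp_id = rownames(d), chromosome = "1",
                     position = seq_len(m) * spacing)
  GenotypeData(d, info)
}

randomPhenotype <- function(genotypes, seed = 1) {
  set.seed(seed)
  stats::setNames(rnorm(ncol(genotypes)), colnames(genotypes))
}

# Brute-force QMDR t for one subset: grouping by pasted genotype strings,
# mean-rule labels, Welch t via stats::t.test where defined.
bfQmdrT <- function(genotypes, y, snps) {
  g <- dosages(genotypes)[snps, , drop = FALSE]
  y <- y[colnames(genotypes)]
  ok <- colSums(is.na(g)) == 0
  g <- g[, ok, drop = FALSE]
  yy <- as.numeric(y[ok])
  key <- apply(g, 2, paste, collapse = ",")
  gm <- mean(yy)
  cellMean <- tapply(yy, key, mean)
  hiCells <- names(cellMean)[cellMean >= gm]
  h <- yy[key %in% hiCells]
  l <- yy[!key %in% hiCells]
  if (length(h) == 0 || length(l) == 0) return(0)
  vh <- if (length(h) > 1) var(h) else 0
  vl <- if (length(l) > 1) var(l) else 0
  if (vh / length(h) + vl / length(l) <= 0) return(0)
  if (length(h) > 1 && length(l) > 1)
    unname(t.test(h, l, var.equal = FALSE)$statistic)
  else
    (mean(h) - mean(l)) / sqrt(vh / length(h) + vl / length(l))
}

# Exhaustive best subset by brute force over given orders.
bfBestModel <- function(genotypes, y, snps, orders = 2L) {
  subsets <- unlist(lapply(sort(orders), function(k)
    combn(sort(snps), k, simplify = FALSE)), recursive = FALSE)
  scores <- vapply(subsets, function(s) bfQmdrT(genotypes, y, s),
                   numeric(1))
  list(subset = subsets[[which.max(scores)]], t = max(scores),
       scores = scores, subsets = subsets)
}

# Entropies from explicit joint frequency tables.
bfEntropy <- function(...) {
  tab <- table(...)
  p <- as.numeric(tab) / sum(tab)
  p <- p[p > 0]
  -sum(p * log2(p))
}

bfMutualInformation <- function(x, y)
  bfEntropy(x) + bfEntropy(y) - bfEntropy(x, y)

# Upper-tail hypergeometric by explicit binomial-coefficient sums.
bfHyperTail <- function(overlap, setSize, querySize, universeSize) {
  ks <- overlap:min(setSize, querySize)
  sum(choose(setSize, ks) *
        choose(universeSize - setSize, querySize - ks)) /
    choose(universeSize, querySize)
}

# A small planted checkerboard dataset: SNPs 1 and 2 interact epistatically,
# the rest are noise.
checkerboardData <- function(n = 300, m = 6, effect = 1.5, maf = 0.5,
                             seed = 1) {
  g <- randomGenotypeData(n, m, maf = maf, seed = seed)
  set.seed(seed + 1)
  d <- dosages(g)
  y <- rnorm(n) + effect * (-1)^(d[1, ] + d[2, ])
  list(genotypes = g, phenotype = stats::setNames(y, colnames(g)),
       causal = rownames(d)[1:2])
}

writeTempLines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
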