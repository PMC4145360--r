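#' @include phase1.R
NULL

#' Construct a FunctionalNetwork
#'
#' Normalizes an edge data.frame: unordered pairs are stored once with
#' gene_a < gene_b and duplicate pairs keep their maximum confidence.
#' Self-loops are a validation error.
#'
#' @param edges data.frame with columns gene_a, gene_b, confidence.
#' @return a \linkS4class{FunctionalNetwork}.
#' @export
FunctionalNetwork <- function(edges) {
  edges <- as.data.frame(edges)
  if (!all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
    stop("edges need columns gene_a, gene_b, confidence")
  if (nrow(edges)) {
    if (any(edges$gene_a == edges$gene_b))
      stop("self-loops are not allowed")
    a <- pmin(as.character(edges$gene_a), as.character(edges$gene_b))
    b <- pmax(as.character(edges$gene_a), as.character(edges$gene_b))
    edges <- data.frame(gene_a = a, gene_b = b,
                        confidence = as.numeric(edges$confidence),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene_a, edges$gene_b, -edges$confidence), ]
    edges <- edges[!duplicated(edges[c("gene_a", "gene_b")]), ]
    rownames(edges) <- NULL
  }
  new("FunctionalNetwork", edges = edges)
}

#' @rdname FunctionalNetwork-class
#' @export
setMethod("networkEdges", "FunctionalNetwork", function(x) x@edges)

#' @rdname FunctionalNetwork-class
#' @export
setMethod("networkGenes", "FunctionalNetwork",
          function(x) sort(unique(c(x@edges$gene_a, x@edges$gene_b))))

setMethod("show", "FunctionalNetwork", function(object) {
  cat("FunctionalNetwork:", nrow(object@edges), "edges,",
      length(networkGenes(object)), "genes\n")
})

#' Read / write a functional network as TSV
#'
#' Three columns (gene_a, gene_b, confidence), with or without a header.
#'
#' @param path TSV path.
#' @export
readFunctionalNetwork <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  hasHeader <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[3])))
  tb <- utils::read.table(path, header = hasHeader, sep = "\t",
                          stringsAsFactors = FALSE)
  names(tb)[1:3] <- c("gene_a", "gene_b", "confidence")
  FunctionalNetwork(tb)
}

#' @rdname readFunctionalNetwork
#' @param network a \linkS4class{FunctionalNetwork}.
#' @export
writeFunctionalNetwork <- function(network, path) {
  utils::write.table(networkEdges(network), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep only high-confidence edges
#'
#' Retains edges with confidence >= \code{minConfidence} (inclusive).
#' Idempotent, and monotone: raising the threshold never adds edges.
#'
#' @param network a \linkS4class{FunctionalNetwork}.
#' @param minConfidence threshold in [0, 1] (default 0.9).
#' @return the filtered \linkS4class{FunctionalNetwork}.
#' @export
filterNetwork <- function(network, minConfidence = 0.9) {
  if (minConfidence < 0 || minConfidence > 1)
    stop("minConfidence must lie in [0, 1]")
  e <- networkEdges(network)
  new("FunctionalNetwork", edges = e[e$confidence >= minConfidence, ,
                                     drop = FALSE])
}

#' Add network neighbours to a gene list
#'
#' Adds at most \code{maxAdded} non-query genes connected to the query set
#' in the (already confidence-filtered) network.  Candidates are ranked by
#' descending maximum edge confidence to the query set, ties broken by
#' descending number of query neighbours, then lexicographic gene id.
#'
#' @param queryGenes character vector of gene ids.
#' @param network a confidence-filtered \linkS4class{FunctionalNetwork}.
#' @param maxAdded maximum genes to add (default 20).
#' @return the augmented, sorted gene set.
#' @export
augmentGeneList <- function(queryGenes, network, maxAdded = 20L) {
  if (maxAdded < 0) stop("maxAdded must be >= 0")
  queryGenes <- unique(as.character(queryGenes))
  e <- networkEdges(network)
  touch <- e$gene_a %in% queryGenes | e$gene_b %in% queryGenes
  e <- e[touch, , drop = FALSE]
  if (maxAdded == 0L || nrow(e) == 0) return(sort(queryGenes))
  other <- ifelse(e$gene_a %in% queryGenes, e$gene_b, e$gene_a)
  keep <- !other %in% queryGenes
  other <- other[keep]
  conf <- e$confidence[keep]
  qnbr <- ifelse(e$gene_a[keep] %in% queryGenes, e$gene_a[keep],
                 e$gene_b[keep])
  if (length(other) == 0) return(sort(queryGenes))
  maxConf <- tapply(conf, other, max)
  nNbr <- tapply(qnbr, other, function(x) length(unique(x)))
  cand <- names(maxConf)
  ord <- order(-maxConf[cand], -nNbr[cand], cand)
  added <- cand[ord][seq_len(min(maxAdded, length(cand)))]
  sort(unique(c(queryGenes, added)))
}

# ---- gene sets -------------------------------------------------------------

#' Construct a GeneSets collection
#' @param sets named list of character vectors.
#' @param universe gene universe; defaults to the union of all sets.
#' @return a \linkS4class{GeneSets}.
#' @export
GeneSets <- function(sets, universe = NULL) {
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  new("GeneSets", sets = sets, universe = sort(unique(universe)))
}

#' @rdname GeneSets-class
#' @export
setMethod("geneSets", "GeneSets", function(x) x@sets)

#' @rdname GeneSets-class
#' @export
setMethod("geneUniverse", "GeneSets", function(x) x@universe)

setMethod("show", "GeneSets", function(object) {
  cat("GeneSets:", length(object@sets), "sets over a universe of",
      length(object@universe), "genes\n")
})

#' Read gene sets from GMT
#'
#' Tab-separated: set name, description, then member genes.  The universe
#' defaults to the union of all set members; supply \code{universe} (a
#' character vector or a one-column text file) to widen it.
#'
#' @param path GMT file.
#' @param universe optional universe (character vector or file path).
#' @return a \linkS4class{GeneSets}.
#' @export
readGmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(lines, "\t")
  bad <- which(lengths(toks) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": fewer than 3 fields")
  sets <- lapply(toks, function(x) x[-(1:2)])
  names(sets) <- vapply(toks, `[`, character(1), 1)
  if (is.character(universe) && length(universe) == 1 &&
      file.exists(universe))
    universe <- readLines(universe)
  GeneSets(sets, universe = unique(c(universe, unlist(sets))))
}

#' @rdname readGmt
#' @param sets a \linkS4class{GeneSets}.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(geneSets(sets)), function(nm)
    paste(c(nm, "na", geneSets(sets)[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric (one-sided) gene-set enrichment
#'
#' For each set, the upper-tail hypergeometric probability
#' \eqn{P(X \ge \mathrm{overlap})} of drawing at least the observed overlap
#' when \code{length(query)} genes are drawn without replacement from a
#' universe containing \code{|set|} successes (equivalently Fisher's exact
#' upper tail).  P-values are unadjusted, matching a screening pipeline
#' that controls false positives through the functional filter itself.
#'
#' @param query character vector of genes, all within the universe.
#' @param sets a \linkS4class{GeneSets}.
#' @return data.frame (set_name, overlap, set_size, query_size,
#'   universe_size, p_value), sorted by p_value.
#' @export
hypergeometricEnrichment <- function(query, sets) {
  query <- unique(as.character(query))
  uni <- geneUniverse(sets)
  outside <- setdiff(query, uni)
  if (length(outside))
    stop("query genes outside the universe: ",
         paste(outside, collapse = ", "))
  N <- length(uni)
  q <- length(query)
  res <- lapply(names(geneSets(sets)), function(nm) {
    s <- geneSets(sets)[[nm]]
    k <- length(intersect(query, s))
    data.frame(set_name = nm, overlap = k, set_size = length(s),
               query_size = q, universe_size = N,
               p_value = stats::phyper(k - 1, length(s), N - length(s), q,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out
}

#' Phase II candidate selection
#'
#' Reduces the Phase I gene list using functional evidence: the network is
#' confidence-filtered, enrichment is computed for the Phase I genes that
#' appear in the filtered network, and a Phase I gene is kept when it
#' appears in the filtered network AND belongs to at least one enriched
#' set (p < alpha), or — in the same network — is connected to such a
#' gene.  With \code{combine = "or"} network membership or enriched-set
#' membership alone suffices.  The kept genes' Phase I best-pair SNPs are
#' unioned (duplicates collapsed), and [augmentGeneList()] then adds up to
#' \code{maxAdded} connected genes.
#'
#' @param phase1Genes DataFrame of significant genes from
#'   [selectSignificantGenes()] (needs gene_id, snp_a, snp_b).
#' @param network a \linkS4class{FunctionalNetwork}.
#' @param sets a \linkS4class{GeneSets}.
#' @param minConfidence edge confidence threshold (default 0.9).
#' @param alpha enrichment significance level (default 0.05, strict).
#' @param maxAdded genes the network may add (default 20).
#' @param combine "and" (default) or "or".
#' @return list with \code{genes} (final augmented gene set),
#'   \code{snpIds} (their unique Phase I SNPs), \code{keptPhase1}
#'   (Phase I genes surviving the filter), and \code{enrichment} (the
#'   enrichment table).
#' @export
selectCandidates <- function(phase1Genes, network, sets,
                             minConfidence = 0.9, alpha = 0.05,
                             maxAdded = 20L, combine = c("and", "or")) {
  combine <- match.arg(combine)
  p1 <- as.character(phase1Genes$gene_id)
  net <- filterNetwork(network, minConfidence)
  inNet <- p1[p1 %in% networkGenes(net)]
  query <- intersect(inNet, geneUniverse(sets))
  enr <- if (length(query))
    hypergeometricEnrichment(query, sets)
  else
    data.frame(set_name = character(), overlap = integer(),
               set_size = integer(), query_size = integer(),
               universe_size = integer(), p_value = numeric())
  enriched <- enr$set_name[enr$p_value < alpha]
  enrichedGenes <- unique(unlist(geneSets(sets)[enriched]))
  core <- if (combine == "and")
    intersect(inNet, enrichedGenes)
  else
    union(inNet, intersect(p1, enrichedGenes))
  # Phase I genes connected (in the filtered network) to a core gene.
  e <- networkEdges(net)
  nbr <- unique(c(e$gene_b[e$gene_a %in% core], e$gene_a[e$gene_b %in% core]))
  kept <- sort(union(core, intersect(p1, nbr)))
  idx <- phase1Genes$gene_id %in% kept
  snps <- sort(unique(c(phase1Genes$snp_a[idx], phase1Genes$snp_b[idx])))
  genes <- if (length(kept)) augmentGeneList(kept, net, maxAdded) else
    character()
  list(genes = genes, snpIds = snps, keptPhase1 = kept, enrichment = enr)
}
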