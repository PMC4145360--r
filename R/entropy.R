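#' @include multiway.R
NULL

#' Binarize a quantitative trait at its global mean
#'
#' 1 iff the value is greater than or equal to the threshold (ties high,
#' the same rule the QMDR cell labelling uses), else 0.  A quantile-based
#' alternative is available through \code{method = "median"} for
#' robustness checks.
#'
#' @param phenotype named numeric vector.
#' @param threshold cut point; defaults to the mean (or median).
#' @param method "mean" (default) or "median" threshold.
#' @return named integer 0/1 vector with attribute \code{"threshold"}.
#' @export
binarizeTrait <- function(phenotype, threshold = NULL,
                          method = c("mean", "median")) {
  method <- match.arg(method)
  if (is.null(threshold))
    threshold <- if (method == "mean") mean(phenotype) else
      stats::median(phenotype)
  structure(as.integer(phenotype >= threshold),
            names = names(phenotype), threshold = threshold)
}

#' Shannon entropy in bits
#'
#' \eqn{H = -\sum_v \hat p(v) \log_2 \hat p(v)} with empirical frequencies
#' and the convention \eqn{0 \log 0 = 0}.
#'
#' @param x discrete variable (any atomic vector; NAs must be removed by
#'   the caller).
#' @return entropy in bits.
#' @export
shannonEntropy <- function(x) {
  if (length(x) == 0) stop("empty sample")
  if (anyNA(x)) stop("remove missing values before computing entropy")
  p <- tabulate(factor(x)) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information in bits
#'
#' \eqn{I(X;Y) = H(X) + H(Y) - H(X,Y)}, non-negative up to rounding.
#'
#' @param x,y discrete variables over the same samples.
#' @return mutual information in bits.
#' @export
mutualInformation <- function(x, y) {
  if (length(x) != length(y))
    stop("variables must share the same samples")
  shannonEntropy(x) + shannonEntropy(y) -
    shannonEntropy(paste(x, y, sep = "\r"))
}

# Complete-case restriction over a list of variables.
.completeCases <- function(...) {
  vars <- list(...)
  keep <- !Reduce(`|`, lapply(vars, is.na))
  lapply(vars, `[`, keep)
}

#' Pairwise synergy (information gain) of two SNPs on a binary trait
#'
#' \eqn{IG(A;B;P) = I(A,B;P) - I(A;P) - I(B;P)} where (A,B) is the joint
#' 9-level genotype variable.  Positive values are synergistic, negative
#' redundant; samples missing any of the three variables are dropped.
#'
#' @param a,b SNP dosage vectors (0/1/2, NA allowed).
#' @param p binarized trait (see [binarizeTrait()]).
#' @return information gain in bits (may be negative).
#' @export
pairwiseSynergy <- function(a, b, p) {
  v <- .completeCases(a, b, p)
  joint <- paste(v[[1]], v[[2]], sep = "\r")
  mutualInformation(joint, v[[3]]) -
    mutualInformation(v[[1]], v[[3]]) -
    mutualInformation(v[[2]], v[[3]])
}

#' Pure three-way synergy of three SNPs on a binary trait
#'
#' \eqn{TWIG = I(A,B,C;P) - IG(A,B;P) - IG(A,C;P) - IG(B,C;P)
#'      - I(A;P) - I(B;P) - I(C;P)}: the information the triple carries
#' about the trait beyond all one- and two-way effects.  All terms are
#' computed on the triple's complete cases.
#'
#' @param a,b,c SNP dosage vectors.
#' @param p binarized trait.
#' @return three-way information gain in bits.
#' @export
threewaySynergy <- function(a, b, c, p) {
  v <- .completeCases(a, b, c, p)
  a <- v[[1]]; b <- v[[2]]; c <- v[[3]]; p <- v[[4]]
  jab <- paste(a, b, sep = "\r")
  jac <- paste(a, c, sep = "\r")
  jbc <- paste(b, c, sep = "\r")
  jabc <- paste(a, b, c, sep = "\r")
  ia <- mutualInformation(a, p)
  ib <- mutualInformation(b, p)
  ic <- mutualInformation(c, p)
  igab <- mutualInformation(jab, p) - ia - ib
  igac <- mutualInformation(jac, p) - ia - ic
  igbc <- mutualInformation(jbc, p) - ib - ic
  mutualInformation(jabc, p) - igab - igac - igbc - ia - ib - ic
}

#' Build the entropy-based SNP interaction network
#'
#' Over the candidate SNPs: node weights are single-SNP mutual
#' informations with the binarized trait (main effects), edges the
#' pairwise information gain with a synergy/redundancy/independence label,
#' triangles the pure three-way information gain, and a parallel
#' redundancy table the inter-SNP mutual information (a linkage-
#' disequilibrium measure, computed without the trait).  Complete cases
#' are taken per tuple.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param phenotype named numeric vector (binarized internally at its
#'   global mean).
#' @param snpIds candidate SNPs (>= 2).
#' @param epsilon |IG| below which an edge is labelled "independent"
#'   (default 0.005 bits; a reporting convention only, raw values are
#'   always emitted).
#' @param method trait binarization method, see [binarizeTrait()].
#' @return an \linkS4class{InteractionNetwork}.
#' @export
buildInteractionNetwork <- function(genotypes, phenotype, snpIds,
                                    epsilon = 0.005,
                                    method = c("mean", "median")) {
  snpIds <- sort(unique(as.character(snpIds)))
  if (length(snpIds) < 2) stop("need at least 2 SNPs")
  y <- .alignPhenotype(genotypes, phenotype)
  p <- binarizeTrait(y, method = match.arg(method))
  g <- dosages(genotypes)[snpIds, , drop = FALSE]
  nodes <- data.frame(
    snp_id = snpIds,
    main_effect_bits = vapply(snpIds, function(s) {
      v <- .completeCases(g[s, ], p)
      mutualInformation(v[[1]], v[[2]])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  pairs <- utils::combn(snpIds, 2, simplify = FALSE)
  ig <- vapply(pairs, function(pr)
    pairwiseSynergy(g[pr[1], ], g[pr[2], ], p), numeric(1))
  edges <- data.frame(
    snp_a = vapply(pairs, `[`, character(1), 1),
    snp_b = vapply(pairs, `[`, character(1), 2),
    synergy_bits = ig,
    class = ifelse(abs(ig) < epsilon, "independent",
                   ifelse(ig > 0, "synergistic", "redundant")),
    stringsAsFactors = FALSE)
  redundancy <- data.frame(
    snp_a = edges$snp_a, snp_b = edges$snp_b,
    mi_bits = vapply(pairs, function(pr) {
      v <- .completeCases(g[pr[1], ], g[pr[2], ])
      mutualInformation(v[[1]], v[[2]])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  triangles <- if (length(snpIds) >= 3) {
    trip <- utils::combn(snpIds, 3, simplify = FALSE)
    data.frame(
      snp_a = vapply(trip, `[`, character(1), 1),
      snp_b = vapply(trip, `[`, character(1), 2),
      snp_c = vapply(trip, `[`, character(1), 3),
      synergy_bits = vapply(trip, function(tr)
        threewaySynergy(g[tr[1], ], g[tr[2], ], g[tr[3], ], p),
        numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(snp_a = character(), snp_b = character(),
               snp_c = character(), synergy_bits = numeric())
  }
  new("InteractionNetwork", nodes = nodes, edges = edges,
      triangles = triangles, redundancy = redundancy,
      traitEntropy = shannonEntropy(p), epsilon = epsilon)
}

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork:", nrow(object@nodes), "SNPs,",
      nrow(object@edges), "edges,", nrow(object@triangles), "triangles\n")
  cat(sprintf("  trait entropy %.4f bits; independence epsilon %g bits\n",
              object@traitEntropy, object@epsilon))
  cls <- table(object@edges$class)
  cat("  edge classes:",
      paste(names(cls), as.integer(cls), collapse = ", "), "\n")
})

#' Export an InteractionNetwork
#'
#' GraphML carries nodes (main-effect bits) and edges (synergy bits,
#' inter-SNP MI, class); triangles have no native GraphML encoding and are
#' only present in the JSON export, which contains the full object.
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param path output path.
#' @export
exportGraphML <- function(network, path) {
  e <- network@edges
  red <- network@redundancy
  e$redundancy_mi_bits <- red$mi_bits[match(
    paste(e$snp_a, e$snp_b), paste(red$snp_a, red$snp_b))]
  gr <- igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = data.frame(name = network@nodes$snp_id,
                          main_effect_bits = network@nodes$main_effect_bits))
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}

#' @rdname exportGraphML
#' @export
exportInteractionJson <- function(network, path = NULL) {
  obj <- list(trait_entropy_bits = network@traitEntropy,
              independence_epsilon_bits = network@epsilon,
              nodes = network@nodes, edges = network@edges,
              triangles = network@triangles,
              redundancy = network@redundancy)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
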