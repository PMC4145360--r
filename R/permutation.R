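#' @include qmdr.R
NULL

# Deterministic sub-seed derivation: a small Lehmer-style mixer keeping all
# intermediates exactly representable in doubles, so a master seed plus a
# salt (permutation counter, gene id, stage name) yields a reproducible
# stream id independent of evaluation order.
.deriveSeed <- function(master, salt) {
  m <- 2147483647
  if (is.character(salt)) {
    cp <- utf8ToInt(salt)
    salt <- sum(cp * ((seq_along(cp) - 1) %% 97 + 1))
  }
  x <- as.numeric(master) %% m
  s <- as.numeric(salt) %% m
  x <- (x * 48271) %% m
  x <- (x + (s %% 65536) * 69621 + s) %% m
  x <- (x * 16807) %% m
  as.integer(x %% (m - 1) + 1)
}

#' Permute a phenotype vector
#'
#' Returns a uniform random permutation of the values over the same sample
#' ids, drawn from R's current RNG state; genotypes are untouched.  The
#' multiset of values is preserved exactly.
#'
#' @param phenotype named numeric vector.
#' @return a named numeric vector with permuted values.
#' @export
permutePhenotype <- function(phenotype) {
  stats::setNames(phenotype[sample.int(length(phenotype))],
                  names(phenotype))
}

#' Empirical permutation p-value
#'
#' \eqn{p = (r + 1) / (N + 1)} where r counts permuted scores greater than
#' or equal to the observed score (ties included, conservative).  The +1
#' convention avoids p = 0 and makes "p < 0.001 with 1000 permutations"
#' achievable exactly when the observed score beats every permutation.
#'
#' @param observed observed score.
#' @param permuted vector of permuted-search scores.
#' @return the empirical p-value, in [1/(N+1), 1].
#' @export
empiricalPValue <- function(observed, permuted) {
  if (length(permuted) == 0) stop("permuted scores must be nonempty")
  (sum(permuted >= observed) + 1) / (length(permuted) + 1)
}

#' Permutation test around a full model search
#'
#' Re-runs the complete search procedure (including its model selection)
#' on each permuted phenotype, so the null distribution accounts for the
#' selection of the best model.  Each permutation uses a sub-seed derived
#' from \code{seed} and the permutation counter, making the result
#' independent of scheduling and bitwise reproducible.
#'
#' @param search function \code{(genotypes, phenotype) -> best score}.
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param phenotype named numeric vector.
#' @param nPermutations number of permutations (default 1000).
#' @param seed master seed.
#' @return a \linkS4class{PermutationResult}.
#' @export
permutationTest <- function(search, genotypes, phenotype,
                            nPermutations = 1000L, seed = 1L) {
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  y <- .alignPhenotype(genotypes, phenotype)
  observed <- as.numeric(search(genotypes, y))
  permuted <- numeric(nPermutations)
  for (i in seq_len(nPermutations)) {
    set.seed(.deriveSeed(seed, i))
    permuted[i] <- as.numeric(search(genotypes, permutePhenotype(y)))
  }
  new("PermutationResult", observed = observed, permuted = permuted,
      empiricalP = empiricalPValue(observed, permuted),
      nPermutations = as.integer(nPermutations), seed = as.integer(seed))
}

#' @rdname PermutationResult-class
#' @export
setMethod("empiricalP", "PermutationResult", function(x) x@empiricalP)

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: observed %.4f, p = %.6g (%d permutations)\n",
    object@observed, object@empiricalP, object@nPermutations))
})

#' Dump permuted scores for diagnostics
#' @param result a \linkS4class{PermutationResult}.
#' @param path output TSV.
#' @export
writePermutedScores <- function(result, path) {
  utils::write.table(
    data.frame(permutation = seq_len(result@nPermutations),
               score = result@permuted),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
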