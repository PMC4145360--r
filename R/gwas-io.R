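#' @include AllGenerics.R
#' @importFrom GenomicRanges GRanges findOverlaps resize
#' @importFrom GenomeInfoDb seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
#'   rowData colData
#' @importFrom utils read.table write.table
NULL

# ---- GenotypeData ----------------------------------------------------------

#' Construct a GenotypeData object
#'
#' @param dosage integer matrix of minor-allele counts, SNPs as rows and
#'   samples as columns (NA = missing).
#' @param snpInfo either a \link[GenomicRanges]{GRanges} named by SNP id, or
#'   a data.frame with columns \code{snp_id}, \code{chromosome},
#'   \code{position} (1-based).  \code{NULL} assigns placeholder positions
#'   1..m on chromosome "un" (window mapping then being meaningless).
#' @param sampleIds sample identifiers; defaults to \code{colnames(dosage)}.
#' @return a \linkS4class{GenotypeData}.
#' @export
GenotypeData <- function(dosage, snpInfo = NULL, sampleIds = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    stop("dosage must have SNP ids as rownames")
  if (is.null(sampleIds))
    stop("sample ids are required")
  colnames(dosage) <- sampleIds
  if (is.null(snpInfo)) {
    gr <- GRanges("un", IRanges(seq_len(nrow(dosage)), width = 1L))
    names(gr) <- rownames(dosage)
  } else if (is(snpInfo, "GRanges")) {
    gr <- snpInfo
    if (is.null(names(gr))) stop("snpInfo GRanges must be named by SNP id")
    gr <- gr[rownames(dosage)]
  } else {
    snpInfo <- as.data.frame(snpInfo)
    if (!all(c("snp_id", "chromosome", "position") %in% names(snpInfo)))
      stop("snpInfo needs columns snp_id, chromosome, position")
    if (any(snpInfo$position < 1))
      stop("SNP positions must be >= 1")
    idx <- match(rownames(dosage), snpInfo$snp_id)
    if (anyNA(idx))
      stop("snpInfo is missing SNPs: ",
           paste(rownames(dosage)[is.na(idx)], collapse = ", "))
    snpInfo <- snpInfo[idx, ]
    gr <- GRanges(as.character(snpInfo$chromosome),
                  IRanges(snpInfo$position, width = 1L))
    names(gr) <- snpInfo$snp_id
  }
  se <- SummarizedExperiment(assays = list(dosage = dosage), rowRanges = gr)
  new("GenotypeData", se)
}

#' @rdname GenotypeData-class
#' @export
setMethod("dosages", "GenotypeData", function(x) assay(x, "dosage"))

#' @rdname GenotypeData-class
#' @export
setMethod("snpIds", "GenotypeData", function(x) rownames(x))

#' @rdname GenotypeData-class
#' @export
setMethod("sampleIds", "GenotypeData", function(x) colnames(x))

setMethod("show", "GenotypeData", function(object) {
  d <- dosages(object)
  cat("GenotypeData:", nrow(d), "SNPs x", ncol(d), "samples\n")
  cat("  missing genotypes:", sum(is.na(d)), "\n")
  chr <- unique(as.character(seqnames(rowRanges(object))))
  cat("  chromosomes:", paste(utils::head(chr, 5), collapse = ", "),
      if (length(chr) > 5) "..." else "", "\n")
})

# ---- readers ---------------------------------------------------------------

.readMapFile <- function(path) {
  mp <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) == 3L) {
    names(mp) <- c("chromosome", "snp_id", "position")
  } else if (ncol(mp) >= 4L) {
    mp <- mp[, 1:4]
    names(mp) <- c("chromosome", "snp_id", "cm", "position")
  } else stop("map file must have 3 or 4 columns")
  if (anyDuplicated(mp$snp_id))
    stop("duplicate snp_id in map file: ",
         paste(unique(mp$snp_id[duplicated(mp$snp_id)]), collapse = ", "))
  if (any(mp$position < 1)) stop("map positions must be >= 1")
  data.frame(snp_id = as.character(mp$snp_id),
             chromosome = as.character(mp$chromosome),
             position = as.integer(mp$position),
             stringsAsFactors = FALSE)
}

# Recode one SNP's allele pairs to minor-allele dosage.  The minor allele is
# the rarer of the two most frequent alleles in the loaded panel; at a
# frequency tie the lexicographically larger allele is deemed minor (so a
# written major/minor "A"/"B" panel round-trips).  "0", ".", "N" and any
# allele beyond the two most frequent become missing.
.recodeAlleles <- function(a1, a2) {
  miss <- c("0", ".", "N", "n")
  a1[a1 %in% miss] <- NA
  a2[a2 %in% miss] <- NA
  tab <- sort(table(c(a1, a2)), decreasing = TRUE)
  if (length(tab) == 0L) return(rep(NA_integer_, length(a1)))
  alleles <- names(tab)[seq_len(min(2L, length(tab)))]
  if (length(alleles) == 1L) {
    minor <- NA_character_; major <- alleles
  } else {
    f <- tab[alleles]
    if (f[1] == f[2]) {
      minor <- max(alleles); major <- min(alleles)
    } else {
      minor <- alleles[2]; major <- alleles[1]
    }
  }
  known <- function(a) is.na(a) | a %in% alleles
  bad <- !(known(a1) & known(a2)) | is.na(a1) | is.na(a2)
  d <- (!is.na(a1) & a1 %in% minor) + (!is.na(a2) & a2 %in% minor)
  d[bad] <- NA_integer_
  as.integer(d)
}

#' Read genotypes from PLINK .ped/.map or a dosage table
#'
#' For \code{format = "ped"}, \code{path} is the .ped file and
#' \code{mapPath} (default: same path with extension .map) supplies SNP ids
#' and 1-based positions; allele pairs are recoded to minor-allele counts
#' per SNP from the loaded panel (tie at frequency 0.5: the
#' lexicographically larger allele is minor), with "0"/"."/"N" and any
#' allele beyond the two most frequent treated as missing.  For
#' \code{format = "dosage"}, \code{path} is a TSV with a \code{sample_id}
#' column followed by one 0/1/2/NA column per SNP; an optional
#' \code{mapPath} supplies coordinates.
#'
#' @param path input file.
#' @param format "ped" or "dosage".
#' @param mapPath optional .map file.
#' @return a \linkS4class{GenotypeData}.
#' @export
readGenotypes <- function(path, format = c("ped", "dosage"), mapPath = NULL) {
  format <- match.arg(format)
  if (format == "ped") {
    if (is.null(mapPath)) mapPath <- sub("\\.ped$", ".map", path)
    snpInfo <- .readMapFile(mapPath)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    m <- nrow(snpInfo)
    want <- 6L + 2L * m
    nf <- lengths(toks)
    if (any(nf != want))
      stop(sprintf("malformed .ped line %d: %d fields, expected %d",
                   which(nf != want)[1], nf[nf != want][1], want))
    ped <- do.call(rbind, toks)
    ids <- ped[, 2]
    if (anyDuplicated(ids))
      stop("duplicate sample id in .ped: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    dosage <- matrix(NA_integer_, nrow = m, ncol = length(ids),
                     dimnames = list(snpInfo$snp_id, ids))
    for (j in seq_len(m)) {
      dosage[j, ] <- .recodeAlleles(ped[, 5L + 2L * j], ped[, 6L + 2L * j])
    }
    GenotypeData(dosage, snpInfo)
  } else {
    tb <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, check.names = FALSE)
    if (names(tb)[1] != "sample_id")
      stop("dosage table must start with a sample_id column")
    ids <- as.character(tb$sample_id)
    if (anyDuplicated(ids))
      stop("duplicate sample id: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    d <- as.matrix(tb[, -1, drop = FALSE])
    if (is.character(d)) {
      bad <- !is.na(d) & d != "NA" & !grepl("^[012]$", d)
      if (any(bad)) {
        idx <- which(bad, arr.ind = TRUE)[1, ]
        stop(sprintf("malformed dosage at line %d, SNP %s: '%s'",
                     idx[1] + 1L, colnames(d)[idx[2]], d[bad][1]))
      }
      d[d == "NA"] <- NA
      storage.mode(d) <- "integer"
    }
    if (any(!is.na(d) & !(d %in% c(0, 1, 2)))) {
      bad <- which(!is.na(d) & !(d %in% c(0, 1, 2)), arr.ind = TRUE)[1, ]
      stop(sprintf("malformed dosage at line %d, SNP %s",
                   bad[1] + 1L, colnames(d)[bad[2]]))
    }
    dosage <- t(d)
    colnames(dosage) <- ids
    if (anyDuplicated(rownames(dosage)))
      stop("duplicate snp_id in dosage table")
    snpInfo <- if (is.null(mapPath)) NULL else .readMapFile(mapPath)
    GenotypeData(dosage, snpInfo)
  }
}

#' Write genotypes to disk
#'
#' \code{format = "dosage"} writes one TSV (plus a .map when \code{prefix}
#' coordinates exist); \code{format = "ped"} writes \code{prefix}.ped and
#' \code{prefix}.map, encoding the major allele as "A" and the minor as
#' "B" and missing genotypes as "0 0".
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param prefix output path prefix (extension added).
#' @param format "dosage" or "ped".
#' @return the paths written, invisibly.
#' @export
writeGenotypes <- function(x, prefix, format = c("dosage", "ped")) {
  format <- match.arg(format)
  gr <- rowRanges(x)
  mp <- data.frame(chromosome = as.character(seqnames(gr)),
                   snp_id = names(gr), cm = 0,
                   position = GenomicRanges::start(gr))
  d <- dosages(x)
  if (format == "dosage") {
    path <- paste0(prefix, ".tsv")
    tb <- data.frame(sample_id = colnames(d), t(d), check.names = FALSE)
    write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
    mapPath <- paste0(prefix, ".map")
    write.table(mp, mapPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(c(path, mapPath))
  } else {
    pedPath <- paste0(prefix, ".ped")
    mapPath <- paste0(prefix, ".map")
    write.table(mp, mapPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    code <- c("A A", "A B", "B B")
    rows <- vapply(seq_len(ncol(d)), function(s) {
      g <- d[, s]
      al <- ifelse(is.na(g), "0 0", code[g + 1L])
      paste(c(colnames(d)[s], colnames(d)[s], "0", "0", "0", "-9", al),
            collapse = " ")
    }, character(1))
    writeLines(rows, pedPath)
    invisible(c(pedPath, mapPath))
  }
}

#' Read a quantitative phenotype
#'
#' Two-column TSV (sample_id, value), with or without a header line.
#' Values must be finite; duplicate sample ids are an error.
#'
#' @param path input file.
#' @return a named numeric vector.
#' @export
readPhenotype <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t| +")[[1]]
  hasHeader <- length(first) >= 2 &&
    is.na(suppressWarnings(as.numeric(first[2])))
  tb <- read.table(path, header = hasHeader, stringsAsFactors = FALSE)
  if (ncol(tb) < 2) stop("phenotype file needs two columns")
  ids <- as.character(tb[[1]])
  vals <- suppressWarnings(as.numeric(tb[[2]]))
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- which(!is.finite(vals) | is.na(vals))[1]
    stop(sprintf("non-finite phenotype value '%s' for sample %s",
                 as.character(tb[[2]][bad]), ids[bad]))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sample id: ", paste(dup, collapse = ", "))
  stats::setNames(vals, ids)
}

#' Write a phenotype vector
#' @param phenotype named numeric vector.
#' @param path output TSV.
#' @export
writePhenotype <- function(phenotype, path) {
  write.table(data.frame(sample_id = names(phenotype), value = phenotype),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations from BED
#'
#' BED3+ (chrom, chromStart, chromEnd, name), 0-based half-open on disk;
#' returned as a 1-based \link[GenomicRanges]{GRanges} named by gene id and
#' sorted by (chromosome, start).  Zero- or negative-length intervals are an
#' error.
#'
#' @param path BED file.
#' @return a named, sorted GRanges.
#' @export
readGeneAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(mcols(gr)$name) || anyNA(mcols(gr)$name))
    stop("BED file must carry gene names in column 4")
  if (any(GenomicRanges::width(gr) < 1))
    stop("zero-length gene interval for ",
         paste(mcols(gr)$name[GenomicRanges::width(gr) < 1], collapse = ", "))
  names(gr) <- mcols(gr)$name
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write gene annotations to BED
#' @param genes named GRanges.
#' @param path output BED path.
#' @export
writeGeneAnnotation <- function(genes, path) {
  mcols(genes)$name <- names(genes)
  rtracklayer::export(genes, path, format = "BED")
  invisible(path)
}

# ---- SNP-to-gene mapping ---------------------------------------------------

#' Map SNPs to genes by a symmetric window
#'
#' A SNP maps to a gene iff it lies on the gene's chromosome and its
#' 1-based position falls within \code{[start - windowBp, end + windowBp]}
#' inclusive, windows clipped at coordinate 1.  A SNP may map to several
#' genes whose windows overlap, and a gene to many SNPs.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param genes named GRanges of gene spans (1-based, from
#'   [readGeneAnnotation()]).
#' @param windowBp window size in bp on each side (default 500000, i.e.
#'   500 kb up- and downstream).
#' @return a \linkS4class{SnpGeneMap}.
#' @export
mapSnpsToGenes <- function(genotypes, genes, windowBp = 500000L) {
  if (length(windowBp) != 1 || windowBp < 0)
    stop("windowBp must be a single non-negative number")
  if (is.null(names(genes))) stop("genes must be named by gene id")
  snps <- rowRanges(genotypes)
  win <- genes
  GenomicRanges::start(win) <- pmax(1L, GenomicRanges::start(genes) - windowBp)
  GenomicRanges::end(win) <- GenomicRanges::end(genes) + windowBp
  # suppressed: disjoint seqlevels between panel and annotation are a
  # legitimate no-overlap situation, not a user error
  hits <- suppressWarnings(findOverlaps(snps, win, ignore.strand = TRUE))
  spos <- GenomicRanges::start(snps)[queryHits(hits)]
  gstart <- GenomicRanges::start(genes)[subjectHits(hits)]
  gend <- GenomicRanges::end(genes)[subjectHits(hits)]
  dist <- pmax(0L, gstart - spos, spos - gend)
  tb <- data.frame(gene_id = names(genes)[subjectHits(hits)],
                   snp_id = names(snps)[queryHits(hits)],
                   distance_bp = as.integer(dist),
                   stringsAsFactors = FALSE)
  tb <- tb[order(tb$gene_id, tb$snp_id), , drop = FALSE]
  rownames(tb) <- NULL
  new("SnpGeneMap", table = tb, windowBp = as.numeric(windowBp))
}

#' @rdname SnpGeneMap-class
#' @export
setMethod("mapTable", "SnpGeneMap", function(x) x@table)

#' @rdname SnpGeneMap-class
#' @export
setMethod("geneIds", "SnpGeneMap",
          function(x) sort(unique(x@table$gene_id)))

#' @rdname SnpGeneMap-class
#' @export
setMethod("snpIds", "SnpGeneMap", function(x) sort(unique(x@table$snp_id)))

#' @rdname SnpGeneMap-class
#' @export
setMethod("snpsOfGene", "SnpGeneMap", function(x, gene)
  sort(x@table$snp_id[x@table$gene_id == gene]))

#' @rdname SnpGeneMap-class
#' @export
setMethod("genesOfSnp", "SnpGeneMap", function(x, snp)
  sort(x@table$gene_id[x@table$snp_id == snp]))

setMethod("show", "SnpGeneMap", function(object) {
  cat("SnpGeneMap:", nrow(object@table), "gene-SNP pairs,",
      length(geneIds(object)), "genes,",
      length(snpIds(object)), "SNPs; window", object@windowBp, "bp\n")
})

#' Write / read a SnpGeneMap as TSV
#' @param map a \linkS4class{SnpGeneMap}.
#' @param path TSV path.
#' @export
writeSnpGeneMap <- function(map, path) {
  write.table(mapTable(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeSnpGeneMap
#' @param windowBp window recorded in the object (metadata only).
#' @export
readSnpGeneMap <- function(path, windowBp = 500000L) {
  tb <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  tb$gene_id <- as.character(tb$gene_id)
  tb$snp_id <- as.character(tb$snp_id)
  new("SnpGeneMap", table = tb, windowBp = as.numeric(windowBp))
}
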