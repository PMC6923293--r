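#' Read a tumor-region table
#'
#' TSV with a header line containing at least \code{region_id}, \code{x},
#' \code{y} and \code{phenotype}; an optional \code{quadrant} column is kept.
#' Lines starting with \code{#} are comments. \code{NA} marks missing values.
#' Row order of the file is preserved.
#'
#' @param path file path.
#' @return data.frame with columns \code{region_id}, \code{x}, \code{y},
#'   \code{quadrant}, \code{phenotype}.
#' @export
readRegionTable <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", check.names = FALSE,
                    na.strings = c("NA", ""))
  need <- c("region_id", "x", "y", "phenotype")
  miss <- setdiff(need, colnames(raw))
  if (length(miss))
    stop("region table '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop("non-numeric '", col, "' value in region table row ", bad[1],
           ": '", raw[[col]][bad[1]], "'")
    v
  }
  data.frame(region_id = raw$region_id,
             x = num("x"), y = num("y"),
             quadrant = if ("quadrant" %in% colnames(raw)) raw$quadrant
                        else NA_character_,
             phenotype = num("phenotype"),
             stringsAsFactors = FALSE)
}

#' Write a tumor-region table
#'
#' Deterministic column order (\code{region_id x y quadrant phenotype}) with
#' a versioned comment header; round-trips through
#' \code{\link{readRegionTable}} without loss.
#'
#' @param regions data.frame as returned by \code{\link{readRegionTable}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRegionTable <- function(regions, path) {
  cols <- c("region_id", "x", "y", "quadrant", "phenotype")
  if (!"quadrant" %in% colnames(regions)) regions$quadrant <- NA_character_
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.toolHeader(), con)
  write.table(regions[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix
#'
#' Two formats. \code{"tsv"}: loci as rows (first column \code{locus_id},
#' optional \code{chrom}), regions as columns, calls in \{0, 1, NA\}.
#' \code{"vcf"}: one sample per region; any genotype containing a
#' non-reference allele collapses to mutant (1), \code{./.} to missing —
#' regions are treated as effectively haploid clones carrying or lacking each
#' somatic mutation. Allele codes are abstract wild-type/mutant labels, not
#' nucleotides.
#'
#' @param path file path.
#' @param format "tsv" or "vcf".
#' @return Integer matrix (loci x regions, values 0/1/NA) with locus
#'   rownames, region colnames and a \code{"chrom"} attribute (per-locus
#'   chromosome labels, NA when absent).
#' @export
readGenotypeMatrix <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(.readGenotypeVcf(path))
  raw <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", check.names = FALSE,
                    na.strings = c("NA", ""))
  if (!"locus_id" %in% colnames(raw))
    stop("genotype TSV '", path, "' lacks required column 'locus_id'")
  chrom <- if ("chrom" %in% colnames(raw)) raw$chrom else
    rep(NA_character_, nrow(raw))
  cells <- raw[, setdiff(colnames(raw), c("locus_id", "chrom")),
               drop = FALSE]
  m <- as.matrix(cells)
  bad <- which(!(m %in% c("0", "1") | is.na(m)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("genotype call outside {0,1,NA} at locus '",
         raw$locus_id[bad[1, 1]], "', region '", colnames(m)[bad[1, 2]],
         "': '", m[bad[1, , drop = FALSE]], "'")
  g <- matrix(as.integer(m), nrow = nrow(m),
              dimnames = list(raw$locus_id, colnames(m)))
  attr(g, "chrom") <- chrom
  g
}

## VCF ingestion via vcfR; only the GT field is used.
.readGenotypeVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  alleles <- function(s) strsplit(s, "[/|]")[[1]]
  call1 <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    a <- alleles(s)
    if (all(a == ".")) return(NA_integer_)
    if (any(a != "0" & a != ".")) 1L else 0L
  }
  g <- matrix(vapply(gt, call1, integer(1)), nrow = nrow(gt),
              dimnames = list(ids, colnames(gt)))
  attr(g, "chrom") <- as.character(fix[, "CHROM"])
  g
}

#' Write a genotype matrix as TSV
#'
#' @param genotypes integer matrix as returned by
#'   \code{\link{readGenotypeMatrix}} (a \code{"chrom"} attribute is written
#'   as a \code{chrom} column when any label is non-missing).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeMatrix <- function(genotypes, path) {
  chrom <- attr(genotypes, "chrom")
  df <- data.frame(locus_id = rownames(genotypes), stringsAsFactors = FALSE)
  if (!is.null(chrom) && any(!is.na(chrom))) df$chrom <- chrom
  df <- cbind(df, as.data.frame(genotypes, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.toolHeader(), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an explicit adjacency edge list
#'
#' TSV with columns \code{region_a} and \code{region_b}, one undirected pair
#' per line; comment lines start with \code{#}.
#'
#' @param path file path.
#' @return data.frame with columns \code{region_a}, \code{region_b}.
#' @export
readAdjacencyList <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", check.names = FALSE)
  miss <- setdiff(c("region_a", "region_b"), colnames(raw))
  if (length(miss))
    stop("adjacency list '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  raw[, c("region_a", "region_b")]
}

#' Write an adjacency graph as an edge-list TSV
#'
#' @param graph a \linkS4class{RegionGraph}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAdjacencyList <- function(graph, path) {
  e <- graphEdges(graph)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.toolHeader(), con)
  write.table(data.frame(region_a = e$from, region_b = e$to,
                         distance = e$distance),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
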