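## Readers and writers for the package's tabular dialects: multi-tree
## newick files, SNP matrices (documented TSV dialect and minimal VCF),
## grouping and trait tables.

#' Read / write newick gene-tree files (one tree per line)
#'
#' @param file path.
#' @return a multiPhylo.
#' @export
readGeneTrees <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  trees <- lapply(lines, parseNewick)
  class(trees) <- "multiPhylo"
  trees
}

#' @rdname readGeneTrees
#' @param trees multiPhylo or list of phylo.
#' @export
writeGeneTrees <- function(trees, file) {
  ape::write.tree(trees, file = file)
  invisible(file)
}

#' Read / write extended-newick network files (one network per line)
#'
#' @param file path.
#' @param lengthUnit recorded unit.
#' @return list of SpeciesNetwork objects.
#' @export
readNetworks <- function(file, lengthUnit = "unknown") {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parseExtendedNewick, lengthUnit = lengthUnit)
}

#' @rdname readNetworks
#' @param nets list of SpeciesNetwork objects (or one).
#' @export
writeNetworks <- function(nets, file) {
  if (is(nets, "SpeciesNetwork")) nets <- list(nets)
  writeLines(vapply(nets, writeExtendedNewick, character(1)), file)
  invisible(file)
}

#' Read / write the SNP TSV dialect
#'
#' Columns: \code{locus}, \code{pos}, \code{ref}, \code{alt}, then one
#' column per individual holding the derived-allele count (0/1 haploid,
#' 0/1/2 diploid) or \code{NA}/\code{.} for missing.
#'
#' @param file path.
#' @param ploidy 1 or 2.
#' @return a \linkS4class{SNPMatrix}.
#' @export
readSnpTsv <- function(file, ploidy = 1L) {
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", "."),
                   colClasses = c(locus = "character", ref = "character",
                                  alt = "character"))
  need <- c("locus", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("SNP TSV needs columns ", paste(need, collapse = ", "))
  }
  inds <- setdiff(names(df), need)
  g <- t(as.matrix(df[, inds, drop = FALSE]))
  storage.mode(g) <- "integer"
  rownames(g) <- inds
  snpMatrix(g, df[, need], ploidy = ploidy)
}

#' @rdname readSnpTsv
#' @param x a SNPMatrix.
#' @export
writeSnpTsv <- function(x, file) {
  df <- cbind(x@sites, as.data.frame(t(x@genotypes), check.names = FALSE))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(file)
}

#' Read a biallelic SNP matrix from a VCF file
#'
#' Minimal VCF reader for genotype-only, uncompressed files: keeps
#' biallelic SNP records, parses GT fields (\code{/} or \code{|}
#' separated; \code{.} = missing) into derived-allele counts, and uses
#' CHROM as the locus id.  Multiallelic records are dropped.
#'
#' @param file path to an uncompressed VCF.
#' @param ploidy expected ploidy (1 or 2).
#' @return a \linkS4class{SNPMatrix}.
#' @export
readSnpVcf <- function(file, ploidy = 2L) {
  lines <- readLines(file)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in VCF")
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t")[[1]]
  inds <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  locus <- character(0); pos <- integer(0); ref <- character(0); alt <- character(0)
  rows <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    if (grepl(",", f[5], fixed = TRUE)) next          # multiallelic
    if (nchar(f[4]) != 1L || nchar(f[5]) != 1L) next  # indel
    gt <- sub(":.*", "", f[-(1:9)])
    alleles <- strsplit(gt, "[/|]")
    cnt <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_integer_)
      sum(as.integer(a))
    }, integer(1))
    locus <- c(locus, f[1]); pos <- c(pos, as.integer(f[2]))
    ref <- c(ref, f[4]); alt <- c(alt, f[5])
    rows[[length(rows) + 1L]] <- cnt
  }
  if (!length(rows)) stop("no biallelic SNP records in VCF")
  g <- do.call(cbind, rows)
  rownames(g) <- inds
  snpMatrix(g, data.frame(locus = locus, pos = pos, ref = ref, alt = alt,
                          stringsAsFactors = FALSE), ploidy = ploidy)
}

#' Write a SNPMatrix as a minimal VCF
#'
#' @param x a SNPMatrix.
#' @param file output path.
#' @export
writeSnpVcf <- function(x, file) {
  g <- x@genotypes
  s <- x@sites
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=retic",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g)), collapse = "\t")), con)
  for (j in seq_len(ncol(g))) {
    gt <- vapply(g[, j], function(v) {
      if (is.na(v)) return(if (x@ploidy == 2L) "./." else ".")
      if (x@ploidy == 1L) as.character(v)
      else paste(c(rep("1", v), rep("0", 2 - v)), collapse = "/")
    }, character(1))
    writeLines(paste(c(s$locus[j], s$pos[j], ".", s$ref[j], s$alt[j], ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(file)
}

#' Read a grouping table
#'
#' TSV with columns \code{taxon} and \code{group}; groups named P1..P4
#' plus optionally \code{outgroup}.  An optional \code{individual} column
#' populates the individual-to-taxon map.
#'
#' @param file path.
#' @return a \linkS4class{GroupingConfig}.
#' @export
readGrouping <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("taxon", "group") %in% names(df))) {
    stop("grouping TSV needs columns taxon, group")
  }
  gl <- split(df$taxon, df$group)
  for (g in c("P1", "P2", "P3", "P4")) {
    if (is.null(gl[[g]])) stop("grouping must define group ", g)
  }
  indivMap <- character(0)
  if ("individual" %in% names(df)) {
    indivMap <- setNames(df$taxon, df$individual)
  }
  groupingConfig(gl$P1, gl$P2, gl$P3, gl$P4,
                 outgroup = if (is.null(gl$outgroup)) character(0) else gl$outgroup,
                 indivMap = indivMap)
}

#' Read a discrete-trait table
#'
#' TSV with a \code{taxon} column and one column per trait (e.g.
#' \code{longevity}, \code{fruit}, \code{environment}) holding character
#' states.
#'
#' @param file path.
#' @return data.frame.
#' @export
readTraitTable <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  if (!"taxon" %in% names(df)) stop("trait table needs a 'taxon' column")
  df
}
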