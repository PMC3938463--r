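#' Read a GeneNetwork-style .geno genotype file
#'
#' Parses the tab-separated genotype dialect used by GeneNetwork for RI
#' panels: optional metadata lines prefixed with `@` (ignored), optional
#' `#` comment lines, then a header row `Chr Locus cM Mb <strain> ...`
#' followed by one row per marker. Genotype codes are `B` (C57BL/6J
#' homozygote), `D` (DBA/2J homozygote), `H` (heterozygote) and `U`
#' (unknown); `H`/`U` are preserved verbatim, never imputed.
#'
#' @param path Path to a .geno (or equivalently structured TSV) file.
#' @return A `geno` object: a list with components `lines` (strain names),
#'   `map` (data.frame with `marker`, `chr`, `cM`, `Mb`, sorted by
#'   chromosome then physical position) and `calls` (character matrix,
#'   lines x markers, codes in B/D/H/U).
#' @details Positions are 1-based megabase coordinates, stored verbatim
#'   (no genome-build lift-over). Markers must be strictly increasing in
#'   Mb within each chromosome; a violation is a format error naming the
#'   offending marker. Duplicate marker identifiers are rejected.
#' @seealso [write_geno()], [dosage_grid()]
#' @export
read_geno <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*(@|#)", raw) & nzchar(trimws(raw))]
  if (length(raw) < 1L) stop("genotype file is empty: ", path)
  fields <- strsplit(raw, "\t", fixed = TRUE)
  header <- trimws(fields[[1L]])
  need <- c("Chr", "Locus", "cM", "Mb")
  if (!all(need %in% header[1:4])) {
    stop("genotype header must start with columns Chr, Locus, cM, Mb")
  }
  lines_ids <- header[-(1:4)]
  if (length(lines_ids) < 1L) stop("genotype file names no strains")
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != length(header))) {
    stop("genotype row ", which(nf != length(header))[1L],
         " has ", nf[nf != length(header)][1L], " fields, expected ",
         length(header))
  }
  body <- lapply(body, trimws)
  map <- data.frame(
    marker = vapply(body, `[[`, "", 2L),
    chr = vapply(body, `[[`, "", 1L),
    cM = as.numeric(vapply(body, `[[`, "", 3L)),
    Mb = as.numeric(vapply(body, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(map$marker)) {
    stop("duplicate marker id: ", map$marker[duplicated(map$marker)][1L])
  }
  for (ch in unique(map$chr)) {
    mb <- map$Mb[map$chr == ch]
    if (any(diff(mb) <= 0)) {
      bad <- map$marker[map$chr == ch][which(diff(mb) <= 0)[1L] + 1L]
      stop("non-monotone Mb position on chromosome ", ch,
           " at marker ", bad)
    }
  }
  calls <- t(vapply(body, function(f) toupper(f[-(1:4)]),
                    character(length(lines_ids))))
  if (length(lines_ids) == 1L) calls <- matrix(calls, ncol = 1L)
  bad_codes <- setdiff(unique(as.vector(calls)), c("B", "D", "H", "U"))
  if (length(bad_codes)) {
    stop("unknown genotype code(s): ", paste(bad_codes, collapse = ", "))
  }
  ord <- order(chr_rank(map$chr), map$Mb)
  map <- map[ord, , drop = FALSE]
  calls <- t(calls[ord, , drop = FALSE])
  dimnames(calls) <- list(lines_ids, map$marker)
  rownames(map) <- NULL
  new_geno(lines_ids, map, calls)
}

new_geno <- function(lines, map, calls) {
  structure(list(lines = lines, map = map, calls = calls), class = "geno")
}

#' Write a genotype matrix in the .geno dialect
#'
#' Inverse of [read_geno()]: a file written here and read back yields an
#' identical `geno` object.
#'
#' @param geno A `geno` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geno <- function(geno, path) {
  stopifnot(inherits(geno, "geno"))
  header <- paste(c("Chr", "Locus", "cM", "Mb", geno$lines), collapse = "\t")
  rows <- vapply(seq_len(nrow(geno$map)), function(i) {
    paste(c(geno$map$chr[i], geno$map$marker[i],
            format(geno$map$cM[i], trim = TRUE, digits = 15),
            format(geno$map$Mb[i], trim = TRUE, digits = 15),
            geno$calls[, i]), collapse = "\t")
  }, "")
  writeLines(c("@type:riset", header, rows), path)
  invisible(path)
}

#' @export
print.geno <- function(x, ...) {
  cat("RI-panel genotypes:", length(x$lines), "lines x",
      nrow(x$map), "markers on",
      length(unique(x$map$chr)), "chromosome(s)\n")
  tab <- table(factor(as.vector(x$calls), levels = c("B", "D", "H", "U")))
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read a BED-like gene annotation table
#'
#' Five tab-separated columns without a header: chromosome, start (Mb),
#' end (Mb), gene symbol, and a 0/1 flag marking genes carrying a
#' non-synonymous SNP segregating between the parental strains.
#' Coordinates are 1-based, inclusive, megabase floats.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with columns `gene_id`, `chr`, `start_Mb`,
#'   `end_Mb`, `has_nssnp` (logical), sorted by chromosome then start.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    return(data.frame(gene_id = character(), chr = character(),
                      start_Mb = numeric(), end_Mb = numeric(),
                      has_nssnp = logical(), stringsAsFactors = FALSE))
  }
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", "numeric", "numeric",
                                        "character", "integer"),
                         stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = d[[4L]], chr = d[[1L]],
                    start_Mb = d[[2L]], end_Mb = d[[3L]],
                    has_nssnp = d[[5L]] != 0L, stringsAsFactors = FALSE)
  bad <- ann$start_Mb > ann$end_Mb
  if (any(bad)) {
    stop("annotation start > end for gene ", ann$gene_id[bad][1L])
  }
  ann <- ann[order(chr_rank(ann$chr), ann$start_Mb), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write a gene annotation table (BED-like TSV)
#'
#' @param annotation Data.frame as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  d <- data.frame(annotation$chr, annotation$start_Mb, annotation$end_Mb,
                  annotation$gene_id, as.integer(annotation$has_nssnp))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write an animal-level phenotype table
#'
#' Long-format TSV with header `animal_id line_id sex trait value`;
#' `sex` is `F` or `M`.
#'
#' @param path Path to the phenotype TSV.
#' @return Data.frame with those five columns.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("animal_id", "line_id", "sex", "trait", "value")
  if (!all(need %in% names(d))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(d$sex), c("F", "M"))
  if (length(bad)) stop("unknown sex code(s): ", paste(bad, collapse = ", "))
  d[, need]
}

#' @rdname read_phenotypes
#' @param pheno Phenotype data.frame to write.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a strain x transcript expression matrix
#'
#' On disk the matrix is transcripts x strains (one row per transcript,
#' header row of strain names, first column `transcript_id`), the layout
#' GeneNetwork exports. In memory the package works with the transpose:
#' strains in rows, transcripts in columns.
#'
#' @param path Path to the expression TSV.
#' @return Numeric matrix, strains x transcripts, with dimnames.
#' @export
read_expression <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1L] != "transcript_id") {
    stop("expression table must have first column transcript_id")
  }
  m <- t(as.matrix(d[, -1L, drop = FALSE]))
  colnames(m) <- d$transcript_id
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @param expr Strain x transcript matrix to write.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(transcript_id = colnames(expr),
                  t(expr), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Published pQTL and region-summary tables bundled as fixtures
#'
#' Returns the published summary tables for the CCl4 liver-fibrosis BXD
#' study that this package's pipeline re-implements: the table of
#' genome-wide significant pQTLs (phenotype, chromosome, maximum LRS,
#' 1.5-LOD support interval, additive allele effect, dataset) and the
#' nine-region summary of the pQTL/eQTL dissection funnel (region
#' coordinates, gene and eQTL counts). Values are stored verbatim as
#' printed. The printed grand totals are kept in a separate component:
#' for two columns (eQTLs, cisQTGs) the printed totals (68, 85) do not
#' equal the printed row sums (62, 88), and the fixtures never reconcile
#' the two.
#'
#' @return A list with `table1` (7-row data.frame of pQTLs), `table2`
#'   (9-row data.frame of region summaries) and `table2_totals`
#'   (the printed totals row as a list).
#' @export
load_printed_tables <- function() {
  p1 <- system.file("extdata", "published_pqtls.tsv", package = "fibroqtl")
  p2 <- system.file("extdata", "published_regions.tsv", package = "fibroqtl")
  p3 <- system.file("extdata", "published_region_totals.tsv",
                    package = "fibroqtl")
  t1 <- utils::read.table(p1, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = c(
                            phenotype = "character", chr = "character",
                            lrs_max = "numeric", snp_max = "character",
                            interval_lo_Mb = "numeric",
                            interval_hi_Mb = "numeric",
                            additive_effect = "numeric",
                            dataset = "character"))
  t2 <- utils::read.table(p2, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = c(
                            chr = "character", region_lo_Mb = "numeric",
                            region_hi_Mb = "numeric",
                            phenotypes = "character", lrs_max = "numeric",
                            size_Mb = "numeric", n_genes = "integer",
                            n_eqtls = "integer", n_cisqtls = "integer",
                            n_cisqtgs = "integer"))
  tot <- utils::read.table(p3, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(nrow(t2) == 9L)
  list(table1 = t1, table2 = t2, table2_totals = as.list(tot[1L, ]))
}

# chromosome ordering: numeric labels first in numeric order, then X, Y,
# then anything else alphabetically
chr_rank <- function(chr) {
  num <- suppressWarnings(as.numeric(chr))
  r <- ifelse(!is.na(num), num,
              ifelse(chr == "X", 1e3, ifelse(chr == "Y", 1e3 + 1, NA)))
  other <- is.na(r)
  if (any(other)) r[other] <- 2e3 + match(chr[other], sort(unique(chr[other])))
  r
}
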