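#' @importFrom GenomicRanges GRanges mcols mcols<- seqnames start
#' @importFrom S4Vectors DataFrame
#' @importFrom utils read.table write.table
NULL

.VALID_BASES <- c("A", "C", "G", "T")

.validateSnpFrame <- function(df, file = "<connection>") {
  ln <- seq_len(nrow(df)) + 1L  # 1 header line
  pos <- suppressWarnings(as.numeric(df$pos))
  bad <- which(is.na(pos) | pos != floor(pos))
  if (length(bad))
    stop("malformed SNP row(s) in ", file, " at line(s) ",
         paste(ln[bad], collapse = ", "), ": non-integer pos", call. = FALSE)
  if (any(pos < 1))
    stop("SNP positions must be 1-based (pos >= 1); offending line(s): ",
         paste(ln[pos < 1], collapse = ", "), call. = FALSE)
  df$pos <- as.integer(pos)
  for (col in c("col_allele", "cvi_allele")) {
    df[[col]] <- toupper(trimws(df[[col]]))
    bad <- which(!df[[col]] %in% .VALID_BASES)
    if (length(bad))
      stop("invalid ", col, " (must be A/C/G/T) at line(s) ",
           paste(ln[bad], collapse = ", "), call. = FALSE)
  }
  same <- which(df$col_allele == df$cvi_allele)
  if (length(same))
    stop("col_allele equals cvi_allele at line(s) ",
         paste(ln[same], collapse = ", "), call. = FALSE)
  # exact duplicate rows collapse; conflicting alleles at one site are an error
  key <- paste(df$chrom, df$pos)
  allele_key <- paste(key, df$col_allele, df$cvi_allele)
  conflict <- tapply(allele_key, key, function(k) length(unique(k)) > 1L)
  if (any(conflict))
    stop("conflicting alleles at duplicated site(s): ",
         paste(names(conflict)[conflict], collapse = ", "), call. = FALSE)
  full_key <- paste(allele_key, df$gene_id)
  dup <- duplicated(full_key)
  df <- df[!dup, , drop = FALSE]
  multi <- tapply(df$gene_id, paste(df$chrom, df$pos),
                  function(g) length(unique(g)) > 1L)
  if (any(multi))
    warning(sum(multi), " SNP site(s) assigned to multiple genes; ",
            "counts will contribute to every listed gene", call. = FALSE)
  df[order(df$chrom, df$pos), , drop = FALSE]
}

.snpFrameToGRanges <- function(df) {
  GRanges(seqnames = df$chrom,
          ranges = IRanges::IRanges(start = df$pos, width = 1L),
          col_allele = df$col_allele,
          cvi_allele = df$cvi_allele,
          gene_id = df$gene_id)
}

#' Read a table of diagnostic SNP sites
#'
#' Each site links a genomic position to the two parental alleles that
#' distinguish the reference-genome parent (Col) from the alternate parent
#' (Cvi), plus the host gene. Two dialects are accepted: a TSV with header
#' \code{chrom pos col_allele cvi_allele gene_id}, and a VCF-like file whose
#' CHROM/POS/REF/ALT columns carry the Col (REF) and Cvi (ALT) alleles and
#' whose INFO field contains a \code{GENE=} tag.
#'
#' Coordinates are 1-based and fully closed (VCF convention). Exact duplicate
#' rows are collapsed; duplicated positions with conflicting alleles are an
#' error; a position listed under several genes is kept once per gene with a
#' warning (its reads count toward every listed gene).
#'
#' @param file path or connection.
#' @param dialect \code{"tsv"} (default) or \code{"vcf"}.
#' @return a \code{GRanges} of width-1 sites sorted by (chrom, pos), with
#'   metadata columns \code{col_allele}, \code{cvi_allele}, \code{gene_id}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tpos\tcol_allele\tcvi_allele\tgene_id",
#'              "Chr1\t100\tA\tG\tAT1G01010",
#'              "Chr1\t250\tC\tT\tAT1G01010"), tf)
#' readSnpTable(tf)
#' @export
readSnpTable <- function(file, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read.table(file, header = TRUE, sep = "\t",
                     colClasses = "character", quote = "",
                     comment.char = "")
    need <- c("chrom", "pos", "col_allele", "cvi_allele", "gene_id")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
      stop("SNP table ", file, " is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    df <- df[, need]
  } else {
    lines <- readLines(file)
    lines <- lines[!startsWith(lines, "##")]
    if (!length(lines) || !startsWith(lines[1L], "#CHROM"))
      stop("VCF-like input ", file, " lacks a #CHROM header line",
           call. = FALSE)
    header <- sub("^#", "", strsplit(lines[1L], "\t")[[1L]])
    body <- read.table(text = lines[-1L], sep = "\t",
                       colClasses = "character", quote = "",
                       comment.char = "")
    colnames(body) <- header[seq_len(ncol(body))]
    need <- c("CHROM", "POS", "REF", "ALT", "INFO")
    miss <- setdiff(need, colnames(body))
    if (length(miss))
      stop("VCF-like input is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    gene <- sub(".*(?:^|;)GENE=([^;]+).*", "\\1", body$INFO)
    no_gene <- !grepl("(^|;)GENE=", body$INFO)
    if (any(no_gene))
      stop("VCF-like rows without a GENE= INFO tag at line(s) ",
           paste(which(no_gene), collapse = ", "), call. = FALSE)
    df <- data.frame(chrom = body$CHROM, pos = body$POS,
                     col_allele = body$REF, cvi_allele = body$ALT,
                     gene_id = gene, stringsAsFactors = FALSE)
  }
  .snpFrameToGRanges(.validateSnpFrame(df, file = as.character(file)))
}

#' Write a SNP table as TSV
#'
#' @param sites a \code{GRanges} as returned by [readSnpTable()].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeSnpTable <- function(sites, file) {
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   pos = start(sites),
                   col_allele = mcols(sites)$col_allele,
                   cvi_allele = mcols(sites)$cvi_allele,
                   gene_id = mcols(sites)$gene_id)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.snpKey <- function(sites)
  paste(as.character(seqnames(sites)), start(sites),
        mcols(sites)$col_allele, mcols(sites)$cvi_allele)

#' Intersect a called SNP set with a reference SNP set
#'
#' Keeps the sites present in both sets with identical position and identical
#' Col/Cvi alleles, mirroring the filtering of de-novo variant calls against a
#' published polymorphism list. Gene annotation is taken from \code{called}.
#'
#' @param called,reference \code{GRanges} SNP tables ([readSnpTable()]).
#' @return the retained subset of \code{called}. An empty result is valid.
#' @export
intersectSnpSites <- function(called, reference) {
  called[.snpKey(called) %in% .snpKey(reference)]
}

#' Read per-SNP allele counts
#'
#' TSV with header
#' \code{library_id chrom pos col_reads cvi_reads other_reads}: for each SNP
#' position and library, the number of reads carrying the Col allele, the Cvi
#' allele, and any other base. \code{other_reads} never enter maternal or
#' paternal totals; they are retained for QC only.
#'
#' @param file path or connection.
#' @return a data.frame with the columns above; counts as integers.
#' @export
readSnpCounts <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  need <- c("library_id", "chrom", "pos",
            "col_reads", "cvi_reads", "other_reads")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("SNP count table ", file, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[, need]
  for (col in c("pos", "col_reads", "cvi_reads", "other_reads")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v))
      stop("non-integer ", col, " in ", file, " at line(s) ",
           paste(which(is.na(v)) + 1L, collapse = ", "), call. = FALSE)
    df[[col]] <- v
  }
  if (any(df$col_reads < 0L | df$cvi_reads < 0L | df$other_reads < 0L))
    stop("negative read counts in ", file, call. = FALSE)
  df
}

#' Write per-SNP allele counts as TSV
#'
#' @param counts data.frame as returned by [readSnpCounts()].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeSnpCounts <- function(counts, file) {
  write.table(counts, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Orient Col/Cvi allele counts to maternal/paternal
#'
#' The maternal allele of a site is the Col allele when the seed parent
#' (mother) of the cross is the reference-genome parent, and the Cvi allele
#' otherwise. Reads matching neither parental allele are dropped from the
#' oriented totals.
#'
#' @param counts per-SNP count data.frame ([readSnpCounts()]).
#' @param cross a [CrossDirection].
#' @param refParent genotype label of the reference-genome parent
#'   (default \code{"Col"}).
#' @return \code{counts} with \code{col_reads}/\code{cvi_reads} replaced by
#'   \code{maternal_reads}/\code{paternal_reads} and a \code{cross} label
#'   column; \code{other_reads} is retained for QC.
#' @examples
#' cnt <- data.frame(library_id = "L1", chrom = "Chr1", pos = 100L,
#'                   col_reads = 10L, cvi_reads = 4L, other_reads = 0L)
#' orientCounts(cnt, CrossDirection("Col", "Cvi"))   # maternal = 10
#' orientCounts(cnt, CrossDirection("Cvi", "Col"))   # maternal = 4
#' @export
orientCounts <- function(counts, cross, refParent = "Col") {
  stopifnot(is(cross, "CrossDirection"))
  if (!refParent %in% c(cross@mother, cross@father))
    stop("reference parent '", refParent,
         "' is neither mother nor father of cross ", crossLabel(cross),
         call. = FALSE)
  motherIsRef <- identical(cross@mother, refParent)
  out <- counts
  if (motherIsRef) {
    out$maternal_reads <- counts$col_reads
    out$paternal_reads <- counts$cvi_reads
  } else {
    out$maternal_reads <- counts$cvi_reads
    out$paternal_reads <- counts$col_reads
  }
  out$col_reads <- NULL
  out$cvi_reads <- NULL
  out$cross <- crossLabel(cross)
  out[, c("library_id", "cross", "chrom", "pos",
          "maternal_reads", "paternal_reads", "other_reads")]
}

#' Aggregate oriented per-SNP counts to per-gene totals
#'
#' Maternal and paternal reads are summed across all of a gene's SNPs; genes
#' with no covered SNP are absent from the result. Per-SNP records at
#' positions missing from the SNP table are skipped with a warning reporting
#' how many were dropped. A SNP listed under several genes contributes to
#' each of them.
#'
#' @param oriented oriented per-SNP counts ([orientCounts()]).
#' @param snpTable \code{GRanges} SNP table ([readSnpTable()]).
#' @return a data.frame with columns \code{gene_id}, \code{cross},
#'   \code{maternal_reads}, \code{paternal_reads}, \code{n_snps}, one row per
#'   gene, sorted by gene id. The number of skipped per-SNP records is
#'   attached as attribute \code{"skipped_records"}.
#' @export
aggregateGeneCounts <- function(oriented, snpTable) {
  stopifnot(all(c("maternal_reads", "paternal_reads", "cross") %in%
                  colnames(oriented)))
  if (length(unique(oriented$cross)) > 1L)
    stop("aggregateGeneCounts expects counts from a single cross direction",
         call. = FALSE)
  snp <- data.frame(chrom = as.character(seqnames(snpTable)),
                    pos = start(snpTable),
                    gene_id = mcols(snpTable)$gene_id,
                    stringsAsFactors = FALSE)
  key_counts <- paste(oriented$chrom, oriented$pos)
  key_snp <- paste(snp$chrom, snp$pos)
  known <- key_counts %in% key_snp
  nskip <- sum(!known)
  if (nskip)
    warning(nskip, " per-SNP count record(s) at positions absent from the ",
            "SNP table were skipped", call. = FALSE)
  kept <- oriented[known, , drop = FALSE]
  # expand: one row per (count record, assigned gene)
  idx <- split(seq_len(nrow(snp)), key_snp)
  hits <- idx[paste(kept$chrom, kept$pos)]
  reps <- lengths(hits)
  expanded <- kept[rep(seq_len(nrow(kept)), reps), , drop = FALSE]
  expanded$gene_id <- snp$gene_id[unlist(hits, use.names = FALSE)]
  if (!nrow(expanded)) {
    out <- data.frame(gene_id = character(), cross = character(),
                      maternal_reads = integer(), paternal_reads = integer(),
                      n_snps = integer())
    attr(out, "skipped_records") <- nskip
    return(out)
  }
  mat <- tapply(expanded$maternal_reads, expanded$gene_id, sum)
  pat <- tapply(expanded$paternal_reads, expanded$gene_id, sum)
  nsnp <- tapply(paste(expanded$chrom, expanded$pos), expanded$gene_id,
                 function(x) length(unique(x)))
  out <- data.frame(gene_id = names(mat),
                    cross = oriented$cross[1L],
                    maternal_reads = as.integer(mat),
                    paternal_reads = as.integer(pat),
                    n_snps = as.integer(nsnp),
                    row.names = NULL)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_records") <- nskip
  out
}

#' Read / write per-gene allelic count tables
#'
#' TSV with header
#' \code{gene_id cross maternal_reads paternal_reads n_snps}.
#'
#' @param file path or connection.
#' @return \code{readGeneCounts}: a data.frame with the columns above.
#' @export
readGeneCounts <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  need <- c("gene_id", "cross", "maternal_reads", "paternal_reads", "n_snps")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("gene count table ", file, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$maternal_reads < 0L | df$paternal_reads < 0L | df$n_snps < 1L))
    stop("gene count table ", file,
         " has negative counts or n_snps < 1", call. = FALSE)
  df[, need]
}

#' @param counts data.frame as returned by [aggregateGeneCounts()].
#' @rdname readGeneCounts
#' @export
writeGeneCounts <- function(counts, file) {
  write.table(counts, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
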