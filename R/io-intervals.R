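#' Construct an interval table
#'
#' Intervals are 0-based half-open (`start` inclusive, `end` exclusive), the
#' BED convention, which is also the package's internal convention
#' everywhere; 1-based formats (GFF3, VCF) are converted at the format
#' boundary on read/write.
#'
#' @param chrom,start,end,strand,label Parallel vectors; `strand` is one of
#'   `"+"`, `"-"`, `"."`.
#' @return A `data.frame` of intervals.
#' @export
intervals <- function(chrom, start, end, strand = ".", label = "") {
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 0L || length(start) == 0L) n <- 0L
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   strand = rep_len(as.character(strand), n),
                   label = rep_len(as.character(label), n),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0L)) stop("interval start must be >= 0")
  if (any(df$start >= df$end)) stop("intervals must satisfy start < end")
  if (any(!df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  df
}

#' Read a BED file
#'
#' @param path Path to a BED3+/BED6 file.
#' @return An interval table (0-based half-open, as in the file).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  label <- if (!is.null(gr$name)) as.character(gr$name) else ""
  label[is.na(label)] <- ""
  intervals(as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
            strand, label)
}

#' Write an interval table as BED6
#'
#' @param x Interval table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("label" %in% names(x)) x$label else "."
  name[!nzchar(name)] <- "."
  strand <- if ("strand" %in% names(x)) x$strand else "."
  lines <- paste(x$chrom, x$start, x$end, name, 0L, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read TE annotations from a GFF3 file
#'
#' TE records carry `family=` and `te_class=` attributes and an `ID`.  GFF3
#' coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention on read.
#'
#' @param path Path to a GFF3 file.
#' @return A TE annotation table with columns `te_id`, `chrom`, `start`,
#'   `end`, `strand`, `family`, `te_class`.
#' @export
read_gff_te <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  strand <- as.character(g$strand)
  strand[is.na(strand) | strand == "*"] <- "."
  data.frame(
    te_id = as.character(g$ID),
    chrom = as.character(g$seqid),
    start = as.integer(g$start) - 1L,
    end = as.integer(g$end),
    strand = strand,
    family = as.character(g$family %||% NA_character_),
    te_class = as.character(g$te_class %||% NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Write TE annotations as GFF3
#'
#' @param tes TE annotation table (see [read_gff_te()]).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff_te <- function(tes, path, source = "tetrack") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(tes) > 0L) {
    attrs <- sprintf("ID=%s;family=%s;te_class=%s",
                     tes$te_id, tes$family, tes$te_class)
    writeLines(paste(tes$chrom, source, "transposable_element",
                     tes$start + 1L, tes$end, ".", tes$strand, ".",
                     attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory PAF columns (coordinates are 0-based half-open,
#' as in the format).  Rows with fewer than 12 columns are skipped with a
#' message reporting the count.
#'
#' @param path Path to a PAF file.
#' @return A `data.frame` with columns `query_name`, `query_len`,
#'   `query_start`, `query_end`, `strand`, `target_name`, `target_len`,
#'   `target_start`, `target_end`, `n_match`, `aln_len`, `mapq`.  Here
#'   "query"/"target" follow PAF naming (query = the sequence aligned,
#'   target = the sequence aligned to).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 12L
  if (any(!ok)) {
    message(sum(!ok), " malformed PAF row(s) skipped")
  }
  fields <- fields[ok]
  if (length(fields) == 0L) {
    return(data.frame(query_name = character(0), query_len = integer(0),
                      query_start = integer(0), query_end = integer(0),
                      strand = character(0), target_name = character(0),
                      target_len = integer(0), target_start = integer(0),
                      target_end = integer(0), n_match = integer(0),
                      aln_len = integer(0), mapq = integer(0)))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  data.frame(
    query_name = m[, 1], query_len = as.integer(m[, 2]),
    query_start = as.integer(m[, 3]), query_end = as.integer(m[, 4]),
    strand = m[, 5], target_name = m[, 6], target_len = as.integer(m[, 7]),
    target_start = as.integer(m[, 8]), target_end = as.integer(m[, 9]),
    n_match = as.integer(m[, 10]), aln_len = as.integer(m[, 11]),
    mapq = as.integer(m[, 12]), stringsAsFactors = FALSE
  )
}

#' Extract TE sequences from an assembly
#'
#' Returns the annotated (plus-strand) sequence of each TE interval.
#'
#' @param assembly A [genome_assembly()].
#' @param tes TE annotation table.
#' @return `tes` with a `sequence` column added.
#' @export
te_sequences <- function(assembly, tes) {
  len <- chrom_lengths(assembly)
  if (any(!tes$chrom %in% names(len))) {
    stop("TE annotation references chromosome(s) absent from assembly")
  }
  if (any(tes$end > len[tes$chrom])) {
    stop("TE interval(s) extend beyond chromosome end")
  }
  tes$sequence <- substring(unclass(assembly)[tes$chrom], tes$start + 1L, tes$end)
  tes
}
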