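#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom runif rnorm phyper setNames
#' @importFrom utils read.table write.table packageVersion
NULL

.datatable.aware <- TRUE

# Derive a reproducible 31-bit sub-seed from a master seed and a label, so
# each pipeline stage draws from its own stream and stages can be re-run
# independently.
subseed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 1009)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half down to an integer (3000.5 -> 3000).
round_half_down <- function(x) ceiling(x - 0.5)

revcomp <- function(x) {
  out <- character(length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out[!ok] <- x[!ok]
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute bases at 0-based positions of a single sequence.
substitute_bases <- function(seq, pos0, alt) {
  if (length(pos0) == 0L) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  v[pos0 + 1L] <- alt
  paste(v, collapse = "")
}

# A base different from `ref`, sampled uniformly from the other three.
other_base <- function(ref) {
  bases <- c("A", "C", "G", "T")
  vapply(ref, function(b) {
    pool <- bases[bases != b]
    pool[sample.int(3L, 1L)]
  }, character(1), USE.NAMES = FALSE)
}

stopifnot_scalar_chrom <- function(assembly, chrom) {
  if (!chrom %in% names(assembly)) {
    stop("chromosome '", chrom, "' not present in assembly", call. = FALSE)
  }
}

# Merge possibly-overlapping half-open intervals into a disjoint sorted set.
merge_starts_ends <- function(starts, ends) {
  if (length(starts) == 0L) return(list(starts = integer(0), ends = integer(0)))
  r <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  list(starts = IRanges::start(r) - 1L, ends = IRanges::end(r))
}

# Membership of 0-based positions in a set of half-open intervals on one
# chromosome.  Intervals may overlap; they are merged first.
pos_in_intervals <- function(pos, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(pos)))
  m <- merge_starts_ends(starts, ends)
  idx <- findInterval(pos, m$starts)
  idx > 0L & pos < m$ends[pmax(idx, 1L)]
}
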