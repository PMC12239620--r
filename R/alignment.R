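#' Alignment scoring parameters for flank comparison
#'
#' The defaults mirror the "asm5" preset used for whole-genome alignment of
#' low-divergence assemblies: match +1, mismatch penalty 19, and a single
#' affine gap component with open 39 and extend 3 (a gap of length L costs
#' `39 + 3*L`).  The preset's second, long-gap affine component is omitted:
#' on 50-bp flanks the long-gap regime is unreachable.
#'
#' @param match_score Match reward (>= 0).
#' @param mismatch_penalty,gap_open,gap_extend Penalties (>= 0).
#' @return A list of class `align_params`.
#' @export
align_params <- function(match_score = 1, mismatch_penalty = 19,
                         gap_open = 39, gap_extend = 3) {
  if (any(c(mismatch_penalty, gap_open, gap_extend) < 0)) {
    stop("penalties must be >= 0")
  }
  structure(list(match_score = match_score,
                 mismatch_penalty = mismatch_penalty,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

#' Smith-Waterman local alignment score and identity
#'
#' Optimal local alignment with affine gaps under [align_params()].  The
#' identity is the number of identical aligned columns in the optimal local
#' alignment divided by the length of the longer input, so short spurious
#' local hits score low.  An empty optimal alignment (no positive-scoring
#' pair) gives score 0 and identity 0.
#'
#' @param a,b DNA strings (each up to 10 kb).
#' @param params An [align_params()] object.
#' @return A list with `score` and `identity`.
#' @export
local_align <- function(a, b, params = align_params()) {
  a <- toupper(a); b <- toupper(b)
  if (grepl("[^ACGTN]", a) || grepl("[^ACGTN]", b)) {
    stop("non-DNA characters in alignment input")
  }
  if (nchar(a) > 10000L || nchar(b) > 10000L) {
    stop("local_align inputs are limited to 10 kb")
  }
  if (!nzchar(a) || !nzchar(b)) {
    return(list(score = 0, identity = 0))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match_score, mismatch = -params$mismatch_penalty,
    baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    return(list(score = 0, identity = 0))
  }
  ident <- Biostrings::nmatch(aln) / max(nchar(a), nchar(b))
  list(score = sc, identity = ident)
}

#' Extract the 50-bp flanks of a TE interval
#'
#' The upstream flank is the sequence immediately before the interval start
#' and the downstream flank the sequence immediately after the interval end,
#' both on the annotated assembly's plus strand, clipped at chromosome
#' bounds.  A flank shorter than `flank_len` sets the `truncated` flag.
#'
#' @param assembly A [genome_assembly()].
#' @param chrom Chromosome name.
#' @param start,end TE interval (0-based half-open).
#' @param flank_len Flank length in bp (default 50).
#' @return A list with `upstream`, `downstream`, and `truncated`.
#' @export
extract_flanks <- function(assembly, chrom, start, end, flank_len = 50L) {
  stopifnot_scalar_chrom(assembly, chrom)
  L <- chrom_lengths(assembly)[[chrom]]
  if (start < 0L || end > L || start >= end) stop("invalid TE interval")
  up_start <- max(0L, start - flank_len)
  dn_end <- min(L, end + flank_len)
  s <- unclass(assembly)[[chrom]]
  upstream <- if (up_start < start) substring(s, up_start + 1L, start) else ""
  downstream <- if (end < dn_end) substring(s, end + 1L, dn_end) else ""
  list(upstream = upstream, downstream = downstream,
       truncated = nchar(upstream) < flank_len | nchar(downstream) < flank_len)
}
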