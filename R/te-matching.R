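#' Fingerprint reference TEs with the SNPs that overlap them
#'
#' For every reference TE overlapped by at least one retained SNP, records
#' the SNP offsets within the TE (0-based: `vcf_pos - 1 - te_start`) and the
#' projected sequence obtained by applying the alternate bases
#' ([apply_variants()]).  TEs with no overlapping SNP are omitted.  Indel
#' variants never contribute to fingerprints; a TE whose interval is touched
#' by an indel's reference span is dropped from tracking entirely, with a
#' message reporting the count (its projected sequence would not be a pure
#' substitution edit).
#'
#' A SNP whose REF allele disagrees with the TE sequence at that offset is a
#' hard error: it indicates the VCF and the assembly are out of register.
#'
#' @param ref_tes TE annotation table with a `sequence` column
#'   ([te_sequences()]).
#' @param variants Variant record table (pre-filtered; only homozygous SNPs
#'   should feed fingerprints, see [filter_variants()]).
#' @return The fingerprinted subset of `ref_tes` with columns `n_snps`,
#'   `projected_sequence`, and a list-column `fingerprint` of
#'   `data.frame(offset, ref, alt)`.
#' @export
annotate_te_snps <- function(ref_tes, variants) {
  if (is.null(ref_tes$sequence)) stop("ref_tes must carry a sequence column")
  empty <- ref_tes[integer(0), , drop = FALSE]
  empty$n_snps <- integer(0)
  empty$projected_sequence <- character(0)
  empty$fingerprint <- list()
  if (nrow(ref_tes) == 0L || nrow(variants) == 0L) return(empty)

  snp <- variants[is_snp(variants), , drop = FALSE]
  indel <- variants[!is_snp(variants), , drop = FALSE]

  drop_te <- rep(FALSE, nrow(ref_tes))
  if (nrow(indel) > 0L) {
    for (chrom in unique(indel$chrom)) {
      sel <- which(ref_tes$chrom == chrom)
      if (!length(sel)) next
      ind <- indel[indel$chrom == chrom, , drop = FALSE]
      ir_te <- IRanges::IRanges(ref_tes$start[sel] + 1L, ref_tes$end[sel])
      ir_in <- IRanges::IRanges(ind$pos, ind$pos - 1L + nchar(ind$ref_allele))
      hit <- IRanges::findOverlaps(ir_te, ir_in)
      drop_te[sel[unique(S4Vectors::queryHits(hit))]] <- TRUE
    }
    if (any(drop_te)) {
      message(sum(drop_te),
              " TE(s) overlapped by indel variants were dropped from tracking")
    }
  }
  tes <- ref_tes[!drop_te, , drop = FALSE]
  if (nrow(tes) == 0L || nrow(snp) == 0L) return(empty)

  fp <- vector("list", nrow(tes))
  for (chrom in unique(tes$chrom)) {
    sel <- which(tes$chrom == chrom)
    sc <- snp[snp$chrom == chrom, , drop = FALSE]
    if (nrow(sc) == 0L) next
    ir_te <- IRanges::IRanges(tes$start[sel] + 1L, tes$end[sel])
    ir_snp <- IRanges::IRanges(sc$pos, sc$pos)
    hit <- IRanges::findOverlaps(ir_te, ir_snp)
    qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
    for (i in unique(qh)) {
      rows <- sh[qh == i]
      ti <- sel[i]
      fp[[ti]] <- data.frame(
        offset = sc$pos[rows] - 1L - tes$start[ti],
        ref = sc$ref_allele[rows], alt = sc$alt_allele[rows],
        stringsAsFactors = FALSE)
    }
  }
  keep <- !vapply(fp, is.null, logical(1))
  out <- tes[keep, , drop = FALSE]
  out$n_snps <- vapply(fp[keep], nrow, integer(1))
  out$projected_sequence <- vapply(seq_len(nrow(out)), function(i) {
    apply_variants(out$sequence[i], fp[keep][[i]])
  }, character(1))
  out$fingerprint <- fp[keep]
  rownames(out) <- NULL
  out
}

#' Apply fingerprint SNPs to a TE sequence
#'
#' Substitution-only edit: the sequence length is preserved and the result
#' differs from the input at exactly the fingerprint offsets.
#'
#' @param te_sequence DNA string.
#' @param fingerprint_snps `data.frame(offset, ref, alt)` with 0-based
#'   offsets within the TE.
#' @return The projected DNA string.
#' @export
apply_variants <- function(te_sequence, fingerprint_snps) {
  if (is.null(fingerprint_snps) || nrow(fingerprint_snps) == 0L) {
    return(te_sequence)
  }
  off <- fingerprint_snps$offset
  if (any(off < 0L) || any(off >= nchar(te_sequence))) {
    stop("fingerprint offset out of range")
  }
  have <- substring(te_sequence, off + 1L, off + 1L)
  if (any(have != fingerprint_snps$ref)) {
    stop("SNP REF allele disagrees with TE sequence (assembly/VCF mismatch)")
  }
  substitute_bases(te_sequence, off, fingerprint_snps$alt)
}

canonical_seq <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

#' Restrict fingerprinted TEs to the uniquely identifiable ones
#'
#' A fingerprinted TE is retained iff its projected sequence occurs exactly
#' once among all projected sequences and its raw sequence occurs exactly
#' once among all reference TE sequences.  Both censuses treat a sequence
#' and its reverse complement as the same sequence.
#'
#' @param polymorphic_tes Output of [annotate_te_snps()].
#' @param all_ref_tes The full reference TE annotation table with sequences
#'   (the raw-sequence census runs over all copies, fingerprinted or not).
#' @return The uniquely identifiable subset of `polymorphic_tes`.
#' @export
uniquely_identifiable <- function(polymorphic_tes, all_ref_tes) {
  if (nrow(polymorphic_tes) == 0L) return(polymorphic_tes)
  raw_census <- table(canonical_seq(all_ref_tes$sequence))
  proj_census <- table(canonical_seq(polymorphic_tes$projected_sequence))
  keep <- raw_census[canonical_seq(polymorphic_tes$sequence)] == 1L &
    proj_census[canonical_seq(polymorphic_tes$projected_sequence)] == 1L
  out <- polymorphic_tes[as.vector(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-reference projected TE sequences against the query TE set
#'
#' A projected reference TE matches a query TE when the full-length
#' sequences are exactly equal in either orientation (no fuzzy matching).
#' `match_class` is `"unique"` for exactly one query match, `"multiple"`
#' for two or more (duplication-ambiguity candidates), `"none"` otherwise.
#'
#' @param unique_tes Output of [uniquely_identifiable()].
#' @param query_tes Query TE annotation table with a `sequence` column.
#' @return A `data.frame` with `ref_te_id`, `query_te_ids` (comma-joined),
#'   `match_class`, `orientation_flip`.
#' @export
cross_reference <- function(unique_tes, query_tes) {
  if (is.null(query_tes$sequence)) stop("query_tes must carry a sequence column")
  qcanon <- canonical_seq(query_tes$sequence)
  out <- data.frame(ref_te_id = character(0), query_te_ids = character(0),
                    match_class = character(0), orientation_flip = logical(0),
                    stringsAsFactors = FALSE)
  if (nrow(unique_tes) == 0L) return(out)
  rows <- lapply(seq_len(nrow(unique_tes)), function(i) {
    proj <- unique_tes$projected_sequence[i]
    hits <- which(qcanon == canonical_seq(proj))
    flip <- query_tes$sequence[hits] != proj
    data.frame(
      ref_te_id = unique_tes$te_id[i],
      query_te_ids = paste(query_tes$te_id[hits], collapse = ","),
      match_class = if (length(hits) == 0L) "none"
                    else if (length(hits) == 1L) "unique" else "multiple",
      orientation_flip = if (length(hits)) any(flip) else NA,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
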