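#' @importFrom data.table data.table := .N setkey
NULL

# Enumerate canonical k-mers of one genome with their positions.
# Canonical form is the lexicographic minimum of a k-mer and its reverse
# complement; with odd k the two can never be equal.
genome_kmers <- function(assembly, k) {
  seqs <- unclass(assembly)
  parts <- lapply(names(seqs), function(chrom) {
    L <- nchar(seqs[[chrom]])
    if (L < k) return(NULL)
    n <- L - k + 1L
    km <- substring(seqs[[chrom]], seq_len(n), seq_len(n) + k - 1L)
    keep <- !grepl("N", km, fixed = TRUE)
    data.table::data.table(chrom = chrom, pos = which(keep) - 1L,
                           kmer = km[keep])
  })
  dt <- data.table::rbindlist(parts)
  if (nrow(dt) == 0L) return(dt)
  rc <- revcomp(dt$kmer)
  fwd_is_canon <- dt$kmer <= rc
  dt[, `:=`(canon = ifelse(fwd_is_canon, kmer, rc),
            strand = ifelse(fwd_is_canon, "+", "-"))]
  dt[, kmer := NULL]
  dt
}

unique_kmers <- function(dt) {
  if (nrow(dt) == 0L) return(dt)
  cnt <- dt[, .N, by = "canon"]
  dt[dt$canon %in% cnt$canon[cnt$N == 1L], ]
}

# Drop anchors whose k-mer interval [pos, pos+k) overlaps a masked
# interval.  Overlap (not mere containment of the start) matters: a k-mer
# spanning a flank/TE junction is unique in both genomes when a TE moves
# between two loci with identical flanks, and would otherwise seed a tiny
# displaced block right at the TE boundary.
mask_positions <- function(dt, mask, k) {
  if (is.null(mask) || nrow(dt) == 0L || nrow(mask) == 0L) return(dt)
  drop <- rep(FALSE, nrow(dt))
  for (chrom in unique(mask$chrom)) {
    sel <- dt$chrom == chrom
    if (!any(sel)) next
    mi <- mask[mask$chrom == chrom, , drop = FALSE]
    drop[sel] <- pos_in_intervals(dt$pos[sel], mi$start - (k - 1L), mi$end)
  }
  dt[!drop, ]
}

new_synteny_map <- function(blocks, k = NA_integer_, stats = list()) {
  if (nrow(blocks) > 0L) {
    blocks <- blocks[order(blocks$ref_chrom, blocks$ref_start), , drop = FALSE]
    rownames(blocks) <- NULL
  }
  structure(list(blocks = blocks, k = k, stats = stats),
            class = "synteny_map")
}

#' @export
print.synteny_map <- function(x, ...) {
  cat("synteny_map:", nrow(x$blocks), "block(s) covering",
      format(sum(x$blocks$ref_end - x$blocks$ref_start), big.mark = ","),
      "reference bp\n")
  invisible(x)
}

empty_blocks <- function() {
  data.frame(ref_chrom = character(0), ref_start = integer(0),
             ref_end = integer(0), query_chrom = character(0),
             query_start = integer(0), query_end = integer(0),
             orientation = character(0), n_anchors = integer(0),
             stringsAsFactors = FALSE)
}

#' Build a collinear-block synteny map from unique k-mer anchors
#'
#' Anchors are k-mers occurring exactly once in each genome (counting both
#' strands).  Matched anchor pairs are chained into exactly collinear runs:
#' a chain extends while the anchor diagonal (query offset) is unchanged and
#' the gap to the previous anchor is at most `max_gap`, so every block is an
#' exact, gap-free coordinate translation and in-block lifts are exact.
#' Chains with at least `min_anchors` anchors become blocks spanning their
#' first to last anchor.
#'
#' Anchors whose k-mer overlaps a `mask_ref`/`mask_query` interval are
#' discarded before chaining.  Masking the TE annotations of both genomes
#' is recommended when the map feeds movement calling: it prevents a
#' relocated TE's interior (or a junction-spanning k-mer at an
#' identical-flank locus) from seeding a tiny displaced block.
#'
#' @param ref,query [genome_assembly()] objects.
#' @param k Odd k-mer size (default 21).
#' @param max_gap Maximum distance between consecutive anchors in a chain
#'   (default 10 kb).
#' @param min_anchors Minimum anchors per block (default 5).
#' @param min_block_span Minimum reference span of a retained block.
#' @param mask_ref,mask_query Optional interval tables of regions whose
#'   anchors are excluded (e.g. TE annotations).
#' @return A `synteny_map`.
#' @export
build_anchor_map <- function(ref, query, k = 21L, max_gap = 10000L,
                             min_anchors = 5L, min_block_span = 0L,
                             mask_ref = NULL, mask_query = NULL) {
  if (k %% 2L == 0L) stop("k must be odd")
  rk <- unique_kmers(genome_kmers(ref, k))
  qk <- unique_kmers(genome_kmers(query, k))
  rk <- mask_positions(rk, mask_ref, k)
  qk <- mask_positions(qk, mask_query, k)
  if (nrow(rk) == 0L || nrow(qk) == 0L) {
    warning("no unique anchors found; returning an empty synteny map")
    return(new_synteny_map(empty_blocks(), k))
  }
  data.table::setkey(rk, canon)
  data.table::setkey(qk, canon)
  anc <- rk[qk, nomatch = NULL]
  # columns: canon, chrom/pos/strand (ref), i.chrom/i.pos/i.strand (query)
  if (nrow(anc) == 0L) {
    warning("no shared unique anchors; returning an empty synteny map")
    return(new_synteny_map(empty_blocks(), k))
  }
  a <- data.frame(ref_chrom = anc$chrom, ref_pos = anc$pos,
                  query_chrom = anc$i.chrom, query_pos = anc$i.pos,
                  forward = anc$strand == anc$i.strand,
                  stringsAsFactors = FALSE)
  a$diag <- ifelse(a$forward, a$query_pos - a$ref_pos,
                   a$query_pos + a$ref_pos)
  a <- a[order(a$ref_chrom, a$ref_pos), , drop = FALSE]
  n <- nrow(a)
  brk <- c(TRUE, a$ref_chrom[-1] != a$ref_chrom[-n] |
             a$query_chrom[-1] != a$query_chrom[-n] |
             a$forward[-1] != a$forward[-n] |
             a$diag[-1] != a$diag[-n] |
             a$ref_pos[-1] - a$ref_pos[-n] > max_gap)
  a$chain <- cumsum(brk)
  dt <- data.table::as.data.table(a)
  ch <- dt[, list(ref_chrom = ref_chrom[1L], query_chrom = query_chrom[1L],
                  orientation = ifelse(forward[1L], "forward", "reverse"),
                  ref_start = min(ref_pos), ref_end = max(ref_pos) + k,
                  query_start = min(query_pos), query_end = max(query_pos) + k,
                  n_anchors = .N),
            by = "chain"]
  ch <- ch[ch$n_anchors >= min_anchors, ]
  blocks <- as.data.frame(ch[, -1])
  # enforce non-overlap on the reference axis (adjacent chains can share up
  # to k-1 bp at an indel junction): trim the later block's start
  if (nrow(blocks) > 1L) {
    blocks <- blocks[order(blocks$ref_chrom, blocks$ref_start), , drop = FALSE]
    for (i in 2:nrow(blocks)) {
      if (blocks$ref_chrom[i] == blocks$ref_chrom[i - 1L] &&
          blocks$ref_start[i] < blocks$ref_end[i - 1L]) {
        d <- blocks$ref_end[i - 1L] - blocks$ref_start[i]
        blocks$ref_start[i] <- blocks$ref_start[i] + d
        if (blocks$orientation[i] == "forward") {
          blocks$query_start[i] <- blocks$query_start[i] + d
        } else {
          blocks$query_end[i] <- blocks$query_end[i] - d
        }
      }
    }
    blocks <- blocks[blocks$ref_start < blocks$ref_end, , drop = FALSE]
  }
  blocks <- blocks[blocks$ref_end - blocks$ref_start >= max(1L, min_block_span), ,
                   drop = FALSE]
  new_synteny_map(blocks, k, stats = list(n_anchors = n,
                                          n_chains = max(a$chain)))
}

#' Build a synteny map from PAF alignment rows
#'
#' Each PAF row at least `min_len` long on the reference (PAF target) axis
#' becomes one block; the strand column sets the orientation.  Rows whose
#' reference spans overlap are resolved by keeping the longer row.
#'
#' @param paf_rows Output of [read_paf()].  The PAF target is taken as the
#'   reference genome, the PAF query as the query genome.
#' @param min_len Minimum reference span (default 1 kb).
#' @return A `synteny_map`.
#' @export
blocks_from_paf <- function(paf_rows, min_len = 1000L) {
  p <- paf_rows[paf_rows$target_end - paf_rows$target_start >= min_len, ,
                drop = FALSE]
  if (nrow(p) == 0L) return(new_synteny_map(empty_blocks()))
  p <- p[order(-(p$target_end - p$target_start)), , drop = FALSE]
  keep <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    prior <- which(keep & p$target_name == p$target_name[i])
    keep[i] <- !any(p$target_start[i] < p$target_end[prior] &
                      p$target_end[i] > p$target_start[prior])
  }
  p <- p[keep, , drop = FALSE]
  blocks <- data.frame(
    ref_chrom = p$target_name, ref_start = p$target_start,
    ref_end = p$target_end, query_chrom = p$query_name,
    query_start = p$query_start, query_end = p$query_end,
    orientation = ifelse(p$strand == "+", "forward", "reverse"),
    n_anchors = NA_integer_, stringsAsFactors = FALSE)
  new_synteny_map(blocks, stats = list(n_rows_in = nrow(paf_rows),
                                       n_rows_kept = nrow(p)))
}

#' Lift reference coordinates to alignment-expected query coordinates
#'
#' A position inside a block is translated exactly; a position between
#' blocks of the same chromosome pair is extrapolated from the nearest
#' flanking block edge and flagged `"interpolated"`; a position inside no
#' pair's span is `"unplaced"`.
#'
#' @param map A `synteny_map`.
#' @param ref_chrom Chromosome name(s), recycled against `ref_pos`.
#' @param ref_pos 0-based reference position(s).
#' @return A `data.frame` with `query_chrom`, `expected_pos`, `orientation`,
#'   `status` (`"block"`, `"interpolated"`, or `"unplaced"`).
#' @export
lift <- function(map, ref_chrom, ref_pos) {
  n <- max(length(ref_chrom), length(ref_pos))
  ref_chrom <- rep_len(as.character(ref_chrom), n)
  ref_pos <- rep_len(as.integer(ref_pos), n)
  out <- data.frame(query_chrom = rep(NA_character_, n),
                    expected_pos = rep(NA_integer_, n),
                    orientation = rep(NA_character_, n),
                    status = rep("unplaced", n), stringsAsFactors = FALSE)
  B <- map$blocks
  if (nrow(B) == 0L) return(out)
  for (chrom in unique(ref_chrom)) {
    sel <- which(ref_chrom == chrom)
    bc <- B[B$ref_chrom == chrom, , drop = FALSE]
    if (nrow(bc) == 0L) next
    bc <- bc[order(bc$ref_start), , drop = FALSE]
    pos <- ref_pos[sel]
    idx <- findInterval(pos, bc$ref_start)
    inb <- idx > 0L & pos < bc$ref_end[pmax(idx, 1L)]
    if (any(inb)) {
      i <- idx[inb]
      fwd <- bc$orientation[i] == "forward"
      exp_pos <- ifelse(fwd,
                        bc$query_start[i] + (pos[inb] - bc$ref_start[i]),
                        bc$query_end[i] - 1L - (pos[inb] - bc$ref_start[i]))
      out$query_chrom[sel[inb]] <- bc$query_chrom[i]
      out$expected_pos[sel[inb]] <- exp_pos
      out$orientation[sel[inb]] <- bc$orientation[i]
      out$status[sel[inb]] <- "block"
    }
    mis <- sel[!inb]
    for (j in mis) {
      p <- ref_pos[j]
      res <- interpolate_lift(bc, p)
      if (!is.null(res)) {
        out$query_chrom[j] <- res$query_chrom
        out$expected_pos[j] <- res$expected_pos
        out$orientation[j] <- res$orientation
        out$status[j] <- "interpolated"
      }
    }
  }
  out
}

# Extrapolate a between-block position from the nearest flanking block edge
# of the chromosome pair whose span contains it (the pair with the largest
# aligned span wins if several qualify).
interpolate_lift <- function(bc, p) {
  pairs <- unique(bc$query_chrom)
  spans <- vapply(pairs, function(qc) {
    b <- bc[bc$query_chrom == qc, , drop = FALSE]
    if (p >= min(b$ref_start) && p < max(b$ref_end)) {
      sum(b$ref_end - b$ref_start)
    } else -1
  }, numeric(1))
  if (all(spans < 0)) return(NULL)
  qc <- pairs[which.max(spans)]
  b <- bc[bc$query_chrom == qc, , drop = FALSE]
  left <- b[b$ref_end <= p, , drop = FALSE]
  right <- b[b$ref_start > p, , drop = FALSE]
  d_left <- if (nrow(left)) p - max(left$ref_end) else Inf
  d_right <- if (nrow(right)) min(right$ref_start) - p else Inf
  if (d_left <= d_right) {
    lb <- left[which.max(left$ref_end), ]
    if (lb$orientation == "forward") {
      list(query_chrom = qc, expected_pos = lb$query_end + d_left,
           orientation = "forward")
    } else {
      list(query_chrom = qc, expected_pos = lb$query_start - 1L - d_left,
           orientation = "reverse")
    }
  } else {
    rb <- right[which.min(right$ref_start), ]
    if (rb$orientation == "forward") {
      list(query_chrom = qc, expected_pos = rb$query_start - d_right,
           orientation = "forward")
    } else {
      list(query_chrom = qc, expected_pos = rb$query_end - 1L + d_right,
           orientation = "reverse")
    }
  }
}

#' Write synteny blocks to a TSV file
#' @param map A `synteny_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synteny_blocks <- function(map, path) {
  write.table(map$blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
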