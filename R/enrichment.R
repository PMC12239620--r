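#' Define arm/center workspaces for each chromosome
#'
#' A workspace is the restricted territory within which null interval
#' placements are simulated.  For each chromosome two mutually exclusive
#' workspaces are defined: the combined terminal "arm" domains
#' `[0, L*f) + [L*(1-f), L)` and the central domain `[L*f, L*(1-f))`, with
#' boundaries rounded half-down to integer bp.  The arm/center split can be
#' replaced entirely by a BED file whose `name` column labels each segment's
#' workspace.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param arm_fraction Fraction of each chromosome assigned to each terminal
#'   arm (default 1/3, i.e. arms are the two terminal thirds).  Must be
#'   < 0.5.
#' @param override_bed Optional path to a BED file defining workspaces
#'   verbatim (segments grouped by their `name` field).
#' @return A named list of `workspace` objects, each a list with `label`,
#'   `segments` (interval table), and `total_bp`.
#' @export
define_workspaces <- function(chrom_lengths, arm_fraction = 1/3,
                              override_bed = NULL) {
  if (!is.null(override_bed)) {
    bed <- read_bed(override_bed)
    if (any(!nzchar(bed$label))) stop("override BED segments must be named")
    out <- lapply(split(bed, bed$label), function(seg) {
      seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
      workspace(seg$label[1], seg)
    })
    return(out[order(names(out))])
  }
  if (arm_fraction >= 0.5) stop("arm_fraction must be < 0.5")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  out <- list()
  for (chrom in names(chrom_lengths)) {
    L <- as.integer(chrom_lengths[[chrom]])
    a <- as.integer(round_half_down(L * arm_fraction))
    b <- L - a
    arm_lab <- paste0("arms:", chrom)
    cen_lab <- paste0("center:", chrom)
    seg <- function(start, end) {
      keep <- start < end
      intervals(chrom = rep(chrom, sum(keep)), start = start[keep],
                end = end[keep])
    }
    out[[arm_lab]] <- workspace(arm_lab, seg(c(0L, b), c(a, L)))
    out[[cen_lab]] <- workspace(cen_lab, seg(a, b))
  }
  out
}

workspace <- function(label, segments) {
  # segments must be non-overlapping within a workspace
  for (sp in split(segments, segments$chrom)) {
    sp <- sp[order(sp$start), , drop = FALSE]
    if (nrow(sp) > 1L && any(sp$start[-1] < sp$end[-nrow(sp)])) {
      stop("workspace segments overlap on chromosome ", sp$chrom[1])
    }
  }
  structure(list(label = label, segments = segments,
                 total_bp = sum(segments$end - segments$start)),
            class = "workspace")
}

#' Nucleotide overlap of two interval sets
#'
#' Total length of the intersection of the two interval unions.
#'
#' @param setA,setB Interval tables on a shared chromosome namespace.
#' @return Overlap in bp.
#' @export
overlap_bp <- function(setA, setB) {
  if (nrow(setA) == 0L || nrow(setB) == 0L) return(0L)
  total <- 0L
  for (chrom in intersect(unique(setA$chrom), unique(setB$chrom))) {
    a <- setA[setA$chrom == chrom, ]
    b <- setB[setB$chrom == chrom, ]
    ra <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
    rb <- IRanges::reduce(IRanges::IRanges(b$start + 1L, b$end))
    total <- total + sum(IRanges::width(IRanges::intersect(ra, rb)))
  }
  total
}

# --- internal: workspace segment space -------------------------------------
#
# Workspace segments are concatenated into a single 0-based axis ("segment
# space").  Null placements always keep an interval inside one segment, so
# working in segment space makes placement and overlap computations
# single-axis and vectorizable.

ws_segspace <- function(ws) {
  seg <- ws$segments[order(ws$segments$chrom, ws$segments$start), , drop = FALSE]
  w <- seg$end - seg$start
  list(chrom = seg$chrom, start = seg$start, end = seg$end,
       width = w, offset = cumsum(c(0L, w))[seq_len(nrow(seg))],
       total = sum(w))
}

# Clip intervals to workspace segments and map them to segment space.
# An interval spanning several segments is split.
to_segspace <- function(x, sp) {
  if (nrow(x) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  out_s <- integer(0); out_e <- integer(0)
  for (j in seq_along(sp$chrom)) {
    xi <- x[x$chrom == sp$chrom[j], , drop = FALSE]
    if (nrow(xi) == 0L) next
    s <- pmax(xi$start, sp$start[j]); e <- pmin(xi$end, sp$end[j])
    keep <- s < e
    if (any(keep)) {
      out_s <- c(out_s, sp$offset[j] + s[keep] - sp$start[j])
      out_e <- c(out_e, sp$offset[j] + e[keep] - sp$start[j])
    }
  }
  o <- order(out_s, out_e)
  data.frame(start = out_s[o], end = out_e[o])
}

# Map segment-space starts back to genome coordinates.
from_segspace <- function(start, len, sp) {
  j <- findInterval(start, sp$offset)
  data.frame(chrom = sp$chrom[j],
             start = sp$start[j] + (start - sp$offset[j]),
             end = sp$start[j] + (start - sp$offset[j]) + len,
             stringsAsFactors = FALSE)
}

# Disjointify segment-space intervals and build a prefix-sum lookup for
# "annotated bp in [0, x)".
prefix_cover <- function(x) {
  if (nrow(x) == 0L) {
    return(list(start = integer(0), end = integer(0), before = 0L))
  }
  r <- IRanges::reduce(IRanges::IRanges(x$start + 1L, x$end))
  s <- IRanges::start(r) - 1L; e <- IRanges::end(r)
  list(start = s, end = e, before = cumsum(c(0L, e - s)))
}

cover_before <- function(x, pc) {
  j <- findInterval(x, pc$start)
  out <- numeric(length(x))
  pos <- j > 0L
  out[pos] <- pc$before[j[pos]] +
    pmax(0L, pmin(x[pos], pc$end[j[pos]]) - pc$start[j[pos]])
  out
}

# Vectorized uniform placement: for each of n draws, a start position for an
# interval of length len, uniform over all in-segment positions.  Returns
# segment-space starts, or NA length handling for oversized intervals
# (clipped to the largest segment, with warning by the caller).
draw_starts <- function(len, sp, n) {
  cap <- pmax(0L, sp$width - len + 1L)
  total <- sum(cap)
  if (total == 0L) {
    jbig <- which(sp$width == max(sp$width))
    j <- jbig[sample.int(length(jbig), n, replace = TRUE)]
    return(list(start = sp$offset[j], clip_end = sp$offset[j] + sp$width[j],
                clipped = TRUE))
  }
  cum <- cumsum(cap)
  r <- sample.int(total, n, replace = TRUE)
  j <- findInterval(r - 1L, c(0L, cum))
  list(start = sp$offset[j] + (r - c(0L, cum)[j] - 1L),
       clip_end = NULL, clipped = FALSE)
}

#' Randomly re-place an interval set within a workspace
#'
#' Each interval is independently assigned a new start position, uniform
#' over all positions that keep it inside a single workspace segment.
#' Interval lengths are preserved and sampled intervals may overlap each
#' other.  An interval longer than every segment is kept at a uniformly
#' chosen largest segment and clipped to it, with a warning.
#'
#' @param x Interval table (lengths are taken from it).
#' @param ws A `workspace`.
#' @return An interval table of the same lengths, placed in the workspace.
#' @export
sample_null <- function(x, ws) {
  sp <- ws_segspace(ws)
  if (sp$total == 0L) stop("empty workspace")
  lens <- x$end - x$start
  out <- vector("list", nrow(x))
  warned <- FALSE
  for (i in seq_len(nrow(x))) {
    d <- draw_starts(lens[i], sp, 1L)
    if (d$clipped && !warned) {
      warning("interval(s) longer than every workspace segment were clipped")
      warned <- TRUE
    }
    len_i <- if (d$clipped) min(lens[i], d$clip_end - d$start) else lens[i]
    out[[i]] <- from_segspace(d$start, len_i, sp)
  }
  res <- do.call(rbind, out)
  intervals(res$chrom, res$start, res$end)
}

#' Permutation enrichment of a variant set in an annotation set
#'
#' Compares the observed nucleotide overlap between a variant interval set
#' and an annotation interval set, both restricted to a workspace, against a
#' null distribution obtained by repeatedly re-placing each variant interval
#' uniformly within the workspace ([sample_null()] placement rule).  The
#' overlap statistic sums each variant interval's overlap with the
#' annotation union, matching the independent-placement null (identical to
#' plain nucleotide overlap whenever the variant intervals are disjoint, as
#' SNP sets are).
#'
#' Reported are the observed overlap, the null mean/sd, the fold change
#' `log2((observed+1)/(null_mean+1))` (the +1 bp pseudocount keeps the fold
#' finite at zero overlap), a two-sided empirical p-value
#' `2*min(p_enrich, p_deplete)` capped at 1 with
#' `p_enrich = (1 + #{null >= obs}) / (n_iter + 1)`, and a one-sided
#' hypergeometric tail probability of drawing the observed-or-more annotated
#' bases when `variant_bp` bases are drawn without replacement from the
#' workspace.  The hypergeometric mapping treats bases as exchangeable
#' draws; the empirical p-value is the primary statistic.
#'
#' @param variants,annotation Interval tables; both are clipped to the
#'   workspace first.
#' @param ws A `workspace`.
#' @param n_iter Number of null placements (default 20000).
#' @param seed Optional RNG seed for reproducible results.
#' @return A list of class `enrichment_result`.
#' @export
enrichment_test <- function(variants, annotation, ws, n_iter = 20000L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  sp <- ws_segspace(ws)
  if (sp$total == 0L) stop("empty workspace")
  va <- to_segspace(variants, sp)
  an <- to_segspace(annotation, sp)
  pc <- prefix_cover(an)
  annotation_bp <- if (length(pc$start)) pc$before[length(pc$before)] else 0L
  observed <- sum(cover_before(va$end, pc) - cover_before(va$start, pc))
  variant_bp <- sum(va$end - va$start)

  null_sum <- numeric(n_iter)
  clipped_any <- FALSE
  for (i in seq_len(nrow(va))) {
    len <- va$end[i] - va$start[i]
    d <- draw_starts(len, sp, n_iter)
    if (d$clipped) {
      clipped_any <- TRUE
      ends <- pmin(d$start + len, d$clip_end)
    } else {
      ends <- d$start + len
    }
    null_sum <- null_sum + (cover_before(ends, pc) - cover_before(d$start, pc))
  }
  if (clipped_any) {
    warning("variant interval(s) longer than every workspace segment were clipped in the null")
  }
  null_mean <- mean(null_sum)
  null_sd <- stats::sd(null_sum)
  p_enrich <- (1 + sum(null_sum >= observed)) / (n_iter + 1)
  p_deplete <- (1 + sum(null_sum <= observed)) / (n_iter + 1)
  structure(list(
    observed_overlap_bp = observed,
    null_mean_bp = null_mean,
    null_sd_bp = null_sd,
    log2_fold = log2((observed + 1) / (null_mean + 1)),
    empirical_p = min(1, 2 * min(p_enrich, p_deplete)),
    p_enrich = p_enrich,
    p_deplete = p_deplete,
    hypergeometric_p = stats::phyper(observed - 1, annotation_bp,
                                     sp$total - annotation_bp, variant_bp,
                                     lower.tail = FALSE),
    n_iterations = n_iter,
    rng_seed = seed,
    workspace_label = ws$label,
    variant_bp = variant_bp,
    annotation_bp = annotation_bp,
    workspace_bp = sp$total
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result [%s]: observed %d bp, null %.2f +/- %.2f bp, log2(fold) %.3f, empirical p %.4g (hypergeometric %.4g), %d iterations\n",
    x$workspace_label, x$observed_overlap_bp, x$null_mean_bp, x$null_sd_bp,
    x$log2_fold, x$empirical_p, x$hypergeometric_p, x$n_iterations))
  invisible(x)
}

#' Enrichment of several variant sets in several annotation sets
#'
#' Runs [enrichment_test()] for every (variant set, annotation set,
#' workspace) combination and returns a heatmap-ready long table.  Each cell
#' uses its own sub-seed derived from `seed`, so any single cell can be
#' reproduced independently.
#'
#' @param variant_sets,annotation_sets Named lists of interval tables.
#' @param workspaces List of `workspace` objects (see [define_workspaces()]).
#' @param n_iter Iterations per cell.
#' @param seed Master seed.
#' @return A `data.frame` with one row per combination.
#' @export
enrichment_table <- function(variant_sets, annotation_sets, workspaces,
                             n_iter = 20000L, seed = 1L) {
  rows <- list()
  for (vn in names(variant_sets)) {
    for (an in names(annotation_sets)) {
      for (ws in workspaces) {
        cell_seed <- subseed(seed, paste(vn, an, ws$label, sep = "|"))
        res <- enrichment_test(variant_sets[[vn]], annotation_sets[[an]], ws,
                               n_iter = n_iter, seed = cell_seed)
        rows[[length(rows) + 1L]] <- data.frame(
          variant_set = vn, annotation = an, workspace = ws$label,
          observed_bp = res$observed_overlap_bp,
          null_mean_bp = res$null_mean_bp, null_sd_bp = res$null_sd_bp,
          log2_fold = res$log2_fold, empirical_p = res$empirical_p,
          hypergeometric_p = res$hypergeometric_p,
          n_iterations = res$n_iterations, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Convert variant records to intervals for enrichment testing
#'
#' A SNP becomes a 1-bp interval; an indel becomes an interval spanning the
#' replaced reference span (the anchored REF allele).
#'
#' @param records Variant record table.
#' @return An interval table.
#' @export
variants_to_intervals <- function(records) {
  if (nrow(records) == 0L) {
    return(intervals(character(0), integer(0), integer(0)))
  }
  start <- records$pos - 1L
  end <- start + pmax(1L, nchar(records$ref_allele))
  intervals(records$chrom, start, end)
}
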