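#' Is a TE nested inside another TE of the same family?
#'
#' TRUE iff the TE's interval is fully contained within a different TE
#' interval of the same family in the same genome.  Nested same-family
#' copies are excluded from movement calling: whether the inner copy moved
#' locally within its enveloping element cannot be inferred from
#' coordinates.
#'
#' @param te One row of a TE annotation table.
#' @param all_tes_same_genome The genome's full TE annotation table.
#' @return Logical.
#' @export
nested_exclusion <- function(te, all_tes_same_genome) {
  host <- all_tes_same_genome
  any(host$te_id != te$te_id &
        host$chrom == te$chrom &
        host$family == te$family &
        host$start <= te$start &
        host$end >= te$end)
}

verdict_levels <- c("unmoved", "intra", "inter", "ambiguous_duplication",
                    "excluded_nested", "excluded_flank", "unplaced")

movement_call_row <- function(ref_te_id, query_te_id = NA_character_,
                              verdict = NA_character_,
                              expected_chrom = NA_character_,
                              expected_pos = NA_integer_,
                              observed_chrom = NA_character_,
                              observed_pos = NA_integer_,
                              distance = NA_integer_,
                              identity_up = NA_real_,
                              identity_down = NA_real_,
                              lift_status = NA_character_,
                              note = "") {
  data.frame(ref_te_id = ref_te_id, query_te_id = query_te_id,
             verdict = verdict, expected_chrom = expected_chrom,
             expected_pos = expected_pos, observed_chrom = observed_chrom,
             observed_pos = observed_pos, distance = distance,
             identity_up = identity_up, identity_down = identity_down,
             lift_status = lift_status, note = note, stringsAsFactors = FALSE)
}

flank_too_similar <- function(id_up, id_down, threshold, rule) {
  switch(rule,
         either = max(id_up, id_down) >= threshold,
         both = min(id_up, id_down) >= threshold,
         stop("unknown flank rule: ", rule))
}

#' Classify matched TEs as unmoved, moved, ambiguous, or excluded
#'
#' For every cross-referenced TE pair the reference start coordinate is
#' lifted through the synteny map to its alignment-expected query
#' coordinate.  A pair whose observed query TE sits on a different
#' chromosome than expected is an interchromosomal candidate; on the
#' expected chromosome, an observed start within `tolerance` bp of the
#' expected coordinate is `unmoved` and anything farther is an
#' intrachromosomal candidate with `distance = |observed - expected|`.
#' Candidates are then filtered: a candidate nested in a same-family TE (in
#' either genome) is `excluded_nested`; a candidate whose 50-bp flanks at
#' the old and new locus are too similar under [local_align()] is
#' `excluded_flank` (similar flanks at both loci suggest an alignment
#' artifact rather than movement).  Matches found at two or more query loci
#' are assigned `ambiguous_duplication` directly.
#'
#' @param matches Output of [cross_reference()].
#' @param ref_tes,query_tes Full TE annotation tables of the two genomes.
#' @param map A `synteny_map` from reference to query.
#' @param ref_genome,query_genome The two assemblies (for flank extraction).
#' @param tolerance Coordinate slack, in bp, absorbed as "unmoved"
#'   (default 100).
#' @param flank_identity_max Flank identity at or above which a candidate is
#'   excluded (default 0.90, i.e. movement requires flanks < 90% identical).
#' @param flank_rule `"either"` (default: exclude when either flank reaches
#'   the threshold) or `"both"` (exclude only when both do).
#' @param flank_len Flank length in bp (default 50).
#' @param filter_inter Apply the flank filter to interchromosomal candidates
#'   as well (default `TRUE`); set `FALSE` to filter only the
#'   intrachromosomal list.
#' @param scoring Scoring for flank alignment ([align_params()]).
#' @return A `data.frame` of movement calls, one row per match.
#' @export
call_movements <- function(matches, ref_tes, query_tes, map,
                           ref_genome, query_genome,
                           tolerance = 100L, flank_identity_max = 0.90,
                           flank_rule = c("either", "both"),
                           flank_len = 50L, filter_inter = TRUE,
                           scoring = align_params()) {
  flank_rule <- match.arg(flank_rule)
  rows <- vector("list", nrow(matches))
  ref_idx <- match(matches$ref_te_id, ref_tes$te_id)
  if (anyNA(ref_idx)) stop("match references a TE id absent from ref_tes")
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, ]
    rte <- ref_tes[ref_idx[i], ]
    if (m$match_class == "none") next
    if (m$match_class == "multiple") {
      rows[[i]] <- movement_call_row(m$ref_te_id, m$query_te_ids,
                                     verdict = "ambiguous_duplication",
                                     note = "exact sequence found at multiple query loci")
      next
    }
    qte <- query_tes[match(m$query_te_ids, query_tes$te_id), ]
    if (anyNA(qte$te_id)) stop("match references a TE id absent from query_tes")
    lf <- lift(map, rte$chrom, rte$start)
    if (lf$status == "unplaced") {
      rows[[i]] <- movement_call_row(m$ref_te_id, qte$te_id,
                                     verdict = "unplaced",
                                     observed_chrom = qte$chrom,
                                     observed_pos = qte$start,
                                     lift_status = "unplaced")
      next
    }
    base <- movement_call_row(m$ref_te_id, qte$te_id,
                              expected_chrom = lf$query_chrom,
                              expected_pos = lf$expected_pos,
                              observed_chrom = qte$chrom,
                              observed_pos = qte$start,
                              lift_status = lf$status)
    if (qte$chrom == lf$query_chrom &&
        abs(qte$start - lf$expected_pos) <= tolerance) {
      base$verdict <- "unmoved"
      rows[[i]] <- base
      next
    }
    candidate <- if (qte$chrom == lf$query_chrom) "intra" else "inter"
    if (candidate == "intra") {
      base$distance <- abs(qte$start - lf$expected_pos)
    }
    if (nested_exclusion(rte, ref_tes) || nested_exclusion(qte, query_tes)) {
      base$verdict <- "excluded_nested"
      base$note <- "nested in a same-family TE"
      rows[[i]] <- base
      next
    }
    if (candidate == "intra" || filter_inter) {
      rf <- extract_flanks(ref_genome, rte$chrom, rte$start, rte$end, flank_len)
      qf <- extract_flanks(query_genome, qte$chrom, qte$start, qte$end, flank_len)
      if (isTRUE(m$orientation_flip)) {
        qf <- list(upstream = revcomp(qf$downstream),
                   downstream = revcomp(qf$upstream),
                   truncated = qf$truncated)
      }
      id_up <- local_align(rf$upstream, qf$upstream, scoring)$identity
      id_down <- local_align(rf$downstream, qf$downstream, scoring)$identity
      base$identity_up <- id_up
      base$identity_down <- id_down
      if (flank_too_similar(id_up, id_down, flank_identity_max, flank_rule)) {
        base$verdict <- "excluded_flank"
        base$note <- sprintf("flank identity up=%.2f down=%.2f >= %.2f",
                             id_up, id_down, flank_identity_max)
        rows[[i]] <- base
        next
      }
    }
    base$verdict <- candidate
    rows[[i]] <- base
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- movement_call_row("")[integer(0), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Summarize movement calls by TE family
#'
#' @param calls Output of [call_movements()].
#' @param ref_tes Reference TE annotation table (for family lookup).
#' @return A `data.frame` with one row per family plus a `total` row,
#'   counting interchromosomal and intrachromosomal movements.
#' @export
summarize_by_family <- function(calls, ref_tes) {
  fam <- ref_tes$family[match(calls$ref_te_id, ref_tes$te_id)]
  families <- sort(unique(ref_tes$family))
  tab <- data.frame(family = families,
                    n_inter = vapply(families, function(f) {
                      sum(calls$verdict == "inter" & fam == f)
                    }, integer(1)),
                    n_intra = vapply(families, function(f) {
                      sum(calls$verdict == "intra" & fam == f)
                    }, integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  rbind(tab, data.frame(family = "total", n_inter = sum(tab$n_inter),
                        n_intra = sum(tab$n_intra)))
}
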