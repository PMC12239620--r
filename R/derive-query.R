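# Query-genome derivation: apply background and fingerprint variants to the
# reference, execute the planted TE movements as clean cut-and-paste edits
# (no excision scar, no target-site duplication), and keep an exact
# reference->query coordinate map as ground truth.

# Apply a sorted, non-overlapping edit list to one chromosome string.
# edits: data.frame(pos, end, insert_seq, id); a deletion has end > pos and
# empty insert_seq; an insertion has end == pos.  Returns the edited
# string, the kept-segment coordinate map, and the query positions of the
# insertions.
apply_edits <- function(seq_str, edits) {
  L <- nchar(seq_str)
  if (nrow(edits) == 0L) {
    return(list(seq = seq_str,
                segments = data.frame(ref_start = 0L, ref_end = L,
                                      query_start = 0L),
                inserts = data.frame(id = character(0),
                                     query_start = integer(0),
                                     stringsAsFactors = FALSE)))
  }
  edits <- edits[order(edits$pos, edits$end), , drop = FALSE]
  if (any(edits$pos[-1] < edits$end[-nrow(edits)])) {
    stop("overlapping edits")
  }
  pieces <- character(0)
  segs <- list(); ins <- list()
  prev <- 0L; qpos <- 0L
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (e$pos > prev) {
      keep <- substring(seq_str, prev + 1L, e$pos)
      pieces <- c(pieces, keep)
      segs[[length(segs) + 1L]] <- c(prev, e$pos, qpos)
      qpos <- qpos + (e$pos - prev)
    }
    if (e$end > e$pos) {           # deletion
      prev <- e$end
    } else {                       # insertion
      pieces <- c(pieces, e$insert_seq)
      ins[[length(ins) + 1L]] <- list(id = e$id, query_start = qpos)
      qpos <- qpos + nchar(e$insert_seq)
      prev <- e$pos
    }
  }
  if (prev < L) {
    pieces <- c(pieces, substring(seq_str, prev + 1L, L))
    segs[[length(segs) + 1L]] <- c(prev, L, qpos)
  }
  segm <- do.call(rbind, segs)
  list(seq = paste(pieces, collapse = ""),
       segments = data.frame(ref_start = segm[, 1], ref_end = segm[, 2],
                             query_start = segm[, 3]),
       inserts = if (length(ins)) data.frame(
         id = vapply(ins, function(x) x$id, character(1)),
         query_start = vapply(ins, function(x) x$query_start, integer(1)),
         stringsAsFactors = FALSE) else
           data.frame(id = character(0), query_start = integer(0),
                      stringsAsFactors = FALSE))
}

#' Translate reference positions through a truth coordinate map
#'
#' The coordinate map emitted by [derive_query()] lists every unedited
#' reference segment with its query offset.  Positions inside a kept
#' segment translate exactly; positions inside deleted segments return
#' `NA`.  With `boundary = TRUE` a position at the right edge of a kept
#' segment (e.g. the excision junction of a moved TE) translates to the end
#' of the query segment.
#'
#' @param coord_map `data.frame(chrom, ref_start, ref_end, query_start)`.
#' @param chrom,pos Reference coordinates (vectors, recycled).
#' @param boundary Allow `pos == ref_end`.
#' @return Query positions (integer, `NA` where deleted).
#' @export
truth_lift <- function(coord_map, chrom, pos, boundary = FALSE) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  out <- rep(NA_integer_, n)
  for (c0 in unique(chrom)) {
    sel <- which(chrom == c0)
    m <- coord_map[coord_map$chrom == c0, , drop = FALSE]
    if (nrow(m) == 0L) next
    m <- m[order(m$ref_start), , drop = FALSE]
    idx <- findInterval(pos[sel], m$ref_start)
    lim <- if (boundary) m$ref_end else m$ref_end - 1L
    ok <- idx > 0L & pos[sel] <= lim[pmax(idx, 1L)]
    out[sel[ok]] <- m$query_start[idx[ok]] + pos[sel][ok] - m$ref_start[idx[ok]]
  }
  out
}

sample_free_point <- function(L, edge_margin, blocked, min_gap, n_try = 500L) {
  # blocked: matrix of half-open intervals that the point must stay min_gap
  # away from
  for (try in seq_len(n_try)) {
    q <- edge_margin + sample.int(L - 2L * edge_margin, 1L)
    if (is.null(blocked) || nrow(blocked) == 0L ||
        !any(q > blocked[, 1] - min_gap & q < blocked[, 2] + min_gap)) {
      return(q)
    }
  }
  NA_integer_
}

#' Derive the query genome from a simulated reference
#'
#' Applies arm-biased background SNPs and small indels outside TE copies,
#' plants fingerprint SNPs inside TE copies (every TE selected for a
#' movement or duplication is forced to carry at least one), and executes
#' the planted events: intrachromosomal and interchromosomal cut-and-paste
#' movements, nested-inner shifts within their host copy, identical-flank
#' movements onto the twin-flank landing pad, and duplications (the copy
#' remains at its source locus and an identical copy appears elsewhere).
#' All SNPs and background indels are recorded in a reference-frame VCF;
#' TE movements are structural events and are not.
#'
#' @param reference The `assembly` element of [simulate_reference()].
#' @param truth The `truth` element of [simulate_reference()].
#' @param params The same [simulation_params()] used for the reference.
#' @return A list with `assembly` (query genome), `tes` (query TE
#'   annotation with sequences), `vcf` (variant record table), `coord_map`
#'   (reference->query segment map, see [truth_lift()]), `movements` (truth
#'   table of planted events with expected verdicts), and `te_map` (ref
#'   TE id to query TE id pairing for every surviving copy).
#' @export
derive_query <- function(reference, truth, params = truth$params) {
  set.seed(subseed(params$rng_seed, "query"))
  tes <- truth$tes
  chroms <- names(reference)
  L <- chrom_lengths(reference)

  # --- choose movers -------------------------------------------------------
  raw_census <- table(canonical_seq(tes$sequence))
  unique_seq <- raw_census[canonical_seq(tes$sequence)] == 1L
  pool <- which(tes$role == "normal" & tes$te_class == "II" &
                  tes$end - tes$start <= 2500L & as.vector(unique_seq))
  need <- params$n_intra_moves + params$n_inter_moves +
    params$n_duplication_distractors
  if (need > length(pool)) {
    stop("requested movement count exceeds the eligible fingerprinted TE pool")
  }
  picks <- if (need > 0L) sample(pool, need) else integer(0)
  intra_ids <- tes$te_id[picks[seq_len(params$n_intra_moves)]]
  inter_ids <- tes$te_id[picks[params$n_intra_moves + seq_len(params$n_inter_moves)]]
  dup_ids <- tes$te_id[picks[params$n_intra_moves + params$n_inter_moves +
                               seq_len(params$n_duplication_distractors)]]
  flank_ids <- truth$flank_sites$te_id
  nested_inner_ids <- truth$nested$inner_id
  forced <- c(intra_ids, inter_ids, dup_ids, flank_ids, nested_inner_ids)

  # --- background indels (placed first so SNPs can avoid them) -------------
  te_zone <- lapply(setNames(chroms, chroms), function(c0) {
    t0 <- tes[tes$chrom == c0, , drop = FALSE]
    fs <- truth$flank_sites[truth$flank_sites$chrom == c0, , drop = FALSE]
    m <- rbind(cbind(t0$start - 50L, t0$end + 50L),
               if (nrow(fs)) cbind(fs$b_start - 50L, fs$b_start + 150L))
    m
  })
  rate_ratio <- if (params$arm_snp_rate > 0) {
    params$center_snp_rate / params$arm_snp_rate
  } else 0
  indels <- list()
  for (c0 in chroms) {
    arm <- in_arm(seq_len(L[[c0]]) - 1L, L[[c0]], params$arm_fraction)
    allowed <- !pos_in_intervals(seq_len(L[[c0]]) - 1L,
                                 te_zone[[c0]][, 1], te_zone[[c0]][, 2])
    allowed[seq_len(100L)] <- FALSE
    allowed[(L[[c0]] - 99L):L[[c0]]] <- FALSE
    cand_arm <- which(allowed & arm) - 1L
    cand_cen <- which(allowed & !arm) - 1L
    n_arm <- rbinom(1L, length(cand_arm), params$indel_rate)
    n_cen <- rbinom(1L, length(cand_cen), params$indel_rate * rate_ratio)
    pos <- sort(c(if (n_arm) sample(cand_arm, n_arm),
                  if (n_cen) sample(cand_cen, n_cen)))
    # enforce a 60-bp separation so indels never interact
    if (length(pos) > 1L) {
      keep <- logical(length(pos)); last <- -Inf
      for (i in seq_along(pos)) {
        if (pos[i] - last >= 60L) { keep[i] <- TRUE; last <- pos[i] }
      }
      pos <- pos[keep]
    }
    if (length(pos) == 0L) next
    size <- sample(params$indel_size_range[1]:params$indel_size_range[2],
                   length(pos), replace = TRUE)
    is_ins <- runif(length(pos)) < 0.5
    indels[[c0]] <- data.frame(chrom = c0, pos = pos, size = size,
                               is_ins = is_ins, stringsAsFactors = FALSE)
  }
  indels <- if (length(indels)) do.call(rbind, indels) else
    data.frame(chrom = character(0), pos = integer(0), size = integer(0),
               is_ins = logical(0))
  rownames(indels) <- NULL

  # --- SNPs ----------------------------------------------------------------
  snp_pos <- list()
  for (c0 in chroms) {
    arm <- in_arm(seq_len(L[[c0]]) - 1L, L[[c0]], params$arm_fraction)
    allowed <- !pos_in_intervals(seq_len(L[[c0]]) - 1L,
                                 te_zone[[c0]][, 1], te_zone[[c0]][, 2])
    ind <- indels[indels$chrom == c0, , drop = FALSE]
    if (nrow(ind)) {
      allowed <- allowed & !pos_in_intervals(seq_len(L[[c0]]) - 1L,
                                             ind$pos - 12L, ind$pos + ind$size + 12L)
    }
    cand_arm <- which(allowed & arm) - 1L
    cand_cen <- which(allowed & !arm) - 1L
    n_arm <- rbinom(1L, length(cand_arm), params$arm_snp_rate)
    n_cen <- rbinom(1L, length(cand_cen), params$center_snp_rate)
    p <- c(if (n_arm) sample(cand_arm, n_arm),
           if (n_cen) sample(cand_cen, n_cen))
    if (length(p)) snp_pos[[c0]] <- data.frame(chrom = c0, pos = sort(p))
  }
  # fingerprint SNPs inside TE copies
  fp_pos <- list()
  for (i in seq_len(nrow(tes))) {
    len <- tes$end[i] - tes$start[i]
    k <- rbinom(1L, len, params$te_snp_rate)
    if (tes$te_id[i] %in% forced) k <- max(1L, k)
    if (k == 0L) next
    off <- sample.int(len, k) - 1L
    fp_pos[[length(fp_pos) + 1L]] <- data.frame(chrom = tes$chrom[i],
                                                pos = tes$start[i] + off)
  }
  snps <- rbind(do.call(rbind, snp_pos), do.call(rbind, fp_pos))
  if (is.null(snps)) snps <- data.frame(chrom = character(0), pos = integer(0))
  snps <- snps[!duplicated(paste(snps$chrom, snps$pos)), , drop = FALSE]
  snps <- snps[order(match(snps$chrom, chroms), snps$pos), , drop = FALSE]
  snps$ref <- substring(unclass(reference)[snps$chrom], snps$pos + 1L,
                        snps$pos + 1L)
  snps$alt <- other_base(snps$ref)

  # --- edited (variant-applied) reference ----------------------------------
  edited <- unclass(reference)
  for (c0 in chroms) {
    s0 <- snps[snps$chrom == c0, , drop = FALSE]
    edited[[c0]] <- substitute_bases(edited[[c0]], s0$pos, s0$alt)
  }

  # --- destinations --------------------------------------------------------
  te_row <- function(id) tes[tes$te_id == id, , drop = FALSE]
  blocked <- lapply(setNames(chroms, chroms), function(c0) {
    t0 <- tes[tes$chrom == c0, , drop = FALSE]
    fs <- truth$flank_sites[truth$flank_sites$chrom == c0, , drop = FALSE]
    ind <- indels[indels$chrom == c0, , drop = FALSE]
    rbind(cbind(t0$start, t0$end),
          if (nrow(fs)) cbind(fs$b_start, fs$b_start + 100L),
          if (nrow(ind)) cbind(ind$pos - 1L, ind$pos + ind$size + 1L))
  })
  moves <- list()  # te_id, class, dest_chrom, dest_pos (ref frame), excise
  add_block <- function(c0, s, e) {
    blocked[[c0]] <<- rbind(blocked[[c0]], c(s, e))
  }
  for (id in intra_ids) {
    t0 <- te_row(id)
    q <- NA_integer_
    for (try in 1:500) {
      d <- sample(params$intra_distance_range[1]:params$intra_distance_range[2], 1L)
      cand <- t0$start + sample(c(-1L, 1L), 1L) * d
      if (cand < params$edge_margin ||
          cand > L[[t0$chrom]] - params$edge_margin) next
      if (any(cand > blocked[[t0$chrom]][, 1] - params$min_te_gap &
                cand < blocked[[t0$chrom]][, 2] + params$min_te_gap)) next
      q <- cand; break
    }
    if (is.na(q)) stop("could not sample an intrachromosomal destination")
    add_block(t0$chrom, q, q)
    moves[[length(moves) + 1L]] <- list(te_id = id, class = "intra",
                                        dest_chrom = t0$chrom, dest_pos = q,
                                        excise = TRUE)
  }
  for (id in inter_ids) {
    t0 <- te_row(id)
    dest_chrom <- sample(setdiff(chroms, t0$chrom), 1L)
    q <- sample_free_point(L[[dest_chrom]], params$edge_margin,
                           blocked[[dest_chrom]], params$min_te_gap)
    if (is.na(q)) stop("could not sample an interchromosomal destination")
    add_block(dest_chrom, q, q)
    moves[[length(moves) + 1L]] <- list(te_id = id, class = "inter",
                                        dest_chrom = dest_chrom, dest_pos = q,
                                        excise = TRUE)
  }
  for (id in dup_ids) {
    t0 <- te_row(id)
    q <- sample_free_point(L[[t0$chrom]], params$edge_margin,
                           blocked[[t0$chrom]], params$min_te_gap)
    if (is.na(q)) stop("could not sample a duplication destination")
    add_block(t0$chrom, q, q)
    moves[[length(moves) + 1L]] <- list(te_id = id, class = "duplication",
                                        dest_chrom = t0$chrom, dest_pos = q,
                                        excise = FALSE)
  }
  for (i in seq_len(nrow(truth$flank_sites))) {
    fs <- truth$flank_sites[i, ]
    moves[[length(moves) + 1L]] <- list(te_id = fs$te_id, class = "flank",
                                        dest_chrom = fs$chrom,
                                        dest_pos = fs$b_start + 50L,
                                        excise = TRUE)
  }
  for (i in seq_len(nrow(truth$nested))) {
    inner <- te_row(truth$nested$inner_id[i])
    outer <- te_row(truth$nested$outer_id[i])
    lo <- inner$start + 350L
    hi <- outer$end - 50L - (inner$end - inner$start)
    if (hi < lo) stop("nested host too short for an inner shift")
    q <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    moves[[length(moves) + 1L]] <- list(te_id = inner$te_id, class = "nested",
                                        dest_chrom = inner$chrom, dest_pos = q,
                                        excise = TRUE)
  }

  # --- edit lists ----------------------------------------------------------
  edits <- lapply(setNames(chroms, chroms), function(c0) {
    data.frame(pos = integer(0), end = integer(0), insert_seq = character(0),
               id = character(0), stringsAsFactors = FALSE)
  })
  push_edit <- function(c0, pos, end, insert_seq, id) {
    edits[[c0]] <<- rbind(edits[[c0]], data.frame(
      pos = pos, end = end, insert_seq = insert_seq, id = id,
      stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(indels))) {
    e <- indels[i, ]
    if (e$is_ins) {
      push_edit(e$chrom, e$pos, e$pos, random_dna(e$size),
                paste0("bg_ins_", i))
    } else {
      push_edit(e$chrom, e$pos, e$pos + e$size, "", paste0("bg_del_", i))
    }
  }
  for (m in moves) {
    t0 <- te_row(m$te_id)
    seq_q <- substring(edited[[t0$chrom]], t0$start + 1L, t0$end)
    if (m$excise) push_edit(t0$chrom, t0$start, t0$end, "", paste0("cut_", m$te_id))
    push_edit(m$dest_chrom, m$dest_pos, m$dest_pos, seq_q,
              paste0("paste_", m$te_id))
  }

  # --- apply ---------------------------------------------------------------
  qseqs <- character(0); coord_map <- list(); insert_pos <- list()
  for (c0 in chroms) {
    res <- apply_edits(edited[[c0]], edits[[c0]])
    qseqs[[c0]] <- res$seq
    res$segments$chrom <- c0
    coord_map[[c0]] <- res$segments[, c("chrom", "ref_start", "ref_end",
                                        "query_start")]
    if (nrow(res$inserts)) {
      res$inserts$chrom <- c0
      insert_pos[[c0]] <- res$inserts
    }
  }
  query <- genome_assembly(qseqs)
  coord_map <- do.call(rbind, coord_map)
  rownames(coord_map) <- NULL
  inserts <- if (length(insert_pos)) do.call(rbind, insert_pos) else
    data.frame(id = character(0), query_start = integer(0),
               chrom = character(0))

  # --- query TE annotation -------------------------------------------------
  moved_ids <- vapply(moves, function(m) m$te_id, character(1))
  excised <- vapply(moves, function(m) m$excise, logical(1))
  qte <- list()
  for (i in seq_len(nrow(tes))) {
    t0 <- tes[i, ]
    mi <- which(moved_ids == t0$te_id & excised)
    if (length(mi)) {
      m <- moves[[mi]]
      ip <- inserts[inserts$id == paste0("paste_", t0$te_id), ]
      qte[[length(qte) + 1L]] <- data.frame(
        ref_te_id = t0$te_id, chrom = m$dest_chrom, start = ip$query_start,
        end = ip$query_start + (t0$end - t0$start), strand = t0$strand,
        family = t0$family, te_class = t0$te_class, origin = m$class,
        stringsAsFactors = FALSE)
    } else {
      qs <- truth_lift(coord_map, t0$chrom, t0$start)
      if (is.na(qs)) stop("internal error: unmoved TE start not liftable")
      qte[[length(qte) + 1L]] <- data.frame(
        ref_te_id = t0$te_id, chrom = t0$chrom, start = qs,
        end = qs + (t0$end - t0$start), strand = t0$strand,
        family = t0$family, te_class = t0$te_class,
        origin = if (t0$te_id %in% dup_ids) "duplication_source" else "unmoved",
        stringsAsFactors = FALSE)
    }
  }
  for (id in dup_ids) {
    t0 <- te_row(id)
    ip <- inserts[inserts$id == paste0("paste_", id), ]
    qte[[length(qte) + 1L]] <- data.frame(
      ref_te_id = id, chrom = ip$chrom, start = ip$query_start,
      end = ip$query_start + (t0$end - t0$start), strand = t0$strand,
      family = t0$family, te_class = t0$te_class, origin = "duplication_copy",
      stringsAsFactors = FALSE)
  }
  qte <- do.call(rbind, qte)
  if (is.null(qte)) {
    qte <- data.frame(ref_te_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), family = character(0),
                      te_class = character(0), origin = character(0),
                      stringsAsFactors = FALSE)
  }
  ord <- order(match(qte$chrom, chroms), qte$start, qte$end)
  qte <- qte[ord, , drop = FALSE]
  qte$te_id <- if (nrow(qte)) paste0("qte_", seq_len(nrow(qte))) else character(0)
  qte <- qte[, c("te_id", "ref_te_id", "chrom", "start", "end", "strand",
                 "family", "te_class", "origin")]
  rownames(qte) <- NULL
  qte <- te_sequences(query, qte)

  # --- VCF -----------------------------------------------------------------
  n_var <- nrow(snps) + nrow(indels)
  qual <- round(runif(n_var, 40, 220), 1)
  total <- pmax(30L, as.integer(round(rnorm(n_var, 60, 8))))
  altd <- total - sample(0:3, n_var, replace = TRUE)
  vcf_snp <- if (nrow(snps)) variant_records(
    snps$chrom, snps$pos + 1L, snps$ref, snps$alt,
    qual[seq_len(nrow(snps))], altd[seq_len(nrow(snps))],
    total[seq_len(nrow(snps))], "hom") else NULL
  vcf_ind <- NULL
  if (nrow(indels)) {
    j <- nrow(snps) + seq_len(nrow(indels))
    anchor <- substring(unclass(reference)[indels$chrom], indels$pos,
                        indels$pos)  # base before the event (0-based pos-1)
    ref_all <- ifelse(indels$is_ins, anchor,
                      paste0(anchor,
                             substring(unclass(reference)[indels$chrom],
                                       indels$pos + 1L,
                                       indels$pos + indels$size)))
    ins_seq <- vapply(seq_len(nrow(indels)), function(i) {
      if (indels$is_ins[i])

        edits[[indels$chrom[i]]]$insert_seq[
          edits[[indels$chrom[i]]]$id == paste0("bg_ins_", i)]
      else ""
    }, character(1))
    alt_all <- ifelse(indels$is_ins, paste0(anchor, ins_seq), anchor)
    vcf_ind <- variant_records(indels$chrom, indels$pos, ref_all, alt_all,
                               qual[j], altd[j], total[j], "hom")
  }
  vcf <- rbind(vcf_snp, vcf_ind)
  if (is.null(vcf)) {
    vcf <- variant_records(character(0), integer(0), character(0), character(0))
  } else {
    vcf <- vcf[order(match(vcf$chrom, chroms), vcf$pos), , drop = FALSE]
    rownames(vcf) <- NULL
  }

  # --- truth movement table ------------------------------------------------
  expected_verdict <- c(intra = "intra", inter = "inter",
                        duplication = "ambiguous_duplication",
                        flank = "excluded_flank", nested = "excluded_nested")
  mv <- do.call(rbind, lapply(moves, function(m) {
    t0 <- te_row(m$te_id)
    junction <- truth_lift(coord_map, t0$chrom, t0$start, boundary = TRUE)
    ip <- inserts[inserts$id == paste0("paste_", m$te_id), ]
    dist <- if (m$class %in% c("intra", "flank", "nested") &&
                m$dest_chrom == t0$chrom) {
      abs(ip$query_start - junction)
    } else NA_integer_
    qid <- qte$te_id[qte$ref_te_id == m$te_id]
    data.frame(te_id = m$te_id, class = m$class,
               expected_verdict = expected_verdict[[m$class]],
               src_chrom = t0$chrom, src_start = t0$start,
               dest_chrom = m$dest_chrom, dest_query_start = ip$query_start,
               expected_query_pos = junction, distance_bp = dist,
               query_te_id = paste(sort(qid), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(mv)) {
    mv <- data.frame(te_id = character(0), class = character(0),
                     expected_verdict = character(0), src_chrom = character(0),
                     src_start = integer(0), dest_chrom = character(0),
                     dest_query_start = integer(0),
                     expected_query_pos = integer(0),
                     distance_bp = integer(0), query_te_id = character(0))
  }
  rownames(mv) <- NULL

  # internal consistency: a moved TE's query sequence must equal its
  # variant-applied reference sequence
  for (m in moves) {
    t0 <- te_row(m$te_id)
    expected_seq <- substring(edited[[t0$chrom]], t0$start + 1L, t0$end)
    qid <- qte$te_id[qte$ref_te_id == m$te_id]
    got <- qte$sequence[qte$te_id %in% qid]
    if (!all(got == expected_seq)) {
      stop("internal error: moved TE sequence mismatch for ", m$te_id)
    }
  }

  list(assembly = query, tes = qte, vcf = vcf, coord_map = coord_map,
       movements = mv,
       te_map = qte[, c("ref_te_id", "te_id", "origin")])
}
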