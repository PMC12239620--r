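#' Default TE family roster for simulation
#'
#' Ten families spanning class I (retrotransposon) and class II (DNA
#' transposon) elements, with consensus lengths close to the mean copy
#' length of each family in the *C. elegans* assemblies and copy numbers in
#' roughly the observed family proportions, scaled to a miniature
#' three-chromosome genome (about 200 copies in total, an order of 1/90th
#' of the real census).  `per_copy_divergence` is the per-base substitution
#' probability applied independently to each copy so that copies of one
#' family are distinguishable.
#'
#' @return A `data.frame` with columns `name`, `te_class`,
#'   `consensus_length`, `copy_number`, `per_copy_divergence`.
#' @export
te_family_specs <- function() {
  specs <- data.frame(
    name = c("Zator", "hAT", "CMC", "Tc1/Mariner", "Sola", "MITE",
             "Novosib", "Helitron", "Gypsy", "Copia"),
    te_class = c("II", "II", "II", "II", "II", "II", "II", "II", "I", "I"),
    consensus_length = c(330L, 1000L, 1800L, 700L, 280L, 190L, 260L, 2400L,
                         2600L, 1500L),
    copy_number = c(90L, 40L, 18L, 20L, 10L, 6L, 4L, 3L, 8L, 5L),
    per_copy_divergence = c(0.02, 0.02, 0.02, 0.02, 0.02, 0.03, 0.03, 0.02,
                            0.02, 0.02),
    stringsAsFactors = FALSE)
  validate_family_specs(specs)
  specs
}

validate_family_specs <- function(specs) {
  stopifnot(all(c("name", "te_class", "consensus_length", "copy_number",
                  "per_copy_divergence") %in% names(specs)))
  if (any(specs$consensus_length < 150L)) {
    stop("consensus_length must be >= 150 (two flanks plus a trackable core)")
  }
  if (any(specs$copy_number < 0L)) stop("copy_number must be >= 0")
  if (any(specs$per_copy_divergence < 0 | specs$per_copy_divergence > 0.1)) {
    stop("per_copy_divergence must be in [0, 0.1]")
  }
  if (any(!specs$te_class %in% c("I", "II"))) stop("te_class must be I or II")
  invisible(specs)
}

#' Generate a consensus sequence library for the TE families
#'
#' One i.i.d. uniform A/C/G/T consensus per family, reproducible under the
#' seed.
#'
#' @param family_specs See [te_family_specs()].
#' @param seed Integer seed.
#' @return `family_specs` with a `consensus` column added.
#' @export
make_te_library <- function(family_specs = te_family_specs(), seed = 1L) {
  validate_family_specs(family_specs)
  set.seed(subseed(seed, "te_library"))
  family_specs$consensus <- vapply(family_specs$consensus_length, random_dna,
                                   character(1))
  family_specs
}

#' Simulation parameters for the synthetic genome pair
#'
#' The defaults describe a miniature diverged strain pair: three 500-kb
#' chromosomes whose terminal thirds are "arm" domains; background SNP
#' rates of 3 per kb on arms and 2 per kb in centers (the modest arm bias
#' that puts roughly three quarters of variants in the two-thirds of the
#' genome that is arm); small indels at 0.8 per kb (arm-biased by the same
#' ratio); TE placement density four-fold higher on arms; five planted
#' intrachromosomal and five interchromosomal movements; and three each of
#' the nested, identical-flank, and duplication distractor classes.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bp.
#' @param arm_fraction Fraction of each chromosome in each terminal arm.
#' @param arm_snp_rate,center_snp_rate Background SNP probability per bp in
#'   the arm/center domains (arm rate must be >= center rate).
#' @param indel_rate Background small-indel probability per bp on arms; the
#'   center rate is scaled down by `center_snp_rate/arm_snp_rate`.
#' @param indel_size_range Inclusive size range of background indels, bp.
#' @param te_snp_rate Per-bp probability of a fingerprint SNP inside a TE
#'   copy.  The default (4 per kb) slightly exceeds the background arm rate
#'   so that TE sequences come out mildly variant-enriched, the pattern the
#'   enrichment module is built to detect.
#' @param te_arm_weight Relative per-bp TE placement density of arm vs
#'   center domains.
#' @param n_intra_moves,n_inter_moves Planted movement counts.
#' @param intra_distance_range Range (bp) of planted intrachromosomal
#'   movement distances.
#' @param n_nested_distractors,n_identical_flank_distractors,n_duplication_distractors
#'   Distractor counts.
#' @param min_te_gap Minimum bp between placed TE copies.
#' @param edge_margin TE-free margin at each chromosome end, bp.
#' @param rng_seed Master seed; a fixed seed makes all outputs
#'   byte-identical.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_chromosomes = 3L,
                              chromosome_length = 500000L,
                              arm_fraction = 1/3,
                              arm_snp_rate = 0.003,
                              center_snp_rate = 0.002,
                              indel_rate = 0.0008,
                              indel_size_range = c(1L, 10L),
                              te_snp_rate = 0.004,
                              te_arm_weight = 4,
                              n_intra_moves = 5L,
                              n_inter_moves = 5L,
                              intra_distance_range = c(300L, 150000L),
                              n_nested_distractors = 3L,
                              n_identical_flank_distractors = 3L,
                              n_duplication_distractors = 3L,
                              min_te_gap = 150L,
                              edge_margin = 1000L,
                              rng_seed = 1L) {
  p <- list(n_chromosomes = as.integer(n_chromosomes),
            chromosome_length = as.integer(chromosome_length),
            arm_fraction = arm_fraction,
            arm_snp_rate = arm_snp_rate, center_snp_rate = center_snp_rate,
            indel_rate = indel_rate,
            indel_size_range = as.integer(indel_size_range),
            te_snp_rate = te_snp_rate, te_arm_weight = te_arm_weight,
            n_intra_moves = as.integer(n_intra_moves),
            n_inter_moves = as.integer(n_inter_moves),
            intra_distance_range = as.integer(intra_distance_range),
            n_nested_distractors = as.integer(n_nested_distractors),
            n_identical_flank_distractors = as.integer(n_identical_flank_distractors),
            n_duplication_distractors = as.integer(n_duplication_distractors),
            min_te_gap = as.integer(min_te_gap),
            edge_margin = as.integer(edge_margin),
            rng_seed = as.integer(rng_seed))
  if (p$arm_snp_rate < p$center_snp_rate) {
    stop("arm_snp_rate must be >= center_snp_rate (variants concentrate on arms)")
  }
  if (p$arm_fraction <= 0 || p$arm_fraction >= 0.5) {
    stop("arm_fraction must be in (0, 0.5)")
  }
  counts <- c(p$n_intra_moves, p$n_inter_moves, p$n_nested_distractors,
              p$n_identical_flank_distractors, p$n_duplication_distractors)
  if (any(counts < 0L)) stop("movement/distractor counts must be >= 0")
  if (p$intra_distance_range[1] > p$intra_distance_range[2]) {
    stop("invalid intra_distance_range")
  }
  structure(p, class = "simulation_params")
}

chrom_names <- function(n) {
  as.character(utils::as.roman(seq_len(n)))
}

arm_domains <- function(L, arm_fraction) {
  a <- as.integer(round_half_down(L * arm_fraction))
  list(arm = rbind(c(0L, a), c(L - a, L)), center = rbind(c(a, L - a)))
}

# TRUE where 0-based positions fall in an arm domain.
in_arm <- function(pos, L, arm_fraction) {
  a <- as.integer(round_half_down(L * arm_fraction))
  pos < a | pos >= L - a
}

#' Simulate the reference genome with planted TE copies
#'
#' Generates random chromosomes, places TE copies preferentially in the arm
#' domains (per-bp placement density `te_arm_weight`-fold higher than the
#' center), mutates each copy away from its family consensus at
#' `per_copy_divergence` so copies are distinguishable, and plants the
#' reference-side scaffolding of the distractor classes: nested same-family
#' copies (a short same-family fragment written inside a long host copy)
#' and twin-flank sites (a second locus carrying an exact copy of a chosen
#' TE's 50-bp flanks, the landing pad for an identical-flank movement).
#'
#' @param params A [simulation_params()] object.
#' @param library Output of [make_te_library()].
#' @return A list with `assembly` ([genome_assembly()]), `tes` (TE
#'   annotation table with `sequence` and `role` columns), and `truth`
#'   (reference-side ground truth consumed by [derive_query()]).
#' @export
simulate_reference <- function(params = simulation_params(),
                               library = make_te_library()) {
  set.seed(subseed(params$rng_seed, "reference"))
  n_chrom <- params$n_chromosomes
  L <- params$chromosome_length
  chroms <- chrom_names(n_chrom)
  total_te_bp <- sum(library$copy_number * library$consensus_length)
  if (total_te_bp > 0.5 * n_chrom * L) {
    stop("infeasible packing: requested TE bp exceed 50% of the genome")
  }
  seqs <- setNames(vapply(seq_len(n_chrom), function(i) random_dna(L),
                          character(1)), chroms)

  # --- place TE copies -----------------------------------------------------
  placements <- list()   # chrom, start, end, strand, family, te_class, seq, role
  occupied <- setNames(vector("list", n_chrom), chroms)  # matrix start,end
  dom <- arm_domains(L, params$arm_fraction)
  arm_bp <- sum(dom$arm[, 2] - dom$arm[, 1])
  center_bp <- sum(dom$center[, 2] - dom$center[, 1])
  p_arm <- params$te_arm_weight * arm_bp /
    (params$te_arm_weight * arm_bp + center_bp)

  free_at <- function(chrom, start, end, gap) {
    occ <- occupied[[chrom]]
    if (is.null(occ)) return(TRUE)
    !any(start - gap < occ[, 2] & end + gap > occ[, 1])
  }
  place_one <- function(len, family, te_class, role) {
    for (try in 1:500) {
      chrom <- chroms[sample.int(n_chrom, 1L)]
      d <- if (runif(1) < p_arm) dom$arm[sample.int(nrow(dom$arm), 1L), ]
           else dom$center[1, ]
      lo <- max(d[1], params$edge_margin)
      hi <- min(d[2], L - params$edge_margin) - len
      if (hi <= lo) next
      start <- lo + sample.int(hi - lo, 1L)
      if (!free_at(chrom, start, start + len, params$min_te_gap)) next
      occupied[[chrom]] <<- rbind(occupied[[chrom]], c(start, start + len))
      return(list(chrom = chrom, start = start, end = start + len))
    }
    stop("infeasible packing: could not place a ", family, " copy")
  }

  for (f in seq_len(nrow(library))) {
    fam <- library[f, ]
    for (cp in seq_len(fam$copy_number)) {
      pos <- place_one(fam$consensus_length, fam$name, fam$te_class, "normal")
      n_div <- rbinom(1L, fam$consensus_length, fam$per_copy_divergence)
      seq_mut <- fam$consensus
      if (n_div > 0L) {
        at <- sample.int(fam$consensus_length, n_div) - 1L
        seq_mut <- substitute_bases(seq_mut, at,
                                    other_base(substring(seq_mut, at + 1L, at + 1L)))
      }
      strand <- if (runif(1) < 0.5) "+" else "-"
      genome_seq <- if (strand == "+") seq_mut else revcomp(seq_mut)
      placements[[length(placements) + 1L]] <- list(
        chrom = pos$chrom, start = pos$start, end = pos$end, strand = strand,
        family = fam$name, te_class = fam$te_class, genome_seq = genome_seq,
        role = "normal")
    }
  }

  # --- nested same-family distractor scaffolding ---------------------------
  # a 200-bp fragment of the host's family consensus, written inside a long
  # host copy near its start (so the inner copy has room to move rightward
  # within the host in the query genome)
  lens <- vapply(placements, function(p) p$end - p$start, integer(1))
  host_ok <- which(lens >= 900L &
                     vapply(placements, function(p) p$role, character(1)) == "normal")
  if (params$n_nested_distractors > length(host_ok)) {
    stop("not enough long TE copies to host nested distractors")
  }
  hosts <- sample(host_ok, params$n_nested_distractors)
  nested <- list()
  inner_len <- 200L
  for (h in hosts) {
    placements[[h]]$role <- "nested_outer"
    host <- placements[[h]]
    fam <- library[library$name == host$family, ]
    frag <- substring(fam$consensus, 1L, inner_len)
    n_div <- max(1L, rbinom(1L, inner_len, 0.03))
    at <- sample.int(inner_len, min(n_div, inner_len)) - 1L
    frag <- substitute_bases(frag, at,
                             other_base(substring(frag, at + 1L, at + 1L)))
    offset <- 100L + sample.int(51L, 1L) - 1L     # inner offset in [100,150]
    placements[[length(placements) + 1L]] <- list(
      chrom = host$chrom, start = host$start + offset,
      end = host$start + offset + inner_len, strand = "+",
      family = host$family, te_class = host$te_class, genome_seq = frag,
      role = "nested_inner")
    nested[[length(nested) + 1L]] <- c(outer = h, inner = length(placements))
  }

  # --- write TE copies into the chromosomes --------------------------------
  # inner copies are written after their hosts and overwrite host interior
  vecs <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  for (p in placements) {
    vecs[[p$chrom]][(p$start + 1L):p$end] <-
      strsplit(p$genome_seq, "", fixed = TRUE)[[1]]
  }

  # --- twin-flank landing pads ---------------------------------------------
  # pick identical-flank TEs among clean class II copies and copy their
  # flanks to a second locus on the same chromosome
  roles <- vapply(placements, function(p) p$role, character(1))
  classes <- vapply(placements, function(p) p$te_class, character(1))
  lens <- vapply(placements, function(p) p$end - p$start, integer(1))
  twin_ok <- which(roles == "normal" & classes == "II" & lens <= 2000L)
  if (params$n_identical_flank_distractors > length(twin_ok)) {
    stop("not enough TE copies for identical-flank distractors")
  }
  twins <- if (params$n_identical_flank_distractors > 0L) {
    sample(twin_ok, params$n_identical_flank_distractors)
  } else integer(0)
  flank_sites <- list()
  for (t in twins) {
    placements[[t]]$role <- "flank_twin"
    p <- placements[[t]]
    placed <- FALSE
    for (try in 1:500) {
      d <- sample(params$intra_distance_range[1]:params$intra_distance_range[2], 1L)
      b <- p$start + sample(c(-1L, 1L), 1L) * d
      if (b < params$edge_margin || b + 100L > L - params$edge_margin) next
      if (!free_at(p$chrom, b, b + 100L, params$min_te_gap)) next
      occupied[[p$chrom]] <- rbind(occupied[[p$chrom]], c(b, b + 100L))
      up <- vecs[[p$chrom]][(p$start - 49L):p$start]
      dn <- vecs[[p$chrom]][(p$end + 1L):(p$end + 50L)]
      vecs[[p$chrom]][(b + 1L):(b + 100L)] <- c(up, dn)
      flank_sites[[length(flank_sites) + 1L]] <-
        list(placement = t, chrom = p$chrom, b_start = b)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place a twin-flank landing pad")
  }

  assembly <- genome_assembly(vapply(vecs, paste, character(1), collapse = ""))

  # --- annotation table with stable ids in coordinate order ----------------
  tes <- do.call(rbind, lapply(placements, function(p) {
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               strand = p$strand, family = p$family, te_class = p$te_class,
               role = p$role, stringsAsFactors = FALSE)
  }))
  if (is.null(tes)) {
    tes <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      family = character(0), te_class = character(0),
                      role = character(0), stringsAsFactors = FALSE)
  }
  ord <- order(match(tes$chrom, chroms), tes$start, tes$end)
  tes <- tes[ord, , drop = FALSE]
  tes$te_id <- if (nrow(tes)) paste0("te_", seq_len(nrow(tes))) else character(0)
  tes <- tes[, c("te_id", "chrom", "start", "end", "strand", "family",
                 "te_class", "role")]
  rownames(tes) <- NULL
  tes <- te_sequences(assembly, tes)
  id_of_placement <- tes$te_id[match(seq_along(placements), ord)]

  truth <- list(
    tes = tes,
    nested = if (length(nested)) data.frame(
      outer_id = vapply(nested, function(x) id_of_placement[x["outer"]], character(1)),
      inner_id = vapply(nested, function(x) id_of_placement[x["inner"]], character(1)),
      stringsAsFactors = FALSE) else
        data.frame(outer_id = character(0), inner_id = character(0)),
    flank_sites = if (length(flank_sites)) data.frame(
      te_id = vapply(flank_sites, function(x) id_of_placement[x$placement], character(1)),
      chrom = vapply(flank_sites, function(x) x$chrom, character(1)),
      b_start = vapply(flank_sites, function(x) x$b_start, integer(1)),
      stringsAsFactors = FALSE) else
        data.frame(te_id = character(0), chrom = character(0),
                   b_start = integer(0)),
    params = params, library = library)
  list(assembly = assembly, tes = tes, truth = truth)
}
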