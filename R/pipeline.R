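# Pipeline subcommands: simulate -> track -> enrich.  Each writes a
# run_config.log capturing the resolved configuration and package version,
# and derives its RNG stream from the master seed by labeled sub-seeding.

write_run_config <- function(outdir, subcommand, config) {
  flat <- unlist(config)
  lines <- c(sprintf("tetrack_version=%s",
                     as.character(utils::packageVersion("tetrack"))),
             sprintf("subcommand=%s", subcommand),
             sprintf("%s=%s", names(flat), as.character(flat)))
  writeLines(lines, file.path(outdir, "run_config.log"))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a reference/query genome pair with planted TE movements
#'
#' Writes `ref.fa`, `query.fa`, `ref_te.gff3`, `query_te.gff3`,
#' `variants.vcf`, `truth_movements.tsv`, `truth_te.tsv`, `coord_map.tsv`,
#' and `run_config.log` into `outdir`.  With a fixed seed every output is
#' byte-identical across runs.
#'
#' @param config A list with `outdir` and optionally `params`
#'   (a [simulation_params()] object) and `family_specs`.
#' @return Invisibly, a list with the simulation objects and file paths.
#' @export
run_simulate <- function(config) {
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params %||% simulation_params()
  specs <- config$family_specs %||% te_family_specs()
  lib <- make_te_library(specs, seed = params$rng_seed)
  ref <- simulate_reference(params, lib)
  qry <- derive_query(ref$assembly, ref$truth, params)

  write_fasta(ref$assembly, file.path(outdir, "ref.fa"))
  write_fasta(qry$assembly, file.path(outdir, "query.fa"))
  write_gff_te(ref$tes, file.path(outdir, "ref_te.gff3"))
  write_gff_te(qry$tes, file.path(outdir, "query_te.gff3"))
  write_vcf(qry$vcf, file.path(outdir, "variants.vcf"),
            assembly = ref$assembly)
  write_tsv(qry$movements, file.path(outdir, "truth_movements.tsv"))
  truth_te <- merge(ref$tes[, setdiff(names(ref$tes), "sequence")],
                    qry$te_map, by.x = "te_id", by.y = "ref_te_id",
                    all.x = TRUE)
  names(truth_te)[names(truth_te) == "te_id.y"] <- "query_te_id"
  truth_te <- truth_te[order(match(truth_te$chrom, names(ref$assembly)),
                             truth_te$start), ]
  write_tsv(truth_te, file.path(outdir, "truth_te.tsv"))
  write_tsv(qry$coord_map, file.path(outdir, "coord_map.tsv"))
  write_run_config(outdir, "simulate", params)
  invisible(list(reference = ref, query = qry, outdir = outdir))
}

#' Track TE movements between two assemblies
#'
#' Runs the full tracking pipeline: variant filtering, SNP fingerprinting,
#' uniqueness census, cross-referencing, synteny mapping (from a PAF file
#' when given, otherwise from the internal unique k-mer anchor aligner with
#' both TE annotation sets masked), and movement calling.  Writes
#' `fingerprints.tsv`, `matches.tsv`, `synteny_blocks.tsv`,
#' `movements.tsv`, `family_summary.tsv`, and `run_config.log`.
#'
#' @param config A list with paths `ref`, `query`, `ref_te`, `query_te`,
#'   `vcf`, `outdir`, optional `paf`, and optional parameters `tolerance`,
#'   `flank_identity_max`, `flank_rule`, `filter_inter`, `k`, `max_gap`,
#'   `min_qual`, `min_alt_depth`, `min_total_depth`.
#' @return Invisibly, a list with the tracking objects and file paths.
#' @export
run_track <- function(config) {
  for (f in c("ref", "query", "ref_te", "query_te", "vcf", "outdir")) {
    if (is.null(config[[f]])) stop("config$", f, " is required")
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- read_fasta(config$ref)
  query <- read_fasta(config$query)
  ref_tes <- te_sequences(ref, read_gff_te(config$ref_te))
  query_tes <- te_sequences(query, read_gff_te(config$query_te))
  variants <- read_vcf(config$vcf, assembly = ref)
  kept <- filter_variants(variants,
                          min_qual = config$min_qual %||% 30,
                          min_alt_depth = config$min_alt_depth %||% 10L,
                          min_total_depth = config$min_total_depth %||% 30L,
                          hom_only = TRUE)
  poly <- annotate_te_snps(ref_tes, kept)
  uniq <- uniquely_identifiable(poly, ref_tes)
  matches <- cross_reference(uniq, query_tes)
  map <- if (!is.null(config$paf)) {
    blocks_from_paf(read_paf(config$paf),
                    min_len = config$min_block_len %||% 1000L)
  } else {
    build_anchor_map(ref, query,
                     k = config$k %||% 21L,
                     max_gap = config$max_gap %||% 10000L,
                     mask_ref = ref_tes, mask_query = query_tes)
  }
  calls <- call_movements(matches, ref_tes, query_tes, map, ref, query,
                          tolerance = config$tolerance %||% 100L,
                          flank_identity_max = config$flank_identity_max %||% 0.90,
                          flank_rule = config$flank_rule %||% "either",
                          filter_inter = config$filter_inter %||% TRUE)
  fam <- summarize_by_family(calls, ref_tes)

  fp <- poly[, c("te_id", "chrom", "start", "end", "family", "n_snps")]
  fp$offsets <- vapply(poly$fingerprint, function(f) {
    paste(f$offset, collapse = ",")
  }, character(1))
  write_tsv(fp, file.path(outdir, "fingerprints.tsv"))
  write_tsv(matches, file.path(outdir, "matches.tsv"))
  write_synteny_blocks(map, file.path(outdir, "synteny_blocks.tsv"))
  write_tsv(calls, file.path(outdir, "movements.tsv"))
  write_tsv(fam, file.path(outdir, "family_summary.tsv"))
  write_run_config(outdir, "track", list(
    ref = config$ref, query = config$query, ref_te = config$ref_te,
    query_te = config$query_te, vcf = config$vcf,
    paf = config$paf %||% "", tolerance = config$tolerance %||% 100L,
    flank_identity_max = config$flank_identity_max %||% 0.90,
    flank_rule = config$flank_rule %||% "either",
    filter_inter = config$filter_inter %||% TRUE,
    k = config$k %||% 21L, max_gap = config$max_gap %||% 10000L,
    n_variants_in = nrow(variants), n_variants_kept = nrow(kept),
    n_fingerprinted = nrow(poly), n_unique = nrow(uniq)))
  invisible(list(fingerprints = poly, unique_tes = uniq, matches = matches,
                 map = map, calls = calls, family_summary = fam,
                 outdir = outdir))
}

#' Workspace-restricted enrichment of variants in annotations
#'
#' Converts a variant file (VCF or BED) to intervals, builds arm/center
#' workspaces (from chromosome lengths of a FASTA/VCF-declared genome or
#' from a workspace BED), and computes the permutation enrichment of the
#' variants in each annotation set within each workspace.  Writes
#' `enrichment.tsv` and `run_config.log`.
#'
#' @param config A list with `variants` (VCF or BED path), `annotations`
#'   (named character vector or list of BED paths), `outdir`, and either
#'   `genome` (FASTA path) or `workspace_bed`; optional `n_iter`,
#'   `arm_fraction`, `seed`.
#' @return Invisibly, the enrichment table.
#' @export
run_enrich <- function(config) {
  for (f in c("variants", "annotations", "outdir")) {
    if (is.null(config[[f]])) stop("config$", f, " is required")
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  vpath <- config$variants
  vints <- if (grepl("\\.vcf$", vpath, ignore.case = TRUE)) {
    variants_to_intervals(read_vcf(vpath))
  } else {
    read_bed(vpath)
  }
  workspaces <- if (!is.null(config$workspace_bed)) {
    define_workspaces(NULL, override_bed = config$workspace_bed)
  } else if (!is.null(config$genome)) {
    define_workspaces(chrom_lengths(read_fasta(config$genome)),
                      arm_fraction = config$arm_fraction %||% 1/3)
  } else {
    stop("config must supply either genome or workspace_bed")
  }
  ann_paths <- config$annotations
  if (is.null(names(ann_paths)) || any(!nzchar(names(ann_paths)))) {
    names(ann_paths) <- sub("\\.bed$", "", basename(unlist(ann_paths)),
                            ignore.case = TRUE)
  }
  annotation_sets <- lapply(ann_paths, read_bed)
  seed <- config$seed %||% 1L
  tab <- enrichment_table(list(variants = vints), annotation_sets,
                          workspaces, n_iter = config$n_iter %||% 20000L,
                          seed = seed)
  write_tsv(tab, file.path(outdir, "enrichment.tsv"))
  write_run_config(outdir, "enrich", list(
    variants = vpath, annotations = paste(unlist(ann_paths), collapse = ","),
    genome = config$genome %||% "", workspace_bed = config$workspace_bed %||% "",
    n_iter = config$n_iter %||% 20000L,
    arm_fraction = config$arm_fraction %||% 1/3, seed = seed))
  invisible(tab)
}
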