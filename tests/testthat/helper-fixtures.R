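# Shared fixtures.  The miniature simulation is expensive enough to build
# once and reuse across test files; test_dir runs everything in one
# session, so a closure cache works.

small_family_specs <- function() {
  data.frame(
    name = c("Zator", "hAT", "CMC", "Tc1/Mariner", "Sola", "MITE", "Gypsy"),
    te_class = c("II", "II", "II", "II", "II", "II", "I"),
    consensus_length = c(330L, 1000L, 1800L, 700L, 280L, 190L, 2600L),
    copy_number = c(20L, 8L, 4L, 5L, 3L, 2L, 2L),
    per_copy_divergence = c(0.02, 0.02, 0.02, 0.02, 0.02, 0.03, 0.02),
    stringsAsFactors = FALSE)
}

small_sim_params <- function(seed = 42L) {
  simulation_params(
    n_chromosomes = 2L, chromosome_length = 120000L,
    n_intra_moves = 2L, n_inter_moves = 2L,
    n_nested_distractors = 1L, n_identical_flank_distractors = 1L,
    n_duplication_distractors = 1L,
    intra_distance_range = c(300L, 30000L),
    rng_seed = seed)
}

.sim_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    params <- small_sim_params()
    lib <- make_te_library(small_family_specs(), seed = params$rng_seed)
    ref <- simulate_reference(params, lib)
    qry <- derive_query(ref$assembly, ref$truth, params)
    .sim_cache$sim <- list(params = params, ref = ref, qry = qry)
  }
  .sim_cache$sim
}

small_track <- function() {
  if (is.null(.sim_cache$track)) {
    s <- small_sim()
    ref_tes <- s$ref$tes
    query_tes <- s$qry$tes
    kept <- filter_variants(s$qry$vcf)
    poly <- annotate_te_snps(ref_tes, kept)
    uniq <- uniquely_identifiable(poly, ref_tes)
    matches <- cross_reference(uniq, query_tes)
    map <- build_anchor_map(s$ref$assembly, s$qry$assembly,
                            mask_ref = ref_tes, mask_query = query_tes)
    calls <- call_movements(matches, ref_tes, query_tes, map,
                            s$ref$assembly, s$qry$assembly)
    .sim_cache$track <- list(poly = poly, uniq = uniq, matches = matches,
                             map = map, calls = calls)
  }
  .sim_cache$track
}

# Indel-only genome pair for lift tests: no TEs, a fixed number of planted
# indels, plus the exact truth coordinate map.
indel_pair <- function(n_indels = 50L, seed = 7L) {
  key <- paste0("indel_", n_indels, "_", seed)
  if (is.null(.sim_cache[[key]])) {
    specs <- small_family_specs()
    specs$copy_number <- 0L
    params <- simulation_params(
      n_chromosomes = 2L, chromosome_length = 150000L,
      arm_snp_rate = 0.0005, center_snp_rate = 0.0005,
      indel_rate = n_indels / (2 * 150000 * 0.75),
      n_intra_moves = 0L, n_inter_moves = 0L,
      n_nested_distractors = 0L, n_identical_flank_distractors = 0L,
      n_duplication_distractors = 0L, rng_seed = seed)
    lib <- make_te_library(specs, seed = seed)
    ref <- simulate_reference(params, lib)
    qry <- derive_query(ref$assembly, ref$truth, params)
    .sim_cache[[key]] <- list(ref = ref$assembly, qry = qry$assembly,
                              coord_map = qry$coord_map, vcf = qry$vcf)
  }
  .sim_cache[[key]]
}
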