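make_tes <- function(chrom, start, end, family = "Zator", seqs = NULL,
                     assembly = NULL) {
  tes <- data.frame(te_id = paste0("te_", seq_along(start)), chrom = chrom,
                    start = start, end = end, strand = "+", family = family,
                    te_class = "II", stringsAsFactors = FALSE)
  if (!is.null(assembly)) tes <- te_sequences(assembly, tes)
  if (!is.null(seqs)) tes$sequence <- seqs
  tes
}

test_that("SNP fingerprinting computes offsets and omits SNP-free TEs", {
  set.seed(83)
  asm <- genome_assembly(c(I = random_dna_str(1000)))
  tes <- make_tes("I", c(100, 500), c(200, 700), assembly = asm)
  expect_equal(nrow(annotate_te_snps(tes, variant_records(character(0),
                                                          integer(0),
                                                          character(0),
                                                          character(0)))), 0L)
  ref_base <- substring(unclass(asm)[["I"]], 150, 150)
  v <- variant_records("I", 150, ref_base, setdiff(c("A", "C", "G", "T"),
                                                   ref_base)[1])
  poly <- annotate_te_snps(tes, v)
  expect_equal(nrow(poly), 1L)
  expect_equal(poly$te_id, "te_1")
  expect_equal(poly$fingerprint[[1]]$offset, 49L)  # (150-1) - 100
  expect_equal(substring(poly$projected_sequence, 50, 50), v$alt_allele)

  # REF allele disagreement is a hard error
  wrong <- variant_records("I", 150, setdiff(c("A", "C", "G", "T"),
                                             ref_base)[1], ref_base)
  expect_error(annotate_te_snps(tes, wrong), "mismatch")
})

test_that("TEs overlapped by indels are dropped from tracking", {
  set.seed(89)
  asm <- genome_assembly(c(I = random_dna_str(1000)))
  tes <- make_tes("I", c(100, 500), c(200, 700), assembly = asm)
  s150 <- substring(unclass(asm)[["I"]], 150, 150)
  s550 <- substring(unclass(asm)[["I"]], 550, 552)
  v <- rbind(
    variant_records("I", 150, s150, setdiff(c("A","C","G","T"), s150)[1]),
    variant_records("I", 550, s550, substring(s550, 1, 1)))  # deletion in te_2
  expect_message(poly <- annotate_te_snps(tes, v), "dropped")
  expect_equal(poly$te_id, "te_1")
})

test_that("fingerprint overlap assignment matches a brute-force all-pairs scan", {
  set.seed(97)
  L <- 20000
  asm <- genome_assembly(c(I = random_dna_str(L), II = random_dna_str(L)))
  n_te <- 120
  chrom <- sample(c("I", "II"), n_te, replace = TRUE)
  start <- sample(0:(L - 400), n_te)
  tes <- make_tes(chrom, start, start + sample(50:400, n_te, replace = TRUE),
                  assembly = asm)
  n_snp <- 800
  vc <- sample(c("I", "II"), n_snp, replace = TRUE)
  vp <- sample(L, n_snp)
  ref <- substring(unclass(asm)[vc], vp, vp)
  v <- variant_records(vc, vp, ref,
                       vapply(ref, function(b) setdiff(c("A","C","G","T"), b)[1],
                              character(1)))
  v <- v[!duplicated(paste(v$chrom, v$pos)), ]
  poly <- annotate_te_snps(tes, v)
  # oracle: quadratic interval check
  want <- lapply(seq_len(nrow(tes)), function(i) {
    hit <- v$chrom == tes$chrom[i] & v$pos - 1 >= tes$start[i] &
      v$pos - 1 < tes$end[i]
    sort(v$pos[hit])
  })
  has <- vapply(want, length, integer(1)) > 0
  expect_equal(poly$te_id, tes$te_id[has])
  for (j in seq_len(nrow(poly))) {
    i <- match(poly$te_id[j], tes$te_id)
    expect_equal(sort(poly$fingerprint[[j]]$offset + tes$start[i] + 1L),
                 want[[i]])
  }
})

test_that("applying variants is a pure substitution edit", {
  expect_equal(apply_variants("ACGTACGT",
                              data.frame(offset = 2L, ref = "G", alt = "T")),
               "ACTTACGT")
  expect_equal(apply_variants("ACGT", data.frame(offset = integer(0),
                                                 ref = character(0),
                                                 alt = character(0))), "ACGT")
  expect_error(apply_variants("ACGT", data.frame(offset = 9L, ref = "A",
                                                 alt = "T")), "range")
  set.seed(101)
  s <- random_dna_str(1000)
  off <- sample(0:999, 30)
  ref <- substring(s, off + 1, off + 1)
  alt <- vapply(ref, function(b) setdiff(c("A","C","G","T"), b)[1], character(1))
  got <- apply_variants(s, data.frame(offset = off, ref = ref, alt = alt))
  v <- strsplit(s, "")[[1]]; v[off + 1] <- alt
  expect_equal(got, paste(v, collapse = ""))
  expect_equal(nchar(got), nchar(s))
  # composition change equals the SNP count
  expect_equal(sum(strsplit(got, "")[[1]] != strsplit(s, "")[[1]]), 30L)
})

test_that("uniqueness census drops duplicated sequences in either orientation", {
  seqs <- c(strrep("ACGTA", 40), strrep("ACGTA", 40), random_dna_str(200),
            random_dna_str(200))
  seqs[4] <- revcomp_oracle(seqs[3])   # same element, opposite orientation
  tes <- make_tes("I", c(0, 300, 600, 900), c(200, 500, 800, 1100),
                  seqs = seqs)
  poly <- tes
  poly$projected_sequence <- poly$sequence
  poly$n_snps <- 1L
  u <- uniquely_identifiable(poly, tes)
  expect_equal(nrow(u), 0L)

  single <- make_tes("I", 0, 200, seqs = random_dna_str(200))
  ps <- single; ps$projected_sequence <- ps$sequence; ps$n_snps <- 1L
  expect_equal(nrow(uniquely_identifiable(ps, single)), 1L)
})

test_that("uniqueness on the miniature genome matches a sequence-multiset census", {
  s <- small_sim()
  tr <- small_track()
  canon <- function(x) pmin(x, revcomp_oracle(x))
  raw_count <- table(canon(s$ref$tes$sequence))
  proj_count <- table(canon(tr$poly$projected_sequence))
  want <- tr$poly$te_id[raw_count[canon(tr$poly$sequence)] == 1 &
                          proj_count[canon(tr$poly$projected_sequence)] == 1]
  expect_setequal(tr$uniq$te_id, want)
})

test_that("cross-referencing finds exact matches in either orientation", {
  qseqs <- c(random_dna_str(200), random_dna_str(180))
  qtes <- make_tes("II", c(0, 400), c(200, 580), seqs = qseqs)
  u <- make_tes("I", c(0, 300), c(200, 480),
                seqs = c("x", "y"))
  u$projected_sequence <- c(qseqs[1], revcomp_oracle(qseqs[2]))
  m <- cross_reference(u, qtes)
  expect_equal(m$match_class, c("unique", "unique"))
  expect_equal(m$orientation_flip, c(FALSE, TRUE))
  expect_equal(m$query_te_ids, c("te_1", "te_2"))

  # duplicated query sequence gives a multiple match
  qdup <- make_tes("II", c(0, 400), c(200, 600), seqs = rep(qseqs[1], 2))
  m2 <- cross_reference(u[1, ], qdup)
  expect_equal(m2$match_class, "multiple")
  expect_equal(m2$query_te_ids, "te_1,te_2")
  # and no match at all gives none
  m3 <- cross_reference(u[1, ], make_tes("II", 0, 150,
                                         seqs = random_dna_str(150)))
  expect_equal(m3$match_class, "none")
})

test_that("the full match table equals a quadratic all-pairs comparison", {
  s <- small_sim(); tr <- small_track()
  got <- tr$matches
  qte <- s$qry$tes
  for (i in seq_len(nrow(tr$uniq))) {
    proj <- tr$uniq$projected_sequence[i]
    hits <- qte$te_id[qte$sequence == proj |
                        qte$sequence == revcomp_oracle(proj)]
    row <- got[got$ref_te_id == tr$uniq$te_id[i], ]
    expect_equal(row$match_class,
                 c("none", "unique", "multiple")[min(length(hits), 2) + 1])
    expect_equal(row$query_te_ids, paste(hits, collapse = ","))
  }
})

test_that("matched query sequences invert back to the reference sequence", {
  # applying the fingerprint SNPs in reverse to a uniquely matched query TE
  # recovers the reference TE sequence exactly (reciprocality of projection)
  tr <- small_track()
  s <- small_sim()
  um <- tr$matches[tr$matches$match_class == "unique", ]
  for (i in sample(seq_len(nrow(um)), min(20, nrow(um)))) {
    u <- tr$uniq[tr$uniq$te_id == um$ref_te_id[i], ]
    q <- s$qry$tes[s$qry$tes$te_id == um$query_te_ids[i], ]
    qs <- if (isTRUE(um$orientation_flip[i])) revcomp_oracle(q$sequence) else
      q$sequence
    fp <- u$fingerprint[[1]]
    back <- apply_variants(qs, data.frame(offset = fp$offset, ref = fp$alt,
                                          alt = fp$ref))
    expect_equal(back, u$sequence)
  }
})
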