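test_that("FASTA round trip preserves records, names, and case folding", {
  asm <- genome_assembly(c(chr1 = "acgt", chr2 = "NNNN"))
  expect_equal(unname(chrom_lengths(asm)), c(4L, 4L))
  expect_equal(unclass(asm)[["chr1"]], "ACGT")

  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(asm, path)
  back <- read_fasta(path)
  expect_identical(unclass(back), unclass(asm))

  # random records against a naive parser, across line-wrap boundaries
  set.seed(31)
  n <- 40
  seqs <- setNames(vapply(sample(5:400, n, replace = TRUE), random_dna_str,
                          character(1)),
                   paste0("rec", seq_len(n)))
  write_fasta(genome_assembly(seqs), path, width = 17L)
  expect_identical(fasta_oracle(path), seqs)
  expect_identical(unclass(read_fasta(path)), seqs)
})

test_that("genome_assembly rejects malformed input", {
  expect_error(genome_assembly(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(genome_assembly(c(a = "")), "empty")
  expect_error(genome_assembly(c(a = "ACGTX")), "outside")
  expect_error(genome_assembly("ACGT"), "named")
})

test_that("VCF reading splits multi-allelic sites and parses depth fields", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=I,length=1000>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s", sep = "\t"),
    "I\t10\t.\tC\tT\t45\tPASS\t.\tGT:AD:DP\t1/1:2,40:42",
    "I\t20\t.\tA\tC,T\t30\tPASS\t.\tGT:AD:DP\t1/2:5,10,15:30",
    "I\t30\t.\tAT\tA\t50\tPASS\t.\tGT:AD:DP\t0/1:20,12:32"), path)
  rec <- read_vcf(path)
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$zygosity, c("hom", "het", "het", "het"))
  expect_equal(rec$alt_depth, c(40L, 10L, 15L, 12L))
  expect_equal(rec$total_depth, c(42L, 30L, 30L, 32L))
  expect_true(all(is_snp(rec) == c(TRUE, TRUE, TRUE, FALSE)))

  # position validation against an assembly
  asm <- genome_assembly(c(I = strrep("A", 25)))
  expect_error(read_vcf(path, assembly = asm), "beyond")
})

test_that("VCF writing round-trips through read_vcf", {
  set.seed(5)
  asm <- genome_assembly(c(I = random_dna_str(500), II = random_dna_str(400)))
  n <- 60
  pos <- sort(sample(2:390, n))
  ref <- substring(unclass(asm)[["I"]], pos, pos)
  rec <- variant_records("I", pos, ref,
                         vapply(ref, function(b) setdiff(c("A","C","G","T"), b)[1],
                                character(1)),
                         qual = round(runif(n, 10, 90), 1),
                         alt_depth = sample(5:40, n, replace = TRUE),
                         total_depth = sample(40:80, n, replace = TRUE),
                         zygosity = sample(c("hom", "het"), n, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(rec, path, assembly = asm)
  back <- read_vcf(path, assembly = asm)
  expect_equal(back$pos, rec$pos)
  expect_equal(back$ref_allele, rec$ref_allele)
  expect_equal(back$alt_allele, rec$alt_allele)
  expect_equal(back$qual, rec$qual)
  expect_equal(back$alt_depth, rec$alt_depth)
  expect_equal(back$total_depth, rec$total_depth)
  expect_equal(back$zygosity, rec$zygosity)

  # record count equals a line-count oracle
  body <- grep("^[^#]", readLines(path), value = TRUE)
  expect_equal(nrow(back), length(body))
})

test_that("variant filter keeps exactly the records meeting the thresholds", {
  # boundary case: all thresholds exactly met
  boundary <- variant_records("I", 10, "C", "T", qual = 30, alt_depth = 10,
                              total_depth = 30, zygosity = "hom")
  expect_equal(nrow(filter_variants(boundary)), 1L)
  # just below the QUAL bound, everything else generous
  low_q <- variant_records("I", 10, "C", "T", qual = 29.9, alt_depth = 100,
                           total_depth = 200, zygosity = "hom")
  expect_equal(nrow(filter_variants(low_q)), 0L)

  # randomized table against an independent predicate scan
  set.seed(17)
  n <- 1000
  rec <- variant_records(
    "I", seq_len(n), "A", "T",
    qual = sample(c(0, 15, 29.9, 30, 30.1, 60, 100), n, replace = TRUE),
    alt_depth = alt <- sample(c(0L, 5L, 9L, 10L, 11L, 40L), n, replace = TRUE),
    total_depth = alt + sample(c(0L, 10L, 19L, 20L, 21L, 40L), n, replace = TRUE),
    zygosity = sample(c("hom", "het"), n, replace = TRUE))
  kept <- filter_variants(rec)
  want <- mapply(function(q, a, d, z) {
    isTRUE(q >= 30) && isTRUE(a >= 10) && isTRUE(d >= 30) && z == "hom"
  }, rec$qual, rec$alt_depth, rec$total_depth, rec$zygosity)
  expect_equal(kept$pos, rec$pos[want])
  # idempotent and order preserving
  expect_identical(filter_variants(kept), kept)
  expect_true(!is.unsorted(kept$pos))
})

test_that("records with missing depth annotations are rejected with a warning", {
  rec <- variant_records("I", c(1, 2), "A", "T", qual = c(50, 50),
                         alt_depth = c(20L, NA), total_depth = c(60L, NA))
  expect_warning(out <- filter_variants(rec), "lacked")
  expect_equal(out$pos, 1L)
})

test_that("BED and GFF3 conversions are exact inverses of each other", {
  # GFF3 is 1-based inclusive: start=1,end=10 becomes [0,10)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "I\tx\ttransposable_element\t1\t10\t.\t+\t.\tID=t1;family=Zator;te_class=II"),
             gff)
  tes <- read_gff_te(gff)
  expect_equal(tes$start, 0L)
  expect_equal(tes$end, 10L)

  set.seed(23)
  n <- 200
  start <- sample(0:5000, n)
  tes <- data.frame(te_id = paste0("t", seq_len(n)),
                    chrom = sample(c("I", "II"), n, replace = TRUE),
                    start = start, end = start + sample(1:300, n, replace = TRUE),
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    family = "Zator", te_class = "II",
                    stringsAsFactors = FALSE)
  write_gff_te(tes, gff)
  back <- read_gff_te(gff)
  expect_equal(back$start, tes$start)
  expect_equal(back$end, tes$end)
  # the GFF3 text itself is 1-based inclusive (an independent check of the
  # written convention)
  body <- strsplit(grep("^[^#]", readLines(gff), value = TRUE), "\t")
  expect_equal(as.integer(vapply(body, `[`, "", 4)), tes$start + 1L)
  expect_equal(as.integer(vapply(body, `[`, "", 5)), tes$end)

  bed <- withr::local_tempfile(fileext = ".bed")
  iv <- intervals(tes$chrom, tes$start, tes$end, tes$strand, tes$te_id)
  write_bed(iv, bed)
  back2 <- read_bed(bed)
  expect_equal(back2$start, iv$start)
  expect_equal(back2$end, iv$end)
  expect_equal(back2$label, iv$label)
  expect_equal(back2$strand, iv$strand)
})

test_that("PAF parsing keeps the 12 mandatory columns and skips bad rows", {
  paf <- withr::local_tempfile(fileext = ".paf")
  good <- paste("q1", 1000, 100, 900, "+", "t1", 2000, 300, 1100, 750, 800, 60,
                sep = "\t")
  writeLines(c(good, "broken\trow"), paf)
  expect_message(rows <- read_paf(paf), "1 malformed")
  expect_equal(nrow(rows), 1L)
  expect_equal(rows$target_start, 300L)
  expect_equal(rows$strand, "+")
})
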