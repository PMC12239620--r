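# Independent oracles used by the tests.  These deliberately re-derive
# results with the most naive possible method (full DP matrices, per-base
# bitmaps, character-vector editing) and never call the package internals
# they are checking.

# Brute-force Smith-Waterman with affine gaps: three (n+1)x(m+1) matrices,
# gap of length L costs go + L*ge, local score floored at zero.
sw_oracle <- function(a, b, match = 1, mis = 19, go = 39, ge = 3) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(E[i + 1, j] - ge, H[i + 1, j] - go - ge)
      F[i + 1, j + 1] <- max(F[i, j + 1] - ge, H[i, j + 1] - go - ge)
      s <- if (va[i] == vb[j]) match else -mis
      H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

# Naive FASTA parser (no Biostrings): returns a named character vector.
fasta_oracle <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  out <- character(0)
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    nm <- sub("^>\\s*", "", lines[heads[i]])
    nm <- sub("\\s.*$", "", nm)
    out[nm] <- paste(lines[from:to], collapse = "")
  }
  toupper(out)
}

# Naive editor: apply a variant-record table (reference frame, anchored
# indels) to an assembly by character-vector surgery.  Indels are applied
# from the right so earlier coordinates stay valid.
apply_vcf_oracle <- function(assembly, records) {
  seqs <- lapply(unclass(assembly), function(s) strsplit(s, "")[[1]])
  snp <- records[nchar(records$ref_allele) == 1L &
                   nchar(records$alt_allele) == 1L, , drop = FALSE]
  ind <- records[!(nchar(records$ref_allele) == 1L &
                     nchar(records$alt_allele) == 1L), , drop = FALSE]
  for (i in seq_len(nrow(snp))) {
    stopifnot(seqs[[snp$chrom[i]]][snp$pos[i]] == snp$ref_allele[i])
    seqs[[snp$chrom[i]]][snp$pos[i]] <- snp$alt_allele[i]
  }
  ind <- ind[order(-ind$pos), , drop = FALSE]
  for (i in seq_len(nrow(ind))) {
    v <- seqs[[ind$chrom[i]]]
    p <- ind$pos[i]                      # 1-based anchor position
    rlen <- nchar(ind$ref_allele[i])
    stopifnot(paste(v[p:(p + rlen - 1L)], collapse = "") == ind$ref_allele[i])
    alt <- strsplit(ind$alt_allele[i], "")[[1]]
    seqs[[ind$chrom[i]]] <- c(v[seq_len(p - 1L)], alt,
                              if (p + rlen <= length(v)) v[(p + rlen):length(v)])
  }
  vapply(seqs, paste, character(1), collapse = "")
}

# Per-base bitmap overlap of two interval sets on a small genome.
overlap_oracle <- function(setA, setB, chrom_len) {
  total <- 0L
  for (chrom in names(chrom_len)) {
    bA <- logical(chrom_len[[chrom]]); bB <- logical(chrom_len[[chrom]])
    a <- setA[setA$chrom == chrom, , drop = FALSE]
    b <- setB[setB$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(a))) bA[(a$start[i] + 1L):a$end[i]] <- TRUE
    for (i in seq_len(nrow(b))) bB[(b$start[i] + 1L):b$end[i]] <- TRUE
    total <- total + sum(bA & bB)
  }
  total
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_oracle <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
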