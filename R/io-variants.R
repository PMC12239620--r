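#' Construct a table of variant records
#'
#' Variants follow the VCF convention: `pos` is 1-based, indels are anchored
#' on the base preceding the event, and both alleles are non-empty.  A record
#' is a SNP iff both alleles have length 1.
#'
#' @param chrom,pos,ref_allele,alt_allele,qual,alt_depth,total_depth,zygosity
#'   Parallel vectors; `zygosity` is `"hom"` or `"het"`.
#' @return A `data.frame` with one row per variant.
#' @export
variant_records <- function(chrom, pos, ref_allele, alt_allele,
                            qual = NA_real_, alt_depth = NA_integer_,
                            total_depth = NA_integer_, zygosity = "hom") {
  n <- max(length(chrom), length(pos), length(ref_allele),
           length(alt_allele))
  if (length(chrom) == 0L) n <- 0L
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref_allele = rep_len(toupper(as.character(ref_allele)), n),
    alt_allele = rep_len(toupper(as.character(alt_allele)), n),
    qual = rep_len(as.numeric(qual), n),
    alt_depth = rep_len(as.integer(alt_depth), n),
    total_depth = rep_len(as.integer(total_depth), n),
    zygosity = rep_len(as.character(zygosity), n),
    stringsAsFactors = FALSE
  )
  if (any(df$pos < 1L)) stop("variant pos must be >= 1 (VCF convention)")
  if (any(!nzchar(df$ref_allele)) || any(!nzchar(df$alt_allele))) {
    stop("alleles must be non-empty")
  }
  ok_depth <- is.na(df$alt_depth) | is.na(df$total_depth) |
    df$alt_depth <= df$total_depth
  if (any(!ok_depth)) stop("alt_depth must not exceed total_depth")
  if (any(!df$zygosity %in% c("hom", "het"))) {
    stop("zygosity must be 'hom' or 'het'")
  }
  df
}

#' Is a variant record a SNP?
#' @param records Variant record table.
#' @return Logical vector.
#' @export
is_snp <- function(records) {
  nchar(records$ref_allele) == 1L & nchar(records$alt_allele) == 1L
}

# Zygosity from a VCF GT string for one alt allele index (1-based within the
# site's ALT list).  "1/1" is homozygous; "0/1", "1/0", "1/2" are
# heterozygous for that allele; a missing GT is treated as homozygous (the
# expected input is a strain-vs-reference VCF) with a warning upstream.
gt_zygosity <- function(gt, alt_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_character_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  hits <- sum(alleles == as.character(alt_index))
  if (hits == 0L) return(NA_character_)
  if (hits == length(alleles)) "hom" else "het"
}

#' Read a VCF file into a variant record table
#'
#' Multi-allelic sites are split into one record per alternate allele, in
#' file order.  Per-allele supporting depth is taken from the `AD` field and
#' total depth from `DP` (falling back to the sum of `AD`).  Records with a
#' missing genotype are treated as homozygous with a warning.
#'
#' @param path Path to a VCF 4.x file.
#' @param assembly Optional [genome_assembly()]; when supplied, positions
#'   beyond the chromosome ends raise an error.
#' @return A variant record table (see [variant_records()]).
#' @export
read_vcf <- function(path, assembly = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0L) {
    return(variant_records(character(0), integer(0), character(0), character(0)))
  }
  has_gt <- ncol(v@gt) >= 2L
  out <- vector("list", nrow(fix))
  n_missing_gt <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    gt <- NA_character_; ad <- NULL; dp <- NA_integer_
    if (has_gt) {
      keys <- strsplit(v@gt[i, 1L], ":", fixed = TRUE)[[1]]
      vals <- strsplit(v@gt[i, 2L], ":", fixed = TRUE)[[1]]
      fields <- setNames(as.list(vals), keys)
      gt <- fields[["GT"]] %||% NA_character_
      if (!is.null(fields[["AD"]])) {
        ad <- suppressWarnings(as.integer(strsplit(fields[["AD"]], ",", fixed = TRUE)[[1]]))
      }
      if (!is.null(fields[["DP"]])) {
        dp <- suppressWarnings(as.integer(fields[["DP"]]))
      }
    }
    if (is.na(dp) && !is.null(ad)) dp <- sum(ad, na.rm = TRUE)
    rows <- lapply(seq_along(alts), function(j) {
      zyg <- gt_zygosity(gt, j)
      if (is.na(zyg)) {
        n_missing_gt <<- n_missing_gt + 1L
        zyg <- "hom"
      }
      adj <- if (!is.null(ad) && length(ad) >= j + 1L) ad[j + 1L] else NA_integer_
      variant_records(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                      fix[i, "REF"], alts[j], qual, adj, dp, zyg)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  if (n_missing_gt > 0L) {
    warning(n_missing_gt,
            " record(s) had missing or non-alt genotypes; treated as homozygous")
  }
  if (!is.null(assembly)) {
    len <- chrom_lengths(assembly)
    if (any(!rec$chrom %in% names(len))) {
      stop("VCF chromosome(s) absent from assembly: ",
           paste(setdiff(unique(rec$chrom), names(len)), collapse = ", "))
    }
    span_end <- rec$pos - 1L + nchar(rec$ref_allele)
    if (any(span_end > len[rec$chrom])) {
      stop("variant position(s) beyond chromosome end")
    }
  }
  rec
}

#' Write a variant record table to a minimal VCF 4.2 file
#'
#' @param records Variant record table.
#' @param path Output path.
#' @param assembly Optional assembly used to emit `##contig` header lines.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, assembly = NULL, sample_name = "query") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(assembly)) {
    len <- chrom_lengths(assembly)
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(len), len), con)
  }
  writeLines(c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")), con)
  if (nrow(records) > 0L) {
    gt <- ifelse(records$zygosity == "hom", "1/1", "0/1")
    ref_d <- ifelse(is.na(records$total_depth) | is.na(records$alt_depth), 0L,
                    records$total_depth - records$alt_depth)
    ad <- paste(ref_d, ifelse(is.na(records$alt_depth), 0L, records$alt_depth),
                sep = ",")
    dp <- ifelse(is.na(records$total_depth), ".",
                 as.character(records$total_depth))
    qual <- ifelse(is.na(records$qual), ".",
                   formatC(records$qual, format = "g", digits = 6))
    writeLines(paste(records$chrom, records$pos, ".", records$ref_allele,
                     records$alt_allele, qual, "PASS", ".", "GT:AD:DP",
                     paste(gt, ad, dp, sep = ":"), sep = "\t"), con)
  }
  invisible(path)
}

#' Apply the variant retention filter
#'
#' Retains records with `qual >= min_qual`, `alt_depth >= min_alt_depth`,
#' `total_depth >= min_total_depth`, and (by default) homozygous genotype.
#' Records with missing quality or depth annotations are rejected with a
#' warning rather than raising an error.  The defaults are the thresholds
#' used for strain-vs-reference short-read variant calls: QUAL of 30 or
#' greater, at least 10 variant-supporting reads, and at least 30 total
#' high-quality reads, keeping only sites homozygous in the query strain.
#'
#' @param records Variant record table.
#' @param min_qual,min_alt_depth,min_total_depth Retention thresholds.
#' @param hom_only Keep only homozygous records (default `TRUE`).
#' @return The retained records, in input order.
#' @export
filter_variants <- function(records, min_qual = 30, min_alt_depth = 10L,
                            min_total_depth = 30L, hom_only = TRUE) {
  if (nrow(records) == 0L) return(records)
  missing_ann <- is.na(records$qual) | is.na(records$alt_depth) |
    is.na(records$total_depth)
  if (any(missing_ann)) {
    warning(sum(missing_ann),
            " record(s) lacked QUAL or depth annotations and were rejected")
  }
  keep <- !missing_ann &
    records$qual >= min_qual &
    records$alt_depth >= min_alt_depth &
    records$total_depth >= min_total_depth
  if (hom_only) keep <- keep & records$zygosity == "hom"
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
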