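#' Construct a genome assembly object
#'
#' A genome assembly is an ordered, named set of chromosome sequences.  It is
#' stored as a named character vector of uppercase DNA strings and carries the
#' class `"genome_assembly"`.  All other coordinates in the package (TE
#' annotations, synteny blocks, workspaces) refer to these sequences using
#' 0-based half-open intervals.
#'
#' @param sequences Named character vector of DNA sequences (alphabet
#'   `A/C/G/T/N`; lowercase is folded to uppercase).
#' @return A `genome_assembly` object.
#' @export
genome_assembly <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate chromosome names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  }
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) stop("empty sequence records are not allowed")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("sequences contain characters outside {A,C,G,T,N}: ",
         paste(names(sequences)[bad], collapse = ", "))
  }
  structure(sequences, class = "genome_assembly")
}

#' Chromosome lengths of an assembly
#' @param assembly A `genome_assembly`.
#' @return Named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(assembly) {
  setNames(nchar(unclass(assembly)), names(assembly))
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly:", length(x), "chromosome(s),",
      format(sum(chrom_lengths(x)), big.mark = ","), "bp\n")
  print(chrom_lengths(x))
  invisible(x)
}

#' Read a FASTA file into a genome assembly
#'
#' Record order is preserved, lowercase is folded to uppercase, and the
#' sequence name is the first whitespace-delimited word of the header.
#'
#' @param path Path to a FASTA file.
#' @return A [genome_assembly()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  genome_assembly(setNames(as.character(ss), nm))
}

#' Write a genome assembly to FASTA
#'
#' @param assembly A `genome_assembly`.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(assembly))
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}
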