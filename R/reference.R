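#' Read a reference FASTA into memory
#'
#' Loads every sequence of a FASTA file and returns a named character vector
#' of uppercase sequences. Names are the first whitespace-delimited token of
#' each FASTA header, matching the contig names used in VCF files.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return Named character vector; one element per contig, alphabet A,C,G,T,N.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

# 1-based closed-interval substring of one contig, clamped to contig bounds.
# Returns "" when the clamped interval is empty.
ref_sub <- function(reference, contig, start, end) {
  seq <- get_contig(reference, contig)
  start <- max(1L, as.integer(start))
  end <- min(nchar(seq), as.integer(end))
  if (end < start) return("")
  substr(seq, start, end)
}

get_contig <- function(reference, contig) {
  if (!contig %in% names(reference)) {
    stop("contig '", contig, "' absent from reference FASTA")
  }
  reference[[contig]]
}

#' Reverse complement of a DNA string
#'
#' @param x DNA string over A,C,G,T,N.
#' @return The reverse complement as a character scalar.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# GC percentage of a DNA string (N counts in the denominator).
gc_percent <- function(x) {
  if (nchar(x) == 0) return(NA_real_)
  b <- strsplit(x, "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

# Apply one REF -> ALT substitution at a 1-based position of a sequence.
apply_variant <- function(seq, pos, ref, alt) {
  paste0(
    substr(seq, 1L, pos - 1L),
    alt,
    substr(seq, pos + nchar(ref), nchar(seq))
  )
}
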