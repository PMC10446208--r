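#' Construct a biallelic variant record
#'
#' A variant record is the unit passed between all annotation stages: one
#' contig, a 1-based position, single REF and ALT alleles, an identifier and
#' an optional genotype string.
#'
#' @param contig Contig name; must match a FASTA sequence name.
#' @param pos 1-based position of the first REF base.
#' @param ref REF allele (non-empty DNA string).
#' @param alt ALT allele (non-empty DNA string, no symbolic alleles).
#' @param id Record identifier, `"."` when absent.
#' @param gt Genotype string such as `"0/1"`, `NA` when absent.
#' @return A list with fields `contig`, `pos`, `ref`, `alt`, `id`, `gt`.
#' @export
variant_record <- function(contig, pos, ref, alt, id = ".", gt = NA_character_) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  stopifnot(nchar(ref) >= 1, nchar(alt) >= 1, pos >= 1)
  if (ref == alt) stop("REF and ALT must differ")
  if (!grepl("^[ACGTN]+$", ref) || !grepl("^[ACGTN]+$", alt)) {
    stop("alleles must be over A,C,G,T,N")
  }
  list(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
       id = id, gt = gt)
}

#' Classify a variant by its allele shapes
#'
#' Pure insertions and deletions are recognised in their anchored (normalized)
#' form: a deletion has a single-base ALT equal to the first REF base, an
#' insertion has a single-base REF equal to the first ALT base. Everything
#' else is an SNV, MNV, or complex substitution.
#'
#' @param ref,alt Allele strings.
#' @return One of `"snv"`, `"mnv"`, `"del"`, `"ins"`, `"complex"`.
#' @export
classify_variant <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  if (lr == la) {
    if (lr == 1L) "snv" else "mnv"
  } else if (la == 1L && lr > 1L && substr(ref, 1L, 1L) == alt) {
    "del"
  } else if (lr == 1L && la > 1L && substr(alt, 1L, 1L) == ref) {
    "ins"
  } else {
    "complex"
  }
}

# TRUE when either allele carries an N base.
has_n_allele <- function(variant) {
  grepl("N", variant$ref, fixed = TRUE) || grepl("N", variant$alt, fixed = TRUE)
}

# One-row data.frame view of a variant record (used to build output tables).
variant_as_row <- function(variant) {
  data.frame(contig = variant$contig, pos = variant$pos, ref = variant$ref,
             alt = variant$alt, id = variant$id,
             genotype = ifelse(is.na(variant$gt), ".", variant$gt),
             stringsAsFactors = FALSE)
}
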