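#' Normalize a variant to its parsimonious, left-aligned representation
#'
#' A variant is parsimonious when it is represented in as few nucleotides as
#' possible without a zero-length allele, and left-aligned when its position
#' cannot be shifted further 5' while keeping allele lengths constant. SNVs
#' pass through unchanged. For indels and MNVs the algorithm first trims
#' common rightmost bases, extending both alleles one reference base to the
#' left whenever an allele would become empty, then trims common leftmost
#' bases while both alleles are longer than one base.
#'
#' @param variant A variant record (see [variant_record()]).
#' @param reference Named character vector from [read_reference()].
#' @return The variant with updated `pos`, `ref`, `alt`, plus
#'   `original_pos`/`original_ref`/`original_alt` and a logical `normalized`
#'   flag (FALSE only when left extension would run off the contig start, in
#'   which case the record is returned unchanged with a warning).
#' @export
normalize_variant <- function(variant, reference) {
  seq <- get_contig(reference, variant$contig)
  out <- variant
  out$original_pos <- variant$pos
  out$original_ref <- variant$ref
  out$original_alt <- variant$alt
  out$normalized <- TRUE

  pos <- variant$pos
  ref <- toupper(variant$ref)
  alt <- toupper(variant$alt)

  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    out$ref <- ref
    out$alt <- alt
    return(out)
  }

  # Right-trim shared last bases; left-extend with the reference base when an
  # allele empties out.
  repeat {
    lr <- nchar(ref)
    la <- nchar(alt)
    if (lr > 0L && la > 0L &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
      next
    }
    if (lr == 0L || la == 0L) {
      if (pos <= 1L) {
        warning("cannot left-extend variant at ", variant$contig, ":",
                variant$pos, " beyond contig start; left unnormalized")
        out$normalized <- FALSE
        return(out)
      }
      pos <- pos - 1L
      b <- substr(seq, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      next
    }
    break
  }

  # Left-trim shared first bases while both alleles keep length > 1.
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
    pos <- pos + 1L
  }

  out$pos <- pos
  out$ref <- ref
  out$alt <- alt
  out
}

#' Test whether a variant is already parsimonious and left-aligned
#'
#' @inheritParams normalize_variant
#' @return TRUE iff `variant` equals its own normalization.
#' @export
is_normalized <- function(variant, reference) {
  nv <- suppressWarnings(normalize_variant(variant, reference))
  isTRUE(nv$normalized) &&
    nv$pos == variant$pos && nv$ref == variant$ref && nv$alt == variant$alt
}
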