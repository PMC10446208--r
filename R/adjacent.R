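#' 3'-edge position of a variant
#'
#' For a pure (anchored) insertion or deletion, walks the reference 3' of the
#' indel: while the leftmost base of the indel pattern (the anchor-trimmed
#' REF or ALT) equals the next reference base, the pattern is rotated left by
#' one and the edge advances by one. For SNV/MNV/complex records the edge is
#' the position of the last REF base.
#'
#' @param variant A normalized variant record.
#' @param reference Named character vector from [read_reference()].
#' @return List with `edge` (1-based position), `pattern` (anchor-trimmed
#'   indel pattern, unrotated), `pattern_3p` (pattern rotated to its 3'-most
#'   placement) and `class` (see [classify_variant()]).
#' @export
three_prime_edge <- function(variant, reference) {
  seq <- get_contig(reference, variant$contig)
  cls <- classify_variant(variant$ref, variant$alt)
  if (!cls %in% c("del", "ins")) {
    return(list(edge = variant$pos + nchar(variant$ref) - 1L,
                pattern = NA_character_, pattern_3p = NA_character_,
                class = cls))
  }
  pattern <- if (cls == "del") substring(variant$ref, 2L) else substring(variant$alt, 2L)
  n <- nchar(pattern)
  # First 3'-adjacent reference base: past the deleted run for deletions,
  # right after the anchor for insertions. Initial edge is one base 5' of it.
  edge <- if (cls == "del") variant$pos + n else variant$pos
  cur <- pattern
  pos3 <- edge + 1L
  L <- nchar(seq)
  while (pos3 <= L && substr(cur, 1L, 1L) == substr(seq, pos3, pos3)) {
    cur <- paste0(substring(cur, 2L), substr(cur, 1L, 1L))
    edge <- pos3
    pos3 <- pos3 + 1L
  }
  list(edge = edge, pattern = pattern, pattern_3p = cur, class = cls)
}

#' Breakpoint-ambiguity annotation of a variant
#'
#' Computes the 5'-aligned, 3'-aligned and 3'-edge positions. For a
#' deletion the 5'-aligned position is the leftmost possible first deleted
#' base (`pos + 1` of the left-aligned record), the 3'-aligned position is
#' the first base of the 3'-most equivalent deleted run (edge - pattern
#' length + 1). For an insertion the 5'-aligned position is the leftmost
#' possible 5'-adjacent base (the record position) and the 3'-aligned
#' position equals the edge, the rightmost possible 5'-adjacent base.
#' SNV/MNV/complex variants are never ambiguous. A variant is flagged
#' `ambiguous` when its 5'- and 3'-aligned positions differ, and
#' `in_duplicate` when the shift range spans at least one full copy of the
#' indel pattern (see [in_duplicate()]).
#'
#' @inheritParams three_prime_edge
#' @return List with `five`, `three`, `edge`, `ambiguous`, `in_duplicate`,
#'   `class`, `pattern`, `pattern_3p` and pattern length `n`.
#' @export
aligned_positions <- function(variant, reference) {
  w <- three_prime_edge(variant, reference)
  cls <- w$class
  if (!cls %in% c("del", "ins")) {
    ann <- list(five = variant$pos, three = variant$pos, edge = w$edge,
                ambiguous = FALSE, in_duplicate = FALSE, class = cls,
                pattern = w$pattern, pattern_3p = w$pattern_3p, n = NA_integer_)
    return(ann)
  }
  n <- nchar(w$pattern)
  if (cls == "del") {
    five <- variant$pos + 1L
    three <- w$edge - n + 1L
  } else {
    five <- variant$pos
    three <- w$edge
  }
  ann <- list(five = five, three = three, edge = w$edge,
              ambiguous = five != three, in_duplicate = NA, class = cls,
              pattern = w$pattern, pattern_3p = w$pattern_3p, n = n)
  ann$in_duplicate <- in_duplicate(variant, reference, ann)
  ann
}

#' In-duplicate status of an indel
#'
#' TRUE when a deletion removes one copy of a locally duplicated (or higher
#' order) sequence, or an insertion creates or extends a duplication: the
#' ambiguity shift range (3'-aligned minus 5'-aligned position for deletions;
#' edge minus 5'-aligned position for insertions) covers at least one full
#' copy of the indel pattern.
#'
#' @inheritParams three_prime_edge
#' @param ann Annotation from [aligned_positions()].
#' @return Logical; FALSE for SNV/MNV/complex variants.
#' @export
in_duplicate <- function(variant, reference, ann) {
  if (!ann$class %in% c("del", "ins")) return(FALSE)
  shift <- if (ann$class == "del") ann$three - ann$five else ann$edge - ann$five
  shift >= ann$n
}

#' Flanking bases and ambiguity segments of a variant
#'
#' The left flank is `n_flank` reference bases 5' of the 5'-aligned position;
#' the right flank is `n_flank` bases 3' of the 3'-edge. The middle segments
#' give the full equivalent region under REF and under ALT. Flanks are
#' truncated at contig boundaries.
#'
#' @inheritParams in_duplicate
#' @param n_flank Number of flanking bases on each side.
#' @return List with `left`, `right`, `ref_segment`, `alt_segment`.
#' @export
flanking_bases <- function(variant, reference, ann, n_flank) {
  stopifnot(n_flank >= 1)
  contig <- variant$contig
  left <- ref_sub(reference, contig, ann$five - n_flank, ann$five - 1L)
  right <- ref_sub(reference, contig, ann$edge + 1L, ann$edge + n_flank)
  ref_segment <- ref_sub(reference, contig, ann$five, ann$edge)
  alt_segment <- switch(ann$class,
    del = substring(ref_segment, ann$n + 1L),
    ins = paste0(substr(ref_segment, 1L, 1L), ann$pattern,
                 substring(ref_segment, 2L)),
    # SNV/MNV/complex: the whole segment is the REF allele.
    variant$alt
  )
  list(left = left, right = right,
       ref_segment = ref_segment, alt_segment = alt_segment)
}

#' HGVS DNA-level description of a variant
#'
#' Builds a genomic (`g.`) description following the HGVS 3' rule: indels in
#' repeated context are described at their 3'-most equivalent placement, and
#' an insertion whose inserted sequence duplicates the immediately 5'
#' reference run is reported as `dup`.
#'
#' @inheritParams in_duplicate
#' @return Character scalar `"<contig>:g.<description>"`.
#' @export
hgvs_dna <- function(variant, reference, ann) {
  contig <- variant$contig
  pos <- variant$pos
  ref <- variant$ref
  alt <- variant$alt
  desc <- switch(ann$class,
    snv = paste0(pos, ref, ">", alt),
    mnv = paste0(pos, "_", pos + nchar(ref) - 1L, "delins", alt),
    del = {
      if (ann$n == 1L) paste0(ann$edge, "del")
      else paste0(ann$three, "_", ann$edge, "del")
    },
    ins = {
      n <- ann$n
      run_start <- ann$edge - n + 1L
      run <- if (run_start >= 1L) ref_sub(reference, contig, run_start, ann$edge) else ""
      if (identical(run, ann$pattern_3p)) {
        if (n == 1L) paste0(ann$edge, "dup")
        else paste0(run_start, "_", ann$edge, "dup")
      } else {
        paste0(ann$edge, "_", ann$edge + 1L, "ins", ann$pattern_3p)
      }
    },
    complex = {
      if (nchar(ref) == 1L) paste0(pos, "delins", alt)
      else paste0(pos, "_", pos + nchar(ref) - 1L, "delins", alt)
    }
  )
  paste0(contig, ":g.", desc)
}

#' 3'-direction distance to the next variant
#'
#' Number of reference bases strictly between the current variant's 3'-edge
#' and the next variant's 5'-aligned position. Overlapping spans yield 0 with
#' a message.
#'
#' @param current Annotation of the current variant ([aligned_positions()]).
#' @param nxt Annotation of the next variant on the same contig.
#' @return Non-negative integer.
#' @export
distance_to_next <- function(current, nxt) {
  d <- nxt$five - current$edge - 1L
  if (d < 0L) {
    message("overlapping variant spans; distance reported as 0")
    d <- 0L
  }
  as.integer(d)
}

#' Wildtype and mutated sequence of a genomic region
#'
#' Applies all variants inside the region to the wildtype substring,
#' right-to-left, and returns the wildtype, mutated and reverse-complemented
#' mutated sequences.
#'
#' @param reference Named character vector from [read_reference()].
#' @param contig Contig name.
#' @param start,end 1-based closed region interval.
#' @param variants List of normalized variant records inside the region.
#' @return List with `wildtype`, `mutated`, `revcomp`.
#' @export
mutated_sequence <- function(reference, contig, start, end, variants) {
  seq <- get_contig(reference, contig)
  stopifnot(start >= 1, end <= nchar(seq), start <= end)
  wt <- substr(seq, start, end)
  if (length(variants) == 0) {
    return(list(wildtype = wt, mutated = wt, revcomp = reverse_complement(wt)))
  }
  pos <- vapply(variants, `[[`, integer(1), "pos")
  refs <- vapply(variants, `[[`, character(1), "ref")
  alts <- vapply(variants, `[[`, character(1), "alt")
  ends <- pos + nchar(refs) - 1L
  if (any(pos < start) || any(ends > end)) {
    stop("variant outside region ", contig, ":", start, "-", end)
  }
  o <- order(pos)
  if (any(pos[o][-1] <= ends[o][-length(o)])) {
    bad <- which(pos[o][-1] <= ends[o][-length(o)])[1]
    stop("overlapping variants at ", contig, ":", pos[o][bad], " and ",
         contig, ":", pos[o][bad + 1])
  }
  mut <- wt
  for (i in rev(o)) {
    local_pos <- pos[i] - start + 1L
    mut <- apply_variant(mut, local_pos, refs[i], alts[i])
  }
  list(wildtype = wt, mutated = mut, revcomp = reverse_complement(mut))
}

#' Custom BED annotation of a variant
#'
#' Labels of all BED intervals overlapping the variant's affected span, the
#' closed interval from its 5'-aligned position to its 3'-edge, so that
#' partially overlapping and ambiguity-shifted variants are annotated too.
#'
#' @inheritParams in_duplicate
#' @param intervals A `GRanges` from [read_bed()].
#' @return Character vector of labels (possibly empty).
#' @export
custom_bed_annotation <- function(variant, ann, intervals) {
  if (length(intervals) == 0) return(character(0))
  span <- GenomicRanges::GRanges(
    variant$contig, IRanges::IRanges(ann$five, ann$edge)
  )
  hits <- GenomicRanges::findOverlaps(span, intervals)
  as.character(intervals$label[S4Vectors::subjectHits(hits)])
}
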