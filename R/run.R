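#' Parse a genomic region string
#'
#' @param region String `"contig:start-end"` with `start <= end`.
#' @return List with `contig`, `start`, `end`.
#' @export
parse_region <- function(region) {
  m <- regmatches(region, regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("malformed region string: ", region)
  start <- as.integer(m[3])
  end <- as.integer(m[4])
  if (start > end) stop("region start exceeds end: ", region)
  list(contig = m[2], start = start, end = end)
}

#' Annotate a VCF against a reference: full pipeline
#'
#' Streams variants through normalization, adjacent-sequence annotation and
#' (optionally) tandem-repeat annotation, and writes a tab-separated
#' annotation table plus, when a region is given, a FASTA with the wildtype,
#' mutated and reverse-complemented mutated sequence of that region.
#'
#' @param vcf Path to the input VCF.
#' @param fasta Path to the reference FASTA.
#' @param out_prefix Output prefix; writes `<prefix>.tsv` and, with `region`,
#'   `<prefix>_sequences.fa`.
#' @param ambiguity Add 5'-aligned, 3'-aligned, 3'-edge positions and the
#'   ambiguous/in-duplicate flags.
#' @param flank Integer; when given, add `flank` bases of left/right flank
#'   and the REF/ALT ambiguity segments.
#' @param hgvs Add HGVS DNA-level descriptions.
#' @param distance Add the 3' distance to the next variant (requires
#'   position-sorted input per contig).
#' @param region Optional `"contig:start-end"` string for sequence
#'   extraction.
#' @param bed Optional path to a BED file of custom annotation intervals.
#' @param tandem_repeat Run the tandem-repeat annotation module.
#' @param params A [tr_params()] object for the repeat engine.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the annotation data.frame (`table`), the
#'   output paths, and counts of processed and skipped records.
#' @export
run_annotation <- function(vcf, fasta, out_prefix,
                           ambiguity = FALSE, flank = NULL, hgvs = FALSE,
                           distance = FALSE, region = NULL, bed = NULL,
                           tandem_repeat = FALSE, params = tr_params(),
                           quiet = FALSE) {
  if (!any(ambiguity, !is.null(flank), hgvs, distance, !is.null(region),
           !is.null(bed), tandem_repeat)) {
    stop("no annotation enabled")
  }
  reference <- read_reference(fasta)
  variants <- read_vcf(vcf, reference)
  n_in <- length(variants)

  normed <- lapply(variants, normalize_variant, reference = reference)
  anns <- lapply(normed, aligned_positions, reference = reference)

  if (distance && length(normed) > 1) {
    pos <- vapply(normed, `[[`, integer(1), "pos")
    ctg <- vapply(normed, `[[`, character(1), "contig")
    for (cc in unique(ctg)) {
      p <- pos[ctg == cc]
      if (is.unsorted(p)) {
        stop("input VCF is not position-sorted on contig ", cc,
             "; the distance annotation requires sorted input")
      }
    }
  }

  intervals <- if (!is.null(bed)) read_bed(bed) else NULL

  rows <- vector("list", length(normed))
  for (i in seq_along(normed)) {
    v <- normed[[i]]
    ann <- anns[[i]]
    row <- variant_as_row(v)
    if (ambiguity) {
      row$five_prime_aligned <- ann$five
      row$three_prime_aligned <- ann$three
      row$three_prime_edge <- ann$edge
      row$ambiguous <- ann$ambiguous
      row$in_duplicate <- ann$in_duplicate
    }
    if (!is.null(flank)) {
      fl <- flanking_bases(v, reference, ann, flank)
      row$left_flank <- fl$left
      row$right_flank <- fl$right
      row$ref_ambiguity_seq <- fl$ref_segment
      row$alt_ambiguity_seq <- fl$alt_segment
    }
    if (hgvs) row$hgvs <- hgvs_dna(v, reference, ann)
    if (distance) {
      nxt <- NA_integer_
      if (i < length(normed) && normed[[i + 1]]$contig == v$contig) {
        nxt <- distance_to_next(ann, anns[[i + 1]])
      }
      row$distance_3p <- nxt
    }
    if (!is.null(intervals)) {
      labs <- custom_bed_annotation(v, ann, intervals)
      row$bed_labels <- if (length(labs)) paste(labs, collapse = ",") else NA
    }
    if (tandem_repeat) {
      tr <- annotate_variant_tr(v, ann, reference, params)
      if (nrow(tr) == 0) {
        tr <- data.frame(motif = NA, start = NA, end = NA, copy_number = NA,
                         match_pct = NA, mismatch_pct = NA, gap_pct = NA,
                         alignment_score = NA, repeat_score = NA,
                         gc_pct = NA, copy_change = NA)
      }
      names(tr) <- paste0("tr_", names(tr))
      row <- cbind(row[rep(1, nrow(tr)), , drop = FALSE], tr)
    }
    rows[[i]] <- row
  }

  tab <- if (length(rows)) do.call(rbind, rows) else empty_annotation_frame(
    ambiguity, flank, hgvs, distance, !is.null(intervals), tandem_repeat)
  rownames(tab) <- NULL
  tsv_path <- paste0(out_prefix, ".tsv")
  write_annotation_table(tab, tsv_path)

  fasta_path <- NULL
  if (!is.null(region)) {
    rg <- parse_region(region)
    inside <- Filter(function(v) {
      v$contig == rg$contig && v$pos >= rg$start &&
        v$pos + nchar(v$ref) - 1L <= rg$end
    }, normed)
    ms <- mutated_sequence(reference, rg$contig, rg$start, rg$end, inside)
    stem <- paste0(rg$contig, "_", rg$start, "_", rg$end)
    fasta_path <- paste0(out_prefix, "_sequences.fa")
    write_sequences(stats::setNames(
      c(ms$wildtype, ms$mutated, ms$revcomp),
      paste0(stem, c("_wildtype", "_mutated", "_mutated_revcomp"))
    ), fasta_path)
  }

  if (!quiet) {
    message(n_in, " variant record(s) annotated; output: ", tsv_path,
            if (!is.null(fasta_path)) paste0(", ", fasta_path) else "")
  }
  invisible(list(table = tab, tsv = tsv_path, fasta = fasta_path,
                 n_records = n_in))
}

empty_annotation_frame <- function(ambiguity, flank, hgvs, distance, bed,
                                   tandem_repeat) {
  cols <- c("contig", "pos", "ref", "alt", "id", "genotype")
  if (ambiguity) cols <- c(cols, "five_prime_aligned", "three_prime_aligned",
                           "three_prime_edge", "ambiguous", "in_duplicate")
  if (!is.null(flank)) cols <- c(cols, "left_flank", "right_flank",
                                 "ref_ambiguity_seq", "alt_ambiguity_seq")
  if (hgvs) cols <- c(cols, "hgvs")
  if (distance) cols <- c(cols, "distance_3p")
  if (bed) cols <- c(cols, "bed_labels")
  if (tandem_repeat) {
    cols <- c(cols, paste0("tr_", c("motif", "start", "end", "copy_number",
                                    "match_pct", "mismatch_pct", "gap_pct",
                                    "alignment_score", "repeat_score",
                                    "gc_pct", "copy_change")))
  }
  df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                      cols), stringsAsFactors = FALSE)
  df
}
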