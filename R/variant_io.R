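#' Read a VCF file into a stream of biallelic variant records
#'
#' Reads CHROM, POS, ID, REF, ALT and the first sample's GT, splits
#' multiallelic records into biallelic ones (see [split_multiallelic()]),
#' verifies every REF against the reference sequence, and skips records with
#' symbolic alleles or characters outside A,C,G,T,N with a warning.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param reference Named character vector from [read_reference()].
#' @return List of variant records in file order.
#' @export
read_vcf <- function(path, reference) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) return(list())

  gts <- rep(NA_character_, nrow(fix))
  if (!is.null(vcf@gt) && ncol(vcf@gt) >= 2) {
    fmt <- vcf@gt[, 1]
    smp <- vcf@gt[, 2]
    for (i in seq_along(fmt)) {
      if (is.na(fmt[i]) || is.na(smp[i])) next
      k <- match("GT", strsplit(fmt[i], ":", fixed = TRUE)[[1]])
      if (is.na(k)) next
      gts[i] <- strsplit(smp[i], ":", fixed = TRUE)[[1]][k]
    }
  }

  out <- list()
  for (i in seq_len(nrow(fix))) {
    contig <- unname(fix[i, "CHROM"])
    pos <- as.integer(fix[i, "POS"])
    id <- unname(fix[i, "ID"])
    if (is.na(id)) id <- "."
    ref <- unname(toupper(fix[i, "REF"]))
    alt_field <- unname(fix[i, "ALT"])
    if (!contig %in% names(reference)) {
      stop("record ", i, ": contig '", contig, "' absent from reference FASTA")
    }
    if (is.na(alt_field) || alt_field == ".") {
      warning("record ", i, ": no ALT allele, skipped")
      next
    }
    if (!grepl("^[ACGTN]+$", ref)) {
      warning("record ", i, ": REF '", ref, "' outside A,C,G,T,N, skipped")
      next
    }
    ref_on_genome <- ref_sub(reference, contig, pos, pos + nchar(ref) - 1L)
    if (!identical(ref_on_genome, ref)) {
      stop("record ", i, ": REF '", ref, "' does not match reference '",
           ref_on_genome, "' at ", contig, ":", pos,
           " (wrong reference build?)")
    }
    alts <- toupper(strsplit(alt_field, ",", fixed = TRUE)[[1]])
    keep <- logical(length(alts))
    for (j in seq_along(alts)) {
      a <- alts[j]
      if (grepl("[][<>*]", a)) {
        warning("record ", i, ": symbolic ALT '", a, "' skipped")
      } else if (!grepl("^[ACGTN]+$", a)) {
        warning("record ", i, ": ALT '", a, "' outside A,C,G,T,N, skipped")
      } else if (a == ref) {
        warning("record ", i, ": ALT equals REF, skipped")
      } else {
        keep[j] <- TRUE
      }
    }
    if (!any(keep)) next
    recs <- split_multiallelic(
      list(contig = contig, pos = pos, id = id, ref = ref,
           alt = alts, gt = gts[i]),
      keep = keep
    )
    out <- c(out, recs)
  }
  out
}

#' Split a multiallelic record into biallelic variant records
#'
#' One output record per ALT allele; CHROM/POS/REF/ID are preserved. The
#' genotype is remapped so the retained ALT becomes allele 1 while all other
#' ALT indices become missing (`.`); phased separators are preserved.
#'
#' @param record List with `contig`, `pos`, `id`, `ref`, `alt` (character
#'   vector of ALT alleles) and optional `gt`.
#' @param keep Logical vector marking which ALT alleles to retain
#'   (default all).
#' @return List of biallelic variant records.
#' @export
split_multiallelic <- function(record, keep = NULL) {
  alts <- record$alt
  if (length(alts) == 0) return(list())
  if (is.null(keep)) keep <- rep(TRUE, length(alts))
  gt <- if (is.null(record$gt)) NA_character_ else record$gt
  lapply(which(keep), function(j) {
    variant_record(record$contig, record$pos, record$ref, alts[j],
                   id = record$id,
                   gt = remap_genotype(gt, j))
  })
}

# Remap allele indices of a GT string after multiallelic splitting: the kept
# ALT (1-based index among ALTs) becomes "1", other ALT indices become ".",
# REF stays "0"; "/" and "|" separators are preserved.
remap_genotype <- function(gt, alt_index) {
  if (is.na(gt) || gt == "" || gt == ".") return(gt)
  alleles <- strsplit(gt, "[/|]")[[1]]
  seps <- regmatches(gt, gregexpr("[/|]", gt))[[1]]
  mapped <- vapply(alleles, function(a) {
    if (a == "." || a == "0") a
    else if (a == as.character(alt_index)) "1"
    else "."
  }, character(1), USE.NAMES = FALSE)
  out <- mapped[1]
  for (i in seq_along(seps)) out <- paste0(out, seps[i], mapped[i + 1])
  out
}

#' Read a BED file of custom annotation intervals
#'
#' @param path Path to a BED file (3+ columns, 0-based half-open intervals).
#' @return A `GRanges`; the `label` metadata column holds the BED name column
#'   when present, otherwise `contig:start-end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  label <- if ("name" %in% names(GenomicRanges::mcols(gr))) {
    as.character(gr$name)
  } else {
    rep(NA_character_, length(gr))
  }
  miss <- is.na(label) | label == ""
  label[miss] <- paste0(GenomicRanges::seqnames(gr)[miss], ":",
                        GenomicRanges::start(gr)[miss] - 1L, "-",
                        GenomicRanges::end(gr)[miss])
  GenomicRanges::mcols(gr)$label <- label
  gr
}

#' Write an annotation table as tab-separated text
#'
#' Writes a header line and one row per variant (or per variant/repeat-region
#' combination). `NA` cells are printed as `"."`; logical cells as
#' `TRUE`/`FALSE`.
#'
#' @param rows A data.frame of annotation rows.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(rows, path) {
  out <- rows
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.logical(v)) v <- as.character(v)
    v <- as.character(v)
    v[is.na(v)] <- "."
    out[[j]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write named sequences to a FASTA file
#'
#' @param sequences Named character vector of DNA sequences (A,C,G,T,N).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sequences <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
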