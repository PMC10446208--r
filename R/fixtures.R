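#' Generate a synthetic reference with embedded tandem repeats
#'
#' Builds a random background sequence at a chosen GC fraction and embeds
#' perfect repeat tracts at fixed positions. The base immediately before each
#' tract is forced to differ from the motif's last base and the base
#' immediately after from the motif's first base, so embedded tracts cannot
#' extend gaplessly by chance and truth copy numbers are unambiguous.
#'
#' @param length Contig length in bases.
#' @param repeats List of `list(motif=, copies=, start=)` entries; tracts
#'   must not overlap.
#' @param name Contig name.
#' @param gc Background GC fraction (default 0.5).
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param file Optional path; when given the reference is also written as
#'   FASTA.
#' @return List with `sequences` (named character vector usable as a
#'   reference) and `truth` (data.frame of contig, start, end, motif, copies).
#' @export
make_reference <- function(length, repeats = list(), name = "chr_sim",
                           gc = 0.5, seed = 1L, file = NULL) {
  stopifnot(length >= 1, gc > 0, gc < 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)

  truth <- data.frame(contig = character(), start = integer(),
                      end = integer(), motif = character(),
                      copies = integer(), stringsAsFactors = FALSE)
  spans <- matrix(integer(), ncol = 2)
  for (r in repeats) {
    motif <- toupper(r$motif)
    w <- nchar(motif)
    tract <- strrep(motif, r$copies)
    start <- as.integer(r$start)
    end <- start + nchar(tract) - 1L
    if (start < 2L || end > length - 1L) {
      stop("repeat tract ", motif, "x", r$copies, " at ", start,
           " leaves no room for guard bases")
    }
    if (nrow(spans) > 0 &&
        any(start <= spans[, 2] + 1L & end >= spans[, 1] - 1L)) {
      stop("embedded repeats overlap")
    }
    spans <- rbind(spans, c(start, end))
    bases[start:end] <- strsplit(tract, "")[[1]]
    # guard bases break motif continuation on both sides
    mb <- strsplit(motif, "")[[1]]
    bases[start - 1L] <- sample(setdiff(c("A", "C", "G", "T"), mb[w]), 1)
    bases[end + 1L] <- sample(setdiff(c("A", "C", "G", "T"), mb[1]), 1)
    truth <- rbind(truth, data.frame(
      contig = name, start = start, end = end, motif = motif,
      copies = as.integer(r$copies), stringsAsFactors = FALSE))
  }
  seqs <- stats::setNames(paste(bases, collapse = ""), name)
  if (!is.null(file)) write_sequences(seqs, file)
  list(sequences = seqs, truth = truth)
}

#' Write variant records as a minimal VCF file
#'
#' @param variants List of variant records ([variant_record()]); a record may
#'   carry multiple comma-free ALT alleles as a character vector in `alt` to
#'   emit a multiallelic line.
#' @param reference Named character vector (for contig header lengths).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
make_vcf <- function(variants, reference, path) {
  any_gt <- any(vapply(variants, function(v) !is.na(v$gt %||% NA_character_),
                       logical(1)))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(reference),
                  ",length=", nchar(reference), ">"),
           if (any_gt)
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (any_gt) cols <- c(cols, "FORMAT", "SAMPLE1")
  rows <- vapply(variants, function(v) {
    alt <- paste(v$alt, collapse = ",")
    base <- paste(v$contig, v$pos, v$id, v$ref, alt, ".", ".", ".",
                  sep = "\t")
    if (any_gt) {
      gt <- if (is.na(v$gt %||% NA_character_)) "./." else v$gt
      base <- paste(base, "GT", gt, sep = "\t")
    }
    base
  }, character(1))
  writeLines(c(hdr, paste(cols, collapse = "\t"), rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-encode an indel at its 3'-most equivalent placement
#'
#' Fixture helper producing a deliberately right-shifted (unnormalized)
#' encoding of a normalized pure indel, useful for exercising the
#' normalizer.
#'
#' @param variant A normalized pure insertion or deletion.
#' @param reference Named character vector from [read_reference()].
#' @return A variant record at the rightmost equivalent placement.
#' @export
shift_3prime <- function(variant, reference) {
  ann <- aligned_positions(variant, reference)
  if (!ann$class %in% c("del", "ins")) return(variant)
  contig <- variant$contig
  if (ann$class == "del") {
    anchor <- ann$three - 1L
    if (anchor < 1L) return(variant)
    variant_record(contig, anchor,
                   ref_sub(reference, contig, anchor, ann$edge),
                   ref_sub(reference, contig, anchor, anchor),
                   id = variant$id, gt = variant$gt)
  } else {
    anchor <- ann$edge
    b <- ref_sub(reference, contig, anchor, anchor)
    variant_record(contig, anchor, b, paste0(b, ann$pattern_3p),
                   id = variant$id, gt = variant$gt)
  }
}

# Longest common prefix / suffix length between two strings, via raw bytes.
common_prefix_len <- function(x, y) {
  a <- charToRaw(x)
  b <- charToRaw(y)
  n <- min(length(a), length(b))
  if (n == 0) return(0L)
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(d) == 0) n else d[1] - 1L
}

common_suffix_len <- function(x, y) {
  a <- rev(charToRaw(x))
  b <- rev(charToRaw(y))
  n <- min(length(a), length(b))
  if (n == 0) return(0L)
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(d) == 0) n else d[1] - 1L
}

#' Brute-force enumeration of equivalent indel placements
#'
#' Exhaustively finds every placement of the same net indel that produces an
#' identical mutated sequence. For a net deletion of `n` bases, returns all
#' 1-based start positions of a deleted run; for a net insertion, all anchor
#' positions `d` such that inserting between `d` and `d+1` reproduces the
#' mutated sequence (`d = 0` means before the first base). Intended as a
#' test oracle on small references.
#'
#' @param variant A variant record (any representation).
#' @param reference Named character vector from [read_reference()].
#' @return List with `type` (`"del"`, `"ins"` or `"none"` for length-
#'   preserving variants) and `placements` (sorted integer vector).
#' @export
oracle_equivalent_placements <- function(variant, reference) {
  seq <- get_contig(reference, variant$contig)
  L <- nchar(seq)
  mut <- apply_variant(seq, variant$pos, variant$ref, variant$alt)
  d <- nchar(variant$ref) - nchar(variant$alt)
  if (d == 0L) {
    return(list(type = "none", placements = variant$pos))
  }
  cpl <- common_prefix_len(seq, mut)
  csl <- common_suffix_len(seq, mut)
  if (d > 0L) {
    n <- d
    ds <- seq_len(L - n + 1L)
    ok <- (ds - 1L) <= cpl & (L - (ds + n - 1L)) <= csl
    list(type = "del", placements = ds[ok])
  } else {
    n <- -d
    d0 <- 0:L
    ok <- d0 <= cpl & (L - d0) <= csl
    list(type = "ins", placements = d0[ok])
  }
}

#' Brute-force normalization oracle
#'
#' Enumerates all representations (position, REF, ALT with non-empty
#' alleles) that produce the same mutated sequence and returns the one with
#' the smallest total allele length, ties broken by the smallest position:
#' the parsimonious, left-aligned representation. Independent of the
#' trim-and-extend normalizer; intended for testing on small references.
#'
#' @param variant A variant record.
#' @param reference Named character vector from [read_reference()].
#' @return A variant record in minimal leftmost form.
#' @export
oracle_normalize <- function(variant, reference) {
  seq <- get_contig(reference, variant$contig)
  L <- nchar(seq)
  mut <- apply_variant(seq, variant$pos, variant$ref, variant$alt)
  Lm <- nchar(mut)
  d <- nchar(variant$ref) - nchar(variant$alt)
  cpl <- common_prefix_len(seq, mut)
  csl <- common_suffix_len(seq, mut)
  lr_max <- max(nchar(variant$ref), nchar(variant$alt)) + 2L
  for (lr in max(1L, d + 1L):lr_max) {
    la <- lr - d
    if (la < 1L) next
    ps <- seq_len(L - lr + 1L)
    ps <- ps[ps + la - 1L <= Lm]
    ok <- (ps - 1L) <= cpl & (L - (ps + lr - 1L)) <= csl
    ps <- ps[ok]
    for (p in ps) {
      ref <- substr(seq, p, p + lr - 1L)
      alt <- substr(mut, p, p + la - 1L)
      if (ref != alt) {
        return(variant_record(variant$contig, p, ref, alt,
                              id = variant$id, gt = variant$gt))
      }
    }
  }
  variant
}
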