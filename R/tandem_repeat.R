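#' Tunable parameters of the tandem-repeat engine
#'
#' @param min_unit,max_unit Motif size range in bp (default 1-6, the common
#'   STR motif range).
#' @param max_gap Maximum tolerated gap between consecutive repeat units in
#'   bp, or `NULL` for the default bound of one motif length per step.
#' @param similarity_threshold Minimum fraction of positionwise matching
#'   bases for a candidate unit to be accepted (1.0 = perfect units only).
#' @param match_score,mismatch_score,gap_score Per-base scores entering the
#'   alignment score; defaults follow the magnitudes customary in tandem
#'   repeat alignment scoring.
#' @param min_copy Minimum copy number: a scalar, or a vector indexed by
#'   motif size (entries beyond its length reuse the last value).
#' @param min_alignment_score Quality floor on the alignment score,
#'   controlling the minimum size of a reported repeat region.
#' @param min_match_pct Quality floor on the match percentage, controlling
#'   repeat purity.
#' @return List of parameters with class `tr_params`.
#' @export
tr_params <- function(min_unit = 1L, max_unit = 6L, max_gap = NULL,
                      similarity_threshold = 1.0,
                      match_score = 2, mismatch_score = -5, gap_score = -7,
                      min_copy = 3L, min_alignment_score = 20,
                      min_match_pct = 100) {
  stopifnot(min_unit >= 1, min_unit <= max_unit,
            similarity_threshold > 0, similarity_threshold <= 1,
            all(min_copy >= 2))
  structure(list(min_unit = as.integer(min_unit),
                 max_unit = as.integer(max_unit),
                 max_gap = if (is.null(max_gap)) NULL else as.integer(max_gap),
                 similarity_threshold = similarity_threshold,
                 match_score = match_score, mismatch_score = mismatch_score,
                 gap_score = gap_score, min_copy = min_copy,
                 min_alignment_score = min_alignment_score,
                 min_match_pct = min_match_pct),
            class = "tr_params")
}

#' Preset parameter profiles for STR annotation
#'
#' `"perfect"` restricts reporting to perfect STRs: similarity threshold and
#' match percentage 100%, minimum region length 10 bp (encoded as minimum
#' alignment score = 10 x match score), and minimum copy numbers of 10 for
#' mononucleotide, 5 for dinucleotide and 4 for tri- to hexanucleotide
#' motifs. `"imperfect90"` relaxes unit similarity and region purity to 90%
#' with the same length and copy floors.
#'
#' @param name `"perfect"` or `"imperfect90"`.
#' @param ... Overrides passed on to [tr_params()].
#' @return A `tr_params` object.
#' @export
tr_profile <- function(name = c("perfect", "imperfect90"), ...) {
  name <- match.arg(name)
  copy_map <- c(10L, 5L, 4L, 4L, 4L, 4L)
  base <- list(min_copy = copy_map, min_alignment_score = 2 * 10,
               min_match_pct = 100, similarity_threshold = 1.0)
  if (name == "imperfect90") {
    base$similarity_threshold <- 0.9
    base$min_match_pct <- 90
  }
  args <- utils::modifyList(base, list(...))
  do.call(tr_params, args)
}

# Minimum copy number for a given motif size.
min_copy_for <- function(params, w) {
  mc <- params$min_copy
  if (length(mc) == 1L) return(mc)
  mc[min(w, length(mc))]
}

# Effective gap bound for a motif size.
max_gap_for <- function(params, w) {
  if (is.null(params$max_gap)) w else params$max_gap
}

#' Variant site used to seed the repeat search
#'
#' The variant site is the pair of reference coordinates immediately 5' of
#' the 5'-aligned position and immediately 3' of the 3'-edge, so that the
#' search window covers the whole ambiguity span plus the directly adjacent
#' bases. Variants containing N in an allele are skipped.
#'
#' @param variant A normalized variant record.
#' @param ann Annotation from [aligned_positions()].
#' @return List with `contig`, `left`, `right`, or `NULL` when the variant
#'   carries an N allele.
#' @export
variant_site <- function(variant, ann) {
  if (has_n_allele(variant)) {
    message("variant at ", variant$contig, ":", variant$pos,
            " contains N; skipped by tandem-repeat annotation")
    return(NULL)
  }
  list(contig = variant$contig, left = ann$five - 1L, right = ann$edge + 1L)
}

#' Candidate conserved repeat motifs for a variant site
#'
#' For each window size in `[min_unit, max_unit]`, every reference window of
#' that size whose span intersects the closed site interval, emitted 5' to
#' 3'. Windows truncated by contig ends are omitted.
#'
#' @param site From [variant_site()].
#' @param reference Named character vector from [read_reference()].
#' @param params A [tr_params()] object.
#' @return data.frame with columns `w`, `start`, `end`, `motif`.
#' @export
candidate_motifs <- function(site, reference, params) {
  seq <- get_contig(reference, site$contig)
  L <- nchar(seq)
  out <- list()
  for (w in params$min_unit:params$max_unit) {
    from <- max(1L, site$left - w + 1L)
    to <- min(site$right, L - w + 1L)
    if (from > to) next
    starts <- seq.int(from, to)
    out[[length(out) + 1L]] <- data.frame(
      w = w, start = starts, end = starts + w - 1L,
      motif = substring(seq, starts, starts + w - 1L),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(w = integer(), start = integer(), end = integer(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Positionwise similarity score between two equal-length strings; positions
# holding N never match.
unit_score <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av == bv & av != "N")
}

# Per-position majority-vote consensus over equal-length unit sequences;
# ties are resolved toward the anchor motif's base.
consensus_motif <- function(seqs, anchor) {
  w <- nchar(anchor)
  m <- do.call(rbind, strsplit(c(anchor, seqs), ""))
  a <- strsplit(anchor, "")[[1]]
  out <- character(w)
  for (j in seq_len(w)) {
    tab <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    top <- names(tab)[tab == max(tab)]
    out[j] <- if (a[j] %in% top) a[j] else top[1]
  }
  paste(out, collapse = "")
}

#' Iterated repeat-unit search in one direction
#'
#' Starting from an anchor motif, repeatedly builds the candidate set of
#' same-size windows at gap 0..max_gap in the given direction, scores each by
#' positionwise base identity against the current motif, accepts the best
#' candidate (ties broken toward the smallest gap) when it reaches the
#' similarity threshold, and continues from the accepted unit. Once five
#' units have been collected in total the comparison motif switches to the
#' running consensus of all collected units and keeps updating each round.
#'
#' @param motif Anchor motif sequence.
#' @param start,end Anchor span on the reference.
#' @param direction `"5p"` or `"3p"`.
#' @param reference Named character vector from [read_reference()].
#' @param contig Contig name.
#' @param params A [tr_params()] object.
#' @param prior_units Character vector of unit sequences already collected in
#'   the other direction (feeds the consensus round count).
#' @return data.frame of accepted units with columns `start`, `end`, `seq`,
#'   `gap` (distance to the previously accepted unit).
#' @export
search_units <- function(motif, start, end, direction = c("5p", "3p"),
                         reference, contig, params, prior_units = character()) {
  direction <- match.arg(direction)
  seq <- get_contig(reference, contig)
  L <- nchar(seq)
  w <- nchar(motif)
  gmax <- max_gap_for(params, w)
  need <- params$similarity_threshold * w - 1e-9
  r_cur <- motif
  collected <- prior_units
  units <- list()
  cur_start <- start
  cur_end <- end
  repeat {
    best_score <- -1L
    best <- NULL
    for (g in 0:gmax) {
      if (direction == "5p") {
        s_end <- cur_start - 1L - g
        s_start <- s_end - w + 1L
      } else {
        s_start <- cur_end + 1L + g
        s_end <- s_start + w - 1L
      }
      if (s_start < 1L || s_end > L) next
      s <- substr(seq, s_start, s_end)
      sc <- unit_score(s, r_cur)
      if (sc > best_score) {
        best_score <- sc
        best <- list(seq = s, start = s_start, end = s_end, gap = g)
      }
    }
    if (is.null(best) || best_score < need) break
    units[[length(units) + 1L]] <- data.frame(
      start = best$start, end = best$end, seq = best$seq, gap = best$gap,
      stringsAsFactors = FALSE)
    collected <- c(collected, best$seq)
    cur_start <- best$start
    cur_end <- best$end
    if (length(collected) >= 5L) {
      r_cur <- consensus_motif(collected, motif)
    }
  }
  if (length(units) == 0) {
    return(data.frame(start = integer(), end = integer(), seq = character(),
                      gap = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, units)
}

# Region statistics for an ordered unit table against a fixed motif under
# the alignment model: matches/mismatches within units, gaps between them.
region_stats <- function(units, motif, params, span_seq) {
  w <- nchar(motif)
  scores <- vapply(units$seq, unit_score, integer(1), b = motif,
                   USE.NAMES = FALSE)
  gaps <- c(0L, units$start[-1] - units$end[-nrow(units)] - 1L)
  match_bases <- sum(scores)
  mismatch_bases <- sum(w - scores)
  gap_bases <- sum(gaps)
  start <- min(units$start)
  end <- max(units$end)
  len <- end - start + 1L
  aln <- params$match_score * match_bases +
    params$mismatch_score * mismatch_bases + params$gap_score * gap_bases
  list(w = w, motif = motif, start = start, end = end,
       copy_number = nrow(units),
       match_bases = match_bases, mismatch_bases = mismatch_bases,
       gap_bases = gap_bases, length = len,
       match_pct = 100 * match_bases / len,
       mismatch_pct = 100 * mismatch_bases / len,
       gap_pct = 100 * gap_bases / len,
       alignment_score = aln,
       repeat_score = aln / len * nrow(units),
       units = units, span_seq = span_seq)
}

#' Assemble a candidate tandem-repeat region from anchor and found units
#'
#' Units from both directions are ordered 5' to 3' around the anchor. When at
#' least five units were found the final motif is the consensus of the anchor
#' and all units and every unit's match/mismatch counts are recomputed
#' against it; otherwise the anchor motif is used. Alignment and repeat
#' scores follow
#' \deqn{AlignmentScore = MS \cdot match + MIS \cdot mismatch + GS \cdot gap}
#' \deqn{RepeatScore = AlignmentScore / length \cdot copynumber}
#'
#' @param anchor List with `motif`, `start`, `end`.
#' @param units_5p,units_3p Unit tables from [search_units()].
#' @param reference Named character vector from [read_reference()].
#' @param contig Contig name.
#' @param params A [tr_params()] object.
#' @return A region list with spans, counts, percentages and scores.
#' @export
assemble_region <- function(anchor, units_5p, units_3p, reference, contig,
                            params) {
  anchor_row <- data.frame(start = anchor$start, end = anchor$end,
                           seq = anchor$motif, gap = 0L,
                           stringsAsFactors = FALSE)
  units <- rbind(units_5p, anchor_row, units_3p)
  units <- units[order(units$start), , drop = FALSE]
  rownames(units) <- NULL
  n_found <- nrow(units) - 1L
  motif <- if (n_found >= 5L) {
    # consensus over anchor + found units; the anchor row is dropped here
    # because consensus_motif() re-adds the anchor motif itself
    anchor_at <- which(units$start == anchor$start & units$end == anchor$end)[1]
    consensus_motif(units$seq[-anchor_at], anchor$motif)
  } else {
    anchor$motif
  }
  span_seq <- ref_sub(reference, contig, min(units$start), max(units$end))
  region <- region_stats(units, motif, params, span_seq)
  region$anchor_motif <- anchor$motif
  region
}

# TRUE when a region meets every quality floor.
region_passes <- function(region, params) {
  region$copy_number >= min_copy_for(params, region$w) &&
    region$match_pct >= params$min_match_pct - 1e-9 &&
    region$alignment_score >= params$min_alignment_score - 1e-9
}

#' Post-processing quality control with tail trimming
#'
#' Keeps regions meeting the copy-number, match-percentage and
#' alignment-score floors. When no candidate passes but at least one exists,
#' the candidate with the best alignment score is trimmed: outermost units
#' are removed one at a time from whichever end yields the better remaining
#' alignment score, recomputing all statistics, until the thresholds are met
#' or the copy number falls below its floor (in which case the candidate is
#' abandoned).
#'
#' @param candidates List of regions from [assemble_region()].
#' @param params A [tr_params()] object.
#' @return List of surviving regions (possibly empty).
#' @export
qc_and_trim <- function(candidates, params) {
  if (length(candidates) == 0) return(list())
  passed <- Filter(function(r) region_passes(r, params), candidates)
  if (length(passed) > 0) return(passed)

  aln <- vapply(candidates, `[[`, numeric(1), "alignment_score")
  rsc <- vapply(candidates, `[[`, numeric(1), "repeat_score")
  best <- candidates[[order(-aln, -rsc)[1]]]
  repeat {
    if (best$copy_number - 1L < min_copy_for(params, best$w)) return(list())
    if (nrow(best$units) < 2L) return(list())
    u <- best$units
    opt5 <- region_stats(u[-1, , drop = FALSE], best$motif, params, NA)
    opt3 <- region_stats(u[-nrow(u), , drop = FALSE], best$motif, params, NA)
    pick <- if (opt3$alignment_score > opt5$alignment_score ||
                (opt3$alignment_score == opt5$alignment_score &&
                 opt3$match_pct >= opt5$match_pct)) opt3 else opt5
    pick$anchor_motif <- best$anchor_motif
    best <- pick
    if (region_passes(best, params)) {
      best$span_seq <- NA_character_  # refreshed by the caller
      return(list(best))
    }
  }
}

# Refresh the reference span sequence of a region (after trimming).
refresh_span_seq <- function(region, reference, contig) {
  region$span_seq <- ref_sub(reference, contig, region$start, region$end)
  region
}

#' Remove redundant tandem-repeat regions of one variant site
#'
#' Regions are ranked by repeat score (ties: higher copy number). Pairwise
#' from the top, the redundancy ratio is the overlap span divided by the
#' union span of the two regions on the reference; when it exceeds 0.5
#' (strictly) the pair member whose motif base-frequency vector is closest
#' (L1) to its whole-region base-frequency vector is kept and the other is
#' dropped; on a tie the earlier-ranked region survives.
#'
#' @param regions List of regions from [assemble_region()]/[qc_and_trim()].
#' @return List of surviving regions, ranked.
#' @export
remove_redundancy <- function(regions) {
  if (length(regions) <= 1) return(regions)
  key <- vapply(regions, function(r) paste(r$motif, r$start, r$end),
                character(1))
  regions <- regions[!duplicated(key)]
  rsc <- vapply(regions, `[[`, numeric(1), "repeat_score")
  cpy <- vapply(regions, `[[`, numeric(1), "copy_number")
  regions <- regions[order(-rsc, -cpy)]
  alive <- rep(TRUE, length(regions))
  for (i in seq_along(regions)) {
    if (!alive[i]) next
    for (j in seq_along(regions)) {
      if (j <= i || !alive[j]) next
      a <- regions[[i]]
      b <- regions[[j]]
      ov <- min(a$end, b$end) - max(a$start, b$start) + 1L
      un <- max(a$end, b$end) - min(a$start, b$start) + 1L
      if (ov <= 0 || un <= 0) next
      if (ov / un > 0.5) {
        da <- freq_difference(a)
        db <- freq_difference(b)
        if (db < da) alive[i] <- FALSE else alive[j] <- FALSE
        if (!alive[i]) break
      }
    }
  }
  regions[alive]
}

# L1 distance between the base-frequency vectors of a region's motif and of
# its whole reference span.
freq_difference <- function(region) {
  fm <- base_freq(region$motif)
  fr <- base_freq(region$span_seq)
  sum(abs(fm - fr))
}

base_freq <- function(x) {
  b <- strsplit(x, "")[[1]]
  tab <- table(factor(b, levels = c("A", "C", "G", "T")))
  as.numeric(tab) / length(b)
}

#' Finalize a repeat region: GC% and variant-induced copy change
#'
#' @param region A surviving region.
#' @param variant The annotated variant record.
#' @return The region with `gc_pct` and `copy_change` fields; the copy
#'   change is the signed allele length difference divided by the motif
#'   length for length-changing variants (fractional values allowed) and 0
#'   for SNV/MNV.
#' @export
finalize_region <- function(region, variant) {
  region$gc_pct <- gc_percent(region$span_seq)
  dl <- nchar(variant$alt) - nchar(variant$ref)
  region$copy_change <- if (dl != 0L) dl / region$w else 0
  region
}

#' Tandem-repeat annotation of one variant
#'
#' Runs the full discovery pipeline: variant site, candidate motifs, unit
#' search in both directions, region assembly, quality control with
#' trimming, redundancy removal and finalization.
#'
#' @param variant A normalized variant record.
#' @param ann Annotation from [aligned_positions()].
#' @param reference Named character vector from [read_reference()].
#' @param params A [tr_params()] object.
#' @return data.frame with one row per reported region: `motif`, `start`,
#'   `end`, `copy_number`, `match_pct`, `mismatch_pct`, `gap_pct`,
#'   `alignment_score`, `repeat_score`, `gc_pct`, `copy_change`. Zero rows
#'   when no repeat qualifies.
#' @export
annotate_variant_tr <- function(variant, ann, reference, params = tr_params()) {
  empty <- data.frame(motif = character(), start = integer(), end = integer(),
                      copy_number = integer(), match_pct = numeric(),
                      mismatch_pct = numeric(), gap_pct = numeric(),
                      alignment_score = numeric(), repeat_score = numeric(),
                      gc_pct = numeric(), copy_change = numeric(),
                      stringsAsFactors = FALSE)
  site <- variant_site(variant, ann)
  if (is.null(site)) return(empty)
  cm <- candidate_motifs(site, reference, params)
  if (nrow(cm) == 0) return(empty)
  regions <- list()
  seen <- character()
  for (k in seq_len(nrow(cm))) {
    anchor <- list(motif = cm$motif[k], start = cm$start[k], end = cm$end[k])
    if (grepl("N", anchor$motif, fixed = TRUE)) next
    u5 <- search_units(anchor$motif, anchor$start, anchor$end, "5p",
                       reference, site$contig, params)
    u3 <- search_units(anchor$motif, anchor$start, anchor$end, "3p",
                       reference, site$contig, params,
                       prior_units = u5$seq)
    reg <- assemble_region(anchor, u5, u3, reference, site$contig, params)
    key <- paste(reg$motif, reg$start, reg$end)
    if (key %in% seen) next
    seen <- c(seen, key)
    regions[[length(regions) + 1L]] <- reg
  }
  survivors <- qc_and_trim(regions, params)
  survivors <- lapply(survivors, refresh_span_seq, reference = reference,
                      contig = site$contig)
  survivors <- remove_redundancy(survivors)
  survivors <- lapply(survivors, finalize_region, variant = variant)
  if (length(survivors) == 0) return(empty)
  do.call(rbind, lapply(survivors, function(r) {
    data.frame(motif = r$motif, start = r$start, end = r$end,
               copy_number = r$copy_number, match_pct = r$match_pct,
               mismatch_pct = r$mismatch_pct, gap_pct = r$gap_pct,
               alignment_score = r$alignment_score,
               repeat_score = r$repeat_score, gc_pct = r$gc_pct,
               copy_change = r$copy_change, stringsAsFactors = FALSE)
  }))
}
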