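# Shared generators for property-style tests: random references (optionally
# with an embedded repeat tract) and random variants in possibly
# unnormalized encodings. Everything is driven by an explicit seed so runs
# are reproducible.

BASES <- c("A", "C", "G", "T")

random_case <- function(seed) {
  set.seed(seed)
  L <- sample(80:300, 1)
  bases <- sample(BASES, L, replace = TRUE)
  if (stats::runif(1) < 0.6) {
    w <- sample(1:4, 1)
    k <- sample(3:8, 1)
    if (L - w * k - 10 > 6) {
      motif <- paste(sample(BASES, w, replace = TRUE), collapse = "")
      start <- sample(6:(L - w * k - 10), 1)
      bases[start:(start + w * k - 1)] <- strsplit(strrep(motif, k), "")[[1]]
    }
  }
  seq <- paste(bases, collapse = "")
  reference <- stats::setNames(seq, "ctg")

  type <- sample(c("del", "ins", "snv", "mnv", "complex"), 1,
                 prob = c(0.35, 0.35, 0.1, 0.1, 0.1))
  p <- sample(15:(L - 30), 1)
  v <- switch(type,
    del = {
      n <- sample(1:10, 1)
      variant_record("ctg", p, substr(seq, p, p + n), substr(seq, p, p))
    },
    ins = {
      n <- sample(1:10, 1)
      ins <- if (stats::runif(1) < 0.5) {
        substr(seq, p + 1, p + n)  # duplicates downstream bases -> ambiguity
      } else {
        paste(sample(BASES, n, replace = TRUE), collapse = "")
      }
      variant_record("ctg", p, substr(seq, p, p),
                     paste0(substr(seq, p, p), ins))
    },
    snv = {
      b <- substr(seq, p, p)
      variant_record("ctg", p, b, sample(setdiff(BASES, b), 1))
    },
    mnv = {
      n <- sample(2:5, 1)
      refal <- substr(seq, p, p + n - 1)
      altal <- refal
      while (altal == refal) {
        altal <- paste(sample(BASES, n, replace = TRUE), collapse = "")
      }
      variant_record("ctg", p, refal, altal)
    },
    complex = {
      n <- sample(2:6, 1)
      m <- sample(1:6, 1)
      refal <- substr(seq, p, p + n - 1)
      altal <- refal
      while (altal == refal) {
        altal <- paste(sample(BASES, m, replace = TRUE), collapse = "")
      }
      variant_record("ctg", p, refal, altal)
    }
  )

  # Re-encode with shared flanking bases half of the time so the normalizer
  # has real work to do.
  if (stats::runif(1) < 0.5) {
    lp <- sample(0:3, 1)
    rp <- sample(0:3, 1)
    if (v$pos - lp >= 1 && v$pos + nchar(v$ref) + rp - 1 <= L) {
      left <- if (lp > 0) substr(seq, v$pos - lp, v$pos - 1) else ""
      right <- if (rp > 0) {
        substr(seq, v$pos + nchar(v$ref), v$pos + nchar(v$ref) + rp - 1)
      } else ""
      v <- variant_record("ctg", v$pos - lp,
                          paste0(left, v$ref, right),
                          paste0(left, v$alt, right))
    }
  }
  list(reference = reference, variant = v)
}

# A deterministic reference holding a (GC)x7 tract at 123-136 plus a
# downstream SNV target, mirroring the dinucleotide worked scenario.
gc7_fixture <- function(seed = 42) {
  make_reference(300, repeats = list(list(motif = "GC", copies = 7,
                                          start = 123)),
                 name = "chr_example", seed = seed)
}

is_rotation <- function(a, b) {
  nchar(a) == nchar(b) && grepl(a, strrep(b, 2), fixed = TRUE)
}

# Reference holding a single perfect tract between hostile flanks; pick a
# flank alphabet disjoint from the motif's for searches at threshold 1.
tract_reference <- function(motif, copies, flank = "GT", flank_rep = 15,
                            name = "ctg") {
  seq <- paste0(strrep(flank, flank_rep), strrep(motif, copies),
                strrep(flank, flank_rep))
  list(reference = stats::setNames(seq, name),
       start = nchar(flank) * flank_rep + 1L,
       end = nchar(flank) * flank_rep + nchar(motif) * copies)
}

snv_at <- function(reference, contig, pos) {
  b <- substr(reference[[contig]], pos, pos)
  variant_record(contig, pos, b, setdiff(c("A", "C", "G", "T"), b)[1])
}
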