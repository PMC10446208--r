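test_that("aligned positions reproduce the dinucleotide-deletion scenario", {
  fx <- gc7_fixture()
  ref <- fx$sequences
  seq <- ref[[1]]
  # GC deletion anchored at 122 inside the (GC)x7 tract at 123-136
  v <- variant_record("chr_example", 122, substr(seq, 122, 124),
                      substr(seq, 122, 122))
  ann <- aligned_positions(v, ref)
  expect_equal(ann$five, 123)
  expect_equal(ann$three, 135)
  expect_equal(ann$edge, 136)
  expect_true(ann$ambiguous)
  expect_true(ann$in_duplicate)
})

test_that("SNV, MNV and complex substitutions are never ambiguous", {
  ref <- stats::setNames(paste0(strrep("A", 98), "GCATTCAT", strrep("G", 40)),
                         "c1")
  snv <- aligned_positions(variant_record("c1", 50, "A", "G"), ref)
  expect_equal(list(snv$five, snv$three, snv$edge), list(50L, 50L, 50L))
  expect_false(snv$ambiguous)
  # complex indel: REF CATTC, ALT G at 100
  cx <- aligned_positions(variant_record("c1", 100, "CATTC", "G"), ref)
  expect_equal(cx$class, "complex")
  expect_equal(list(cx$five, cx$three, cx$edge), list(100L, 100L, 104L))
  expect_false(cx$ambiguous)
  expect_false(cx$in_duplicate)
})

test_that("insertions creating or extending duplications are flagged", {
  # single AT followed by non-repetitive bases; inserting AT duplicates it
  ref <- stats::setNames(paste0(strrep("C", 20), "GATTCGGA", strrep("C", 20)),
                         "c1")
  # positions: 21=G 22=A 23=T 24=T ...; insert "AT" after the AT at 22-23
  v <- variant_record("c1", 21, "G", "GAT")
  ann <- aligned_positions(v, ref)
  expect_equal(ann$five, 21)
  expect_equal(ann$edge, 23)
  expect_true(ann$ambiguous)
  expect_true(ann$in_duplicate)
  # deletion of a lone base with no equal neighbours: shift 0
  ref2 <- stats::setNames(paste0(strrep("C", 20), "AGTTAG", strrep("C", 20)),
                          "c1")
  ann2 <- aligned_positions(variant_record("c1", 21, "AG", "A"), ref2)
  expect_false(ann2$in_duplicate)
})

test_that("aligned positions match the enumeration oracle on random indels", {
  for (i in 1:400) {
    cs <- random_case(3000 + i)
    nv <- suppressWarnings(normalize_variant(cs$variant, cs$reference))
    if (!nv$normalized) next
    ann <- aligned_positions(nv, cs$reference)
    if (!ann$class %in% c("del", "ins")) {
      expect_false(ann$ambiguous, info = paste("case", i))
      next
    }
    op <- oracle_equivalent_placements(nv, cs$reference)
    if (ann$class == "del") {
      expect_equal(ann$five, min(op$placements), info = paste("case", i))
      expect_equal(ann$edge, max(op$placements) + ann$n - 1L,
                   info = paste("case", i))
      expect_equal(ann$three, max(op$placements), info = paste("case", i))
    } else {
      if (min(op$placements) == 0L) next  # unanchorable at contig start
      expect_equal(ann$five, min(op$placements), info = paste("case", i))
      expect_equal(ann$edge, max(op$placements), info = paste("case", i))
    }
    expect_equal(ann$ambiguous, length(op$placements) > 1,
                 info = paste("case", i))
  }
})

test_that("flanking bases expose the full ambiguity segments", {
  fx <- gc7_fixture()
  ref <- fx$sequences
  seq <- ref[[1]]
  v <- variant_record("chr_example", 122, substr(seq, 122, 124),
                      substr(seq, 122, 122))
  ann <- aligned_positions(v, ref)
  fl <- flanking_bases(v, ref, ann, 2)
  expect_equal(fl$left, substr(seq, 121, 122))
  expect_equal(fl$right, substr(seq, 137, 138))
  expect_equal(fl$ref_segment, strrep("GC", 7))
  expect_equal(fl$alt_segment, strrep("GC", 6))
  # flank truncation at the contig start
  snv1 <- variant_record("chr_example", 1, substr(seq, 1, 1),
                         setdiff(c("A", "C", "G", "T"), substr(seq, 1, 1))[1])
  ann1 <- aligned_positions(snv1, ref)
  fl1 <- flanking_bases(snv1, ref, ann1, 3)
  expect_equal(fl1$left, "")
})

test_that("HGVS descriptions follow the 3' rule", {
  ref <- stats::setNames(paste0(strrep("A", 98), "GCATTCA", strrep("G", 50)),
                         "c1")
  # SNV
  snv <- variant_record("c1", 100, "C", "G")
  expect_equal(hgvs_dna(snv, ref, aligned_positions(snv, ref)), "c1:g.100C>G")
  # single-base deletion in the TT run reports the 3'-most T
  del <- variant_record("c1", 101, "AT", "A")
  expect_equal(hgvs_dna(del, ref, aligned_positions(del, ref)), "c1:g.103del")
  # duplication: inserting GC inside a (GC)x7 tract
  fx <- gc7_fixture()
  seq2 <- fx$sequences[[1]]
  ins <- variant_record("chr_example", 122, substr(seq2, 122, 122),
                        paste0(substr(seq2, 122, 122), "GC"))
  expect_equal(hgvs_dna(ins, fx$sequences, aligned_positions(ins, fx$sequences)),
               "chr_example:g.135_136dup")
  # plain insertion with no 5' duplicate run
  ref3 <- stats::setNames(paste0(strrep("C", 30), "ATTTTG", strrep("C", 30)),
                          "c1")
  ins2 <- variant_record("c1", 31, "A", "AGA")
  expect_equal(hgvs_dna(ins2, ref3, aligned_positions(ins2, ref3)),
               "c1:g.31_32insGA")
  # MNV and complex become delins
  mnv <- variant_record("c1", 100, "CA", "GT")
  expect_equal(hgvs_dna(mnv, ref, aligned_positions(mnv, ref)),
               "c1:g.100_101delinsGT")
  cx <- variant_record("c1", 100, "CATTC", "G")
  expect_equal(hgvs_dna(cx, ref, aligned_positions(cx, ref)),
               "c1:g.100_104delinsG")
})

test_that("HGVS never describes an ambiguous indel left of its 3'-most run", {
  for (i in 1:200) {
    cs <- random_case(4000 + i)
    nv <- suppressWarnings(normalize_variant(cs$variant, cs$reference))
    if (!nv$normalized) next
    ann <- aligned_positions(nv, cs$reference)
    if (!ann$class %in% c("del", "ins")) next
    h <- hgvs_dna(nv, cs$reference, ann)
    pos_in_desc <- as.integer(sub("^.*g\\.([0-9]+).*$", "\\1", h))
    lower_bound <- if (ann$class == "del") ann$three else {
      # dup positions start at the 3'-most run; plain insertions at the edge
      if (grepl("dup", h)) ann$edge - ann$n + 1L else ann$edge
    }
    expect_gte(pos_in_desc, lower_bound)
  }
})

test_that("inter-variant distances count strictly intervening bases", {
  fx <- gc7_fixture()
  ref <- fx$sequences
  seq <- ref[[1]]
  del <- variant_record("chr_example", 122, substr(seq, 122, 124),
                        substr(seq, 122, 122))
  ann_del <- aligned_positions(del, ref)
  snv <- variant_record("chr_example", 141, substr(seq, 141, 141),
                        setdiff(c("A", "C", "G", "T"),
                                substr(seq, 141, 141))[1])
  ann_snv <- aligned_positions(snv, ref)
  expect_equal(distance_to_next(ann_del, ann_snv), 4L)
  # adjacent SNVs -> 0
  a <- aligned_positions(variant_record("chr_example", 50,
                                        substr(seq, 50, 50), "N"), ref)
  b <- aligned_positions(variant_record("chr_example", 51,
                                        substr(seq, 51, 51), "N"), ref)
  expect_equal(distance_to_next(a, b), 0L)
  # overlap reports 0 with a note
  expect_message(d <- distance_to_next(b, a), "overlap")
  expect_equal(d, 0L)
})

test_that("mutated sequences apply all in-region variants right-to-left", {
  fx <- make_reference(100, seed = 9)
  ref <- fx$sequences
  seq <- ref[[1]]
  snv <- variant_record("chr_sim", 30, substr(seq, 30, 30),
                        setdiff(c("A", "C", "G", "T"), substr(seq, 30, 30))[1])
  del <- variant_record("chr_sim", 40, substr(seq, 40, 42), substr(seq, 40, 40))
  ms <- mutated_sequence(ref, "chr_sim", 21, 60, list(snv, del))
  expect_equal(nchar(ms$wildtype), 40)
  expect_equal(nchar(ms$mutated), 38)
  expect_equal(ms$revcomp, reverse_complement(ms$mutated))
  expect_equal(reverse_complement(ms$revcomp), ms$mutated)
  # no variants -> wildtype
  ms0 <- mutated_sequence(ref, "chr_sim", 21, 60, list())
  expect_equal(ms0$mutated, ms0$wildtype)
  # overlapping variants are fatal
  del2 <- variant_record("chr_sim", 41, substr(seq, 41, 43), substr(seq, 41, 41))
  expect_error(mutated_sequence(ref, "chr_sim", 21, 60, list(del, del2)),
               "overlap")
})

test_that("BED annotation uses the ambiguity span, not POS alone", {
  fx <- gc7_fixture()
  ref <- fx$sequences
  seq <- ref[[1]]
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr_example\t129\t200\tstr_region",
               "chr_example\t39\t60\telsewhere"), bed)
  intervals <- read_bed(bed)
  # deletion anchored at 122: POS is outside [130,200] but the span reaches it
  del <- variant_record("chr_example", 122, substr(seq, 122, 124),
                        substr(seq, 122, 122))
  labs <- custom_bed_annotation(del, aligned_positions(del, ref), intervals)
  expect_equal(labs, "str_region")
  snv <- variant_record("chr_example", 50, substr(seq, 50, 50), "N")
  labs2 <- custom_bed_annotation(snv, aligned_positions(snv, ref), intervals)
  expect_equal(labs2, "elsewhere")
  snv2 <- variant_record("chr_example", 250, substr(seq, 250, 250), "N")
  expect_length(custom_bed_annotation(snv2, aligned_positions(snv2, ref),
                                      intervals), 0)
})
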