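rc <- function(x) revcomp(x)

make_pair <- function(fragment, r1_span, r2_span, q1 = NULL, q2 = NULL,
                      id = "p1") {
  r1 <- substr(fragment, r1_span[1], r1_span[2])
  r2 <- rc(substr(fragment, r2_span[1], r2_span[2]))
  tibble::tibble(
    id = id, r1_seq = r1,
    r1_qual = q1 %||% strrep("I", nchar(r1)),
    r2_seq = r2, r2_qual = q2 %||% strrep("I", nchar(r2)))
}

test_that("error-free overlapping mates reconstruct the fragment", {
  frag <- "ACGTACGTTT"
  m <- merge_read_pairs(make_pair(frag, c(1, 8), c(3, 10)), min_overlap = 4)
  expect_true(m$merged)
  expect_identical(m$seq, frag)
  expect_equal(m$overlap_len, 6L)
  expect_equal(m$n_mismatch, 0L)
})

test_that("overlap disagreements follow the quality-consensus rule", {
  frag <- "ACGTACGTTT"
  pair <- make_pair(frag, c(1, 8), c(3, 10))
  # r2 disagrees at fragment position 5 (overlap position 3 of r2rc):
  # r2rc = GTACGT** -> mutate its 3rd base; in r2 coordinates that is
  # position 6 of the reverse-complemented read
  r2rc <- rc(pair$r2_seq)
  substr(r2rc, 3, 3) <- "G"
  pair$r2_seq <- rc(r2rc)
  # r2 at Q10 everywhere, r1 at Q40 -> r1 wins the disagreement
  pair$r2_qual <- strrep("+", 8)
  m <- merge_read_pairs(pair, min_overlap = 4)
  expect_true(m$merged)
  expect_identical(m$seq, frag)
  expect_equal(m$n_mismatch, 1L)

  # qualities within delta_q of each other -> N at the disputed column
  pair$r2_qual <- strrep("F", 8)  # Q37 vs Q40: difference 3 < 6
  m2 <- merge_read_pairs(pair, min_overlap = 4)
  expect_identical(substr(m2$seq, 5, 5), "N")
})

test_that("pairs without usable overlap are rejected with a reason", {
  p <- tibble::tibble(id = "x", r1_seq = strrep("A", 30),
                      r1_qual = strrep("I", 30),
                      r2_seq = strrep("A", 30),   # r2rc = TTTT...: no identity
                      r2_qual = strrep("I", 30))
  m <- merge_read_pairs(p)
  expect_false(m$merged)
  expect_true(m$reason %in% c("no_overlap", "overlap_mismatch"))

  short <- tibble::tibble(id = "y", r1_seq = "ACGT", r1_qual = "IIII",
                          r2_seq = "ACGT", r2_qual = "IIII")
  expect_false(merge_read_pairs(short, min_overlap = 20)$merged)
})

test_that("merging reconstructs random fragments over all overlap lengths", {
  withr::with_seed(21, {
    for (i in 1:40) {
      L <- sample(60:140, 1)
      frag <- rand_dna(L)
      ov <- sample(20:(L - 10), 1)
      r1_end <- sample(seq(max(ov, 30), L - 5), 1)
      r2_start <- r1_end - ov + 1
      m <- merge_read_pairs(make_pair(frag, c(1, r1_end), c(r2_start, L)))
      expect_true(m$merged)
      expect_identical(m$seq, frag)
      expect_gte(m$overlap_len, 20L)
    }
  })
})

demo_sheet <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    genotype = paste0("g", 1:4), cross = "X", generation = "F1",
    template = "DNA", region = "ITS1",
    fwd_barcode = c("AAACCCGGGTTT", "AAACCCGGGTTT",
                    "CCCGGGTTTAAA", "CCCGGGTTTAAA"),
    rev_barcode = c("TTTAAACCCGGG", "GGGTTTAAACCC",
                    "TTTAAACCCGGG", "GGGTTTAAACCC"),
    fwd_primer = "AAGGATCATTGTCGTGACG",
    rev_primer = "GCCGAGAGTCGTGTGGTTTA")
}

contig_for <- function(sheet_row, insert) {
  paste0(sheet_row$fwd_barcode, sheet_row$fwd_primer, insert,
         rc(sheet_row$rev_primer), rc(sheet_row$rev_barcode))
}

test_that("demultiplexing resolves dual-barcode combinations exactly", {
  sheet <- demo_sheet()
  withr::with_seed(5, insert <- rand_dna(220))
  # all four barcode combinations, with shared forward/reverse barcodes,
  # must each route to their own sample
  contigs <- tibble::tibble(
    id = paste0("c", 1:4),
    seq = vapply(1:4, function(i) contig_for(sheet[i, ], insert),
                 character(1)))
  dmx <- demultiplex(contigs, sheet)
  expect_identical(dmx$sample_id, sheet$sample_id)
  expect_true(all(dmx$demux_status == "assigned"))

  # two substitutions in the forward barcode exceed max_bc_mismatch = 0
  mutated <- contigs[1, ]
  substr(mutated$seq, 1, 2) <- "GG"
  expect_identical(demultiplex(mutated, sheet)$demux_status, "unassigned")

  # with tolerance 1 the same contig could match nothing or one sample,
  # but a contig one mismatch from two samples is ambiguous
  sheet2 <- sheet[1:2, ]
  sheet2$rev_barcode <- c("TTTAAACCCGGG", "TTTAAACCCGGC")
  amb <- tibble::tibble(id = "a",
                        seq = contig_for(sheet2[1, ], insert))
  # the two rev barcodes differ at their last base, which sits at the start
  # of the reverse-complemented block: make that base N so the contig is one
  # mismatch from both samples
  substr(amb$seq, nchar(amb$seq) - 11L, nchar(amb$seq) - 11L) <- "N"
  res <- demultiplex(amb, sheet2, max_bc_mismatch = 1)
  expect_identical(res$demux_status, "ambiguous")
  expect_true(is.na(res$sample_id))
})

test_that("demultiplexing conserves reads across bins", {
  sheet <- demo_sheet()
  withr::with_seed(6, {
    contigs <- tibble::tibble(
      id = paste0("c", 1:30),
      seq = c(vapply(1:20, function(i) {
        contig_for(sheet[sample(4, 1), ], rand_dna(200))
      }, character(1)),
      vapply(1:10, function(i) rand_dna(260), character(1))))
  })
  dmx <- demultiplex(contigs, sheet)
  expect_equal(sum(dmx$demux_status == "assigned") +
                 sum(dmx$demux_status == "unassigned") +
                 sum(dmx$demux_status == "ambiguous"), 30)
  expect_equal(sum(dmx$demux_status == "assigned"), 20)
})

test_that("barcode and primer trimming recovers the insert", {
  sheet <- demo_sheet()[1, ]
  withr::with_seed(9, insert <- rand_dna(220))
  contig <- tibble::tibble(id = "c", seq = contig_for(sheet, insert))
  trm <- trim_barcodes_and_primers(contig, sheet$fwd_primer,
                                   sheet$rev_primer)
  expect_true(trm$trimmed)
  expect_identical(trm$insert, insert)

  # one substitution in the forward primer is tolerated
  mut <- contig
  substr(mut$seq, 13, 13) <- ifelse(substr(mut$seq, 13, 13) == "A", "C", "A")
  expect_true(trim_barcodes_and_primers(mut, sheet$fwd_primer,
                                        sheet$rev_primer)$trimmed)

  # a reverse-complemented contig is recovered by the orientation retry
  flipped <- tibble::tibble(id = "f", seq = rc(contig$seq))
  trf <- trim_barcodes_and_primers(flipped, sheet$fwd_primer,
                                   sheet$rev_primer)
  expect_true(trf$trimmed)
  expect_identical(trf$insert, insert)

  # a random 19-mer in place of the forward primer is far beyond 2 mismatches
  withr::with_seed(10, {
    bad <- tibble::tibble(id = "b", seq = paste0(
      sheet$fwd_barcode, rand_dna(19), insert,
      rc(sheet$rev_primer), rc(sheet$rev_barcode)))
  })
  trb <- trim_barcodes_and_primers(bad, sheet$fwd_primer, sheet$rev_primer)
  expect_false(trb$trimmed)
  expect_identical(trb$trim_reason, "fwd_primer_not_found")
})

test_that("reference filtering keeps matches and discards junk", {
  withr::with_seed(13, {
    pair <- generate_species_pair(220, 0.033, seed = 99)
    db <- ref_db(tibble::tibble(id = c("F", "L"), species = c("Fp", "Lm"),
                                region = "ITS1",
                                seq_aligned = c(pair$a, pair$b)))
    inserts <- tibble::tibble(
      sample_id = "s1",
      insert = c(pair$a,                                   # identical to ref
                 paste0(substr(pair$a, 1, 110),
                        substr(pair$b, 111, 220)),         # 50/50 chimera
                 vapply(1:100, function(i) rand_dna(220),  # random junk
                        character(1)),
                 ""))
  })
  flt <- reference_filter(inserts, db, "ITS1")
  expect_true(flt$kept[1])
  expect_true(flt$kept[2])     # chimera passes the 0.75 floor, both parents
  expect_true(all(!flt$kept[3:102]))
  expect_true(all(flt$filter_reason[3:102] %in%
                    c("low_identity", "low_coverage")))
  expect_false(flt$kept[103])
  expect_identical(flt$filter_reason[103], "empty_insert")
  expect_equal(sum(flt$kept) + sum(!flt$kept), nrow(inserts))
})

test_that("dereplication counts exact sequence matches per sample", {
  inserts <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s1", "s1"),
    insert = c("AAA", "AAA", "CCC", "GGG", "AAA"))
  rt <- dereplicate(inserts)
  expect_equal(dplyr::n_distinct(rt$ribotype_id), 3)
  expect_equal(sum(rt$count), 5)
  # most abundant sequence gets the first id
  expect_identical(rt$seq[rt$ribotype_id == "rt000001"][1], "AAA")

  # the same string in two samples is one ribotype with two cells
  rt2 <- dereplicate(tibble::tibble(sample_id = c("s1", "s2"),
                                    insert = "ACGT"))
  expect_equal(dplyr::n_distinct(rt2$ribotype_id), 1)
  expect_equal(nrow(rt2), 2)

  # a trailing base difference is a distinct ribotype (exact semantics)
  rt3 <- dereplicate(tibble::tibble(sample_id = "s1",
                                    insert = c("ACGT", "ACGTT")))
  expect_equal(dplyr::n_distinct(rt3$ribotype_id), 2)
})

test_that("dereplication is a lossless multiset transform", {
  withr::with_seed(17, {
    inserts <- tibble::tibble(
      sample_id = sample(c("s1", "s2", "s3"), 200, TRUE),
      insert = sample(vapply(1:12, function(i) rand_dna(30), character(1)),
                      200, TRUE))
  })
  rt <- dereplicate(inserts)
  expanded <- rt[rep(seq_len(nrow(rt)), rt$count), c("sample_id", "seq")]
  expect_equal(
    tibble::as_tibble(dplyr::arrange(dplyr::count(expanded, sample_id, seq),
                                     sample_id, seq)),
    dplyr::arrange(dplyr::count(inserts, sample_id, seq = insert),
                   sample_id, seq))
})
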