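test_that("six-frame extraction returns the longest stop-bounded CDS", {
  orf <- longest_orf_6frame("ATGAAATAA")
  expect_equal(orf$nt_seq, "ATGAAA")
  expect_equal(orf$frame, "+1")
  expect_equal(orf$start, 1)
  expect_equal(orf$end, 6)
  expect_false(orf$no_stop)
  ## all stops everywhere relevant: empty/flagged candidates are dropped
  ## downstream rather than crashing
  res <- longest_orf_6frame("TAATAATAA")
  expect_true(is.null(res) || res$no_stop || res$n_codons < 2)
  expect_error(longest_orf_6frame("AT"), "shorter")
  expect_error(longest_orf_6frame("ATXGGG"), "characters")
})

test_that("a sequence and its reverse complement give the same CDS", {
  set.seed(5)
  for (k in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
    o1 <- longest_orf_6frame(s)
    o2 <- longest_orf_6frame(divscan:::revcomp(s))
    ## the selected length is always strand-symmetric
    expect_identical(o1$n_codons, o2$n_codons)
    ## with a unique longest stop-bounded run the CDS itself is recovered
    ## identically with the frame sign flipped (ties may legitimately resolve
    ## to either strand under the fixed frame-order preference)
    runs <- oracle_orf_runs(s)
    if (length(runs) && sum(runs == max(runs)) == 1 && !o1$no_stop) {
      expect_identical(o1$nt_seq, o2$nt_seq)
      expect_identical(substr(o1$frame, 1, 1) == "+",
                       substr(o2$frame, 1, 1) == "-")
    }
  }
})

test_that("the selected CDS is at least as long as any stop-bounded run", {
  set.seed(6)
  for (k in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
    orf <- longest_orf_6frame(s)
    runs <- oracle_orf_runs(s)
    if (length(runs)) expect_gte(orf$n_codons, max(runs))
  }
})

test_that("quality and annotation filters drop with machine-readable reasons", {
  mk <- function(nt, no_stop = FALSE) {
    structure(list(transcript_id = "tx", frame = "+1", start = 1,
                   end = nchar(nt), n_codons = nchar(nt) %/% 3,
                   nt_seq = nt, aa_seq = "", has_N = grepl("N", nt),
                   has_gap = grepl("-", nt), no_stop = no_stop),
              class = "cds_candidate")
  }
  clean450 <- strrep("GCT", 150)
  ## just below the 300-nt floor
  expect_equal(filter_cds(mk(strrep("GCT", 99)))$reason, "too_short")
  expect_true(filter_cds(mk(strrep("GCT", 100)))$keep)
  withN <- paste0(substr(clean450, 1, 200), "N", substr(clean450, 202, 450))
  expect_equal(filter_cds(mk(withN))$reason, "ambiguous_base")
  expect_equal(filter_cds(mk(clean450, no_stop = TRUE))$reason,
               "no_stop_frame")
  ann <- data.frame(query_id = "tx", evalue = 1e-12)
  expect_true(filter_cds(mk(strrep("GCT", 200)), ann,
                         require_annotation = TRUE)$keep)
  weak <- data.frame(query_id = "tx", evalue = 1e-4)
  expect_equal(filter_cds(mk(strrep("GCT", 200)), weak,
                          require_annotation = TRUE)$reason, "unannotated")
  expect_true(filter_cds(mk(strrep("GCT", 200)), weak,
                         require_annotation = FALSE)$keep)
  ## idempotence: the filter decision does not depend on prior calls
  expect_identical(filter_cds(mk(clean450)), filter_cds(mk(clean450)))
})

test_that("codon alignments are trimmed to the common in-frame overlap", {
  set.seed(8)
  cds300 <- random_coding_sequence(300)
  ## identical anchors, equal lengths: full-length alignment
  pair <- data.frame(gene_id = "g", strand = "+",
                     a_start = 1001, a_end = 1900, a_qstart = 6, a_qend = 905,
                     a_nseg = 1,
                     b_start = 1001, b_end = 1900, b_qstart = 6, b_qend = 905,
                     b_nseg = 1)
  orf_a <- longest_orf_6frame(paste0("CGTAA", cds300, "TAAGC"))
  built <- build_codon_alignment(pair, orf_a, orf_a)
  expect_equal(built$alignment$n_codons, 300)
  ## B misses the first 3 codons and is anchored 9 bp downstream:
  ## a 297-codon in-frame overlap remains
  cds297 <- substr(cds300, 10, 900)
  orf_b <- longest_orf_6frame(paste0("CGTAA", cds297, "TAAGC"))
  pair2 <- pair
  pair2$b_start <- 1010; pair2$b_qend <- 896
  built2 <- build_codon_alignment(pair2, orf_a, orf_b)
  expect_equal(built2$alignment$n_codons, 297)
  expect_identical(built2$alignment$seq_a, built2$alignment$seq_b)
  ## frame-incompatible anchors are dropped with a reason
  pair3 <- pair
  pair3$b_start <- 1011; pair3$b_qend <- 895
  built3 <- build_codon_alignment(pair3, orf_a, orf_b)
  expect_null(built3$alignment)
  expect_true(built3$reason %in% c("frame_mismatch", "length_mismatch"))
  ## alignments below the codon floor are dropped
  expect_equal(build_codon_alignment(pair, orf_a, orf_a,
                                     min_codons = 400)$reason, "too_short")
})
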