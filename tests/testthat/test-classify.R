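test_that("hit tables are filtered by e-value and strand-normalized", {
  f <- withr::local_tempfile()
  rows <- c(
    "q1\ts1\t99.0\t500\t2\t0\t1\t500\t1000\t1499\t1e-20\t900",
    "q2\ts1\t95.0\t400\t5\t0\t1\t400\t2000\t2399\t1e-10\t700",  # above cutoff
    "q3\ts1\t98.0\t401\t3\t0\t1\t401\t500\t100\t1e-40\t800",    # minus strand
    "q4\ts1\tbad\t100\t0\t0\t1\tx\t10\t100\t1e-30\t100")        # malformed
  writeLines(rows, f)
  expect_warning(h <- read_hit_table(f), "malformed")
  expect_setequal(h$qseqid, c("q1", "q3"))
  m <- h[h$qseqid == "q3", ]
  expect_equal(m$s_start, 100)
  expect_equal(m$s_end, 500)
  expect_equal(m$strand, "-")
  ## too few columns is a format error naming the missing columns
  f2 <- withr::local_tempfile()
  writeLines("q1\ts1\t99.0\t500\t2\t0\t1\t500\t1000\t1499", f2)
  expect_error(read_hit_table(f2), "evalue")
})

test_that("transcripts are partitioned into the five positional categories", {
  hits <- make_hits(
    hit("par", "s1", 1, 900, 1000, 1899),          # two scaffolds
    hit("par", "s2", 1, 900, 5000, 5899),
    hit("tan", "s1", 1, 900, 10000, 10899),        # two disjoint loci
    hit("tan", "s1", 1, 900, 50000, 50899),
    hit("al1", "s1", 1, 1500, 1000, 2500),         # reciprocal overlap 1.0
    hit("al2", "s1", 1, 1500, 1000, 2500),
    hit("ex1", "s1", 1, 301, 100, 400),            # intron-split, gap 499 bp
    hit("ex1", "s1", 302, 702, 900, 1300),
    hit("unq", "s1", 1, 900, 90000, 90899))
  cls <- classify_transcripts(hits)
  cat1 <- setNames(cls$category, cls$transcript_id)
  expect_equal(cat1[["par"]], "scaffold_paralog")
  expect_equal(cat1[["tan"]], "tandem_paralog")
  expect_equal(cat1[["al1"]], "allelic")
  expect_equal(cat1[["al2"]], "allelic")
  expect_equal(cat1[["ex1"]], "exon")
  expect_equal(cls$n_segments[cls$transcript_id == "ex1"], 2)
  expect_equal(cat1[["unq"]], "uniq")
  ## every transcript got exactly one category
  expect_equal(nrow(cls), length(unique(hits$qseqid)))
  ## order invariance
  set.seed(1)
  cls2 <- classify_transcripts(hits[sample(nrow(hits)), ])
  expect_identical(cls[order(cls$transcript_id), ],
                   cls2[order(cls2$transcript_id), ])
})

test_that("small scaffold gaps merge while true introns split", {
  near <- make_hits(hit("m", "s1", 1, 300, 100, 399),
                    hit("m", "s1", 301, 600, 420, 719))  # gap 20 <= 30
  expect_equal(classify_transcripts(near)$category, "uniq")
  far <- make_hits(hit("m", "s1", 1, 300, 100, 399),
                   hit("m", "s1", 301, 600, 500, 799))   # gap 100 > 30
  expect_equal(classify_transcripts(far)$category, "exon")
})

test_that("redundant overlapping rows reduce to the best-bitscore locus", {
  hits <- make_hits(hit("q", "s1", 1, 900, 1000, 1899, bs = 900),
                    hit("q", "s1", 31, 900, 1030, 1899, bs = 500))
  cls <- classify_transcripts(hits)
  expect_equal(cls$category, "uniq")
  expect_equal(cls$start, 1000)
  expect_equal(cls$end, 1899)
})

test_that("empty hit lists classify to an empty result with a warning", {
  h <- make_hits(hit("q", "s1", 1, 10, 1, 10))[0, ]
  expect_warning(cls <- classify_transcripts(h), "empty")
  expect_equal(nrow(cls), 0)
})

test_that("ortholog pairing keeps single-locus anchors and drops the rest", {
  ca <- classify_transcripts(make_hits(
    hit("a1", "s1", 1, 900, 100, 999),
    hit("a2", "s1", 1, 900, 5000, 5899),
    hit("a3", "s1", 1, 900, 9000, 9899),
    hit("a3b", "s2", 1, 900, 100, 999)))
  cb <- classify_transcripts(make_hits(
    hit("b1", "s1", 1, 900, 100, 999),
    hit("b2", "s1", 1, 900, 5000, 5899),
    hit("b2x", "s1", 1, 900, 5000, 5899),   # allelic on the B side
    hit("b3", "s2", 1, 900, 100, 999),
    hit("b3x", "s3", 1, 900, 100, 999)))
  cb$category[cb$transcript_id == "b3x"] <- "scaffold_paralog"
  pairs <- pair_orthologs(ca, cb)
  ## a1-b1 pairs; a2 fails (b2 allelic); a3b locus exists on both sides
  expect_setequal(pairs$transcript_a, c("a1", "a3b"))
  expect_equal(pairs$transcript_b[pairs$transcript_a == "a1"], "b1")
  expect_true(all(!pairs$has_introns))
})

test_that("ambiguous loci (two candidate partners) are dropped and logged", {
  ca <- classify_transcripts(make_hits(hit("a1", "s1", 1, 900, 100, 999)))
  cb <- classify_transcripts(make_hits(
    hit("b1", "s1", 1, 900, 100, 999),
    hit("b2", "s1", 1, 905, 95, 999)))
  ## force both b transcripts to uniq at overlapping anchors
  cb$category <- "uniq"
  pairs <- pair_orthologs(ca, cb)
  expect_equal(nrow(pairs), 0)
  expect_true(nrow(attr(pairs, "dropped")) >= 2)
  expect_true(all(attr(pairs, "dropped")$reason == "ambiguous"))
})
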