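test_that("truth sets are deterministic and realize the configured layout", {
  cfg <- sim_config("early", seed = 1)
  ts1 <- make_truth_set(cfg)
  ts2 <- make_truth_set(cfg)
  expect_identical(ts1$truth, ts2$truth)
  expect_identical(ts1$scaffolds, ts2$scaffolds)
  ## genes sorted and non-overlapping within each scaffold
  for (s in split(ts1$truth, ts1$truth$scaffold_id)) {
    expect_false(is.unsorted(s$start_bp))
    if (nrow(s) > 1)
      expect_true(all(s$start_bp[-1] > s$end_bp[-nrow(s)]))
  }
  ## ~58% of genes with true_t = 0 (binomial tolerance, excluding the
  ## configured island which overrides the zero draw)
  frac <- mean(ts1$truth$true_t == 0)
  n <- nrow(ts1$truth)
  expect_lt(abs(frac - 0.58), 3 * sqrt(0.58 * 0.42 / n) + 3 / n)
  ## intron-split genes and only they have >= 2 segments
  expect_true(all(ts1$truth$n_segments >= 2) ==
                all(ts1$truth$category_label == "exon"))
  expect_setequal(unique(ts1$segments$gene_id),
                  ts1$truth$gene_id[ts1$truth$category_label == "exon"])
})

test_that("islands are placed exactly as specified", {
  cfg <- sim_config("custom", n_scaffolds = 1, genes_per_scaffold = 5,
                    frac_zero_divergence = 1,
                    t_distribution = function(n) rep(0, n),
                    complication_rates = c(scaffold_paralog = 0,
                      tandem_paralog = 0, allelic = 0, intron_split = 0),
                    island_spec = list(c(1, 2, 3, 0.5)), seed = 3)
  ts <- make_truth_set(cfg)
  expect_equal(ts$truth$true_t, c(0, 0.5, 0.5, 0.5, 0))
  ## an island too long for the scaffold is a configuration error
  expect_error(sim_config("custom", n_scaffolds = 1, genes_per_scaffold = 5,
                          frac_zero_divergence = 1,
                          t_distribution = function(n) rep(0, n),
                          island_spec = list(c(1, 4, 3, 0.5)), seed = 3),
               "island")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config("early", frac_zero_divergence = 1.2), "proportion")
  expect_error(sim_config("early", complication_rates =
    c(scaffold_paralog = 0.6, tandem_paralog = 0.6, allelic = 0,
      intron_split = 0)), "sum")
  expect_error(sim_config("early", gene_length_codons = 1), ">= 2")
})

test_that("the codon process respects t = 0, omega = 0 and determinism", {
  set.seed(21)
  anc <- random_coding_sequence(120)
  expect_identical(evolve_codon_pair(anc, 0, 0.5, 2)$seq_a, anc)
  ## omega = 0: descendants may differ in nucleotides but never in protein
  p <- evolve_codon_pair(anc, 0.8, 0, 2, seed = 9)
  aa <- function(s) paste(divscan:::translate_codons(
    divscan:::split_codons(s)), collapse = "")
  expect_identical(aa(p$seq_a), aa(p$seq_b))
  expect_false(identical(p$seq_a, p$seq_b))
  ## same seed, same pair
  p2 <- evolve_codon_pair(anc, 0.8, 0, 2, seed = 9)
  expect_identical(p, p2)
  ## invalid ancestors are rejected with a reason
  expect_error(evolve_codon_pair("ATGA", 0.1, 1), "multiple of 3")
  expect_error(evolve_codon_pair("ATGTAAAAA", 0.1, 1), "stop codon")
})

test_that("realized divergence converges to the target branch length", {
  set.seed(31)
  n <- 300
  tt <- numeric(n)
  for (k in seq_len(n)) {
    a <- sim_alignment(300, 0.3, 1, 2)
    r <- divergence_t(apply_omega_rules(yn00_rates(a)))
    tt[k] <- r$t
  }
  expect_lt(abs(mean(tt, na.rm = TRUE) - 0.3) / 0.3, 0.1)
})

test_that("emitted bundles are byte-identical for a fixed config and seed", {
  cfg <- sim_config("custom", n_scaffolds = 2, genes_per_scaffold = 4,
                    gene_length_codons = 110,
                    frac_zero_divergence = 0.5,
                    t_distribution = function(n) rep(0.1, n),
                    seed = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- simulate_bundle(cfg, d1)
  b2 <- simulate_bundle(cfg, d2)
  for (f in c("transcripts_a", "hits_a", "truth", "scaffolds", "annotations"))
    expect_identical(readLines(b1[[f]]), readLines(b2[[f]]))
})

test_that("emitted hit tables realize the complication categories", {
  cfg <- sim_config("custom", n_scaffolds = 3, genes_per_scaffold = 8,
                    gene_length_codons = 110, frac_zero_divergence = 0.5,
                    t_distribution = function(n) rep(0.05, n),
                    complication_rates = c(scaffold_paralog = 0.2,
                      tandem_paralog = 0.2, allelic = 0.2,
                      intron_split = 0.2), seed = 12)
  d <- withr::local_tempdir()
  b <- simulate_bundle(cfg, d)
  truth <- b$truth_set$truth
  hits <- list(A = read_hit_table(b$hits_a), B = read_hit_table(b$hits_b))
  for (k in which(truth$category_label == "scaffold_paralog")) {
    g <- truth[k, ]
    h <- hits[[g$complication_side]]
    qid <- paste0(g$complication_side, "_", g$gene_id)
    expect_gte(length(unique(h$sseqid[h$qseqid == qid])), 2)
  }
  for (k in which(truth$category_label == "exon")) {
    g <- truth[k, ]
    h <- hits$A[hits$A$qseqid == paste0("A_", g$gene_id), ]
    expect_equal(nrow(h), g$n_segments)
    h <- h[order(h$qstart), ]
    ## co-linear: contiguous on the transcript, ordered on the scaffold
    if (nrow(h) > 1) {
      expect_true(all(h$qstart[-1] == h$qend[-nrow(h)] + 1))
      ord <- if (h$strand[1] == "+") diff(h$s_start) > 0 else diff(h$s_start) < 0
      expect_true(all(ord))
    }
  }
  for (k in which(truth$category_label == "allelic")) {
    g <- truth[k, ]
    h <- hits[[g$complication_side]]
    qid <- paste0(g$complication_side, "_", g$gene_id)
    alt <- paste0(qid, "_alt")
    expect_true(alt %in% h$qseqid)
    expect_identical(sort(unique(h$s_start[h$qseqid == qid])),
                     sort(unique(h$s_start[h$qseqid == alt])))
  }
})
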