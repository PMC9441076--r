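test_that("identical sequences give zero rates and the identical flag", {
  a <- codon_alignment(strrep("ATGAAA", 50), strrep("ATGAAA", 50), "id")
  for (r in list(ng86_rates(a), yn00_rates(a))) {
    expect_gt(r$S, 0); expect_gt(r$N, 0)
    expect_equal(r$Sd, 0); expect_equal(r$Nd, 0)
    expect_equal(r$dS, 0); expect_equal(r$dN, 0)
    expect_true("identical" %in% r$flags)
    r2 <- apply_omega_rules(r)
    expect_equal(r2$omega, 0)
    expect_equal(divergence_t(r2)$t, 0)
  }
})

test_that("single synonymous and pathway-averaged differences match the oracle", {
  pad <- strrep("AAA", 19)
  ## TTT <-> TTC: one synonymous difference, dN = 0
  a <- codon_alignment(paste0(pad, "TTT"), paste0(pad, "TTC"))
  r <- ng86_rates(a)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$dN, 0)
  ## TTT <-> CTC: doubly substituted codon, averaged over both orderings
  b <- codon_alignment(paste0(pad, "TTT"), paste0(pad, "CTC"))
  rb <- ng86_rates(b)
  oracle <- oracle_pair_diffs("TTT", "CTC")
  expect_equal(rb$Sd, unname(oracle["sd"]), tolerance = 1e-12)
  expect_equal(rb$Nd, unname(oracle["nd"]), tolerance = 1e-12)
})

test_that("pathway-averaged counts equal the exhaustive oracle on random pairs", {
  set.seed(17)
  tabs <- divscan:::codon_tables()
  for (k in 1:60) {
    anc <- random_coding_sequence(30)
    mut <- evolve_codon_pair(anc, 0.6, 1, 2)
    a <- codon_alignment(mut$seq_a, mut$seq_b)
    r <- ng86_rates(a)
    o <- oracle_total_diffs(mut$seq_a, mut$seq_b)
    expect_equal(r$Sd + r$Nd, unname(o["sd"] + o["nd"]), tolerance = 1e-9)
    expect_equal(r$Sd, unname(o["sd"]), tolerance = 1e-9)
  }
})

test_that("all rate operations are symmetric in the two sequences", {
  set.seed(19)
  p <- evolve_codon_pair(random_coding_sequence(150), 0.4, 0.5, 2)
  a1 <- codon_alignment(p$seq_a, p$seq_b)
  a2 <- codon_alignment(p$seq_b, p$seq_a)
  for (fn in list(ng86_rates, yn00_rates)) {
    r1 <- fn(a1); r2 <- fn(a2)
    for (f in c("S", "N", "Sd", "Nd", "dS", "dN", "kappa"))
      expect_equal(r1[[f]], r2[[f]], tolerance = 1e-12)
  }
  t1 <- ts_tv_counts(a1); t2 <- ts_tv_counts(a2)
  expect_identical(t1, t2)
})

test_that("yn00 approaches ng86 with kappa = 1 and uniform codon usage", {
  set.seed(23)
  rel <- numeric(60)
  for (k in 1:60) {
    a <- sim_alignment(300, 0.3, 1, 1)
    rel[k] <- abs(yn00_rates(a)$S - ng86_rates(a)$S) / ng86_rates(a)$S
  }
  expect_lt(median(rel), 0.05)
})

test_that("kappa estimation recovers the simulated ratio and degrades safely", {
  set.seed(29)
  kaps <- vapply(1:40, function(k) yn00_rates(sim_alignment(300, 0.3, 1, 3))$kappa,
                 numeric(1))
  expect_lt(abs(median(kaps) - 3) / 3, 0.25)
  ## no variation at fourfold/nondegenerate sites: fall back to kappa = 1
  a <- codon_alignment(strrep("ATGAAA", 50), strrep("ATGAAA", 50))
  r <- yn00_rates(a)
  expect_equal(r$kappa, 1)
  expect_true("kappa_fallback" %in% r$flags)
})

test_that("omega edge rules follow the stated conventions", {
  mk <- function(dN, dS, S) {
    r <- ng86_rates(codon_alignment(strrep("ATG", 10), strrep("ATG", 10)))
    r$dN <- dN; r$dS <- dS; r$S <- S
    r
  }
  expect_equal(apply_omega_rules(mk(0, 0, 50))$omega, 0)
  r <- apply_omega_rules(mk(0.1, 0, 50))
  expect_equal(r$dS, 0.02)
  expect_equal(r$omega, 5.0)
  expect_true("dS_zero_reset" %in% r$flags)
  expect_equal(apply_omega_rules(mk(0.02, 0.2, 50))$omega, 0.1)
  expect_equal(apply_omega_rules(mk(0, 0.2, 50))$omega, 0)
  rs <- apply_omega_rules(mk(NA_real_, 0.2, 50))
  expect_true(is.na(rs$omega))
  expect_true("infinite_filtered" %in% rs$flags)
  ## the data-frame path agrees with the single-record path
  df <- data.frame(dN = c(0, 0.1, 0.02), dS = c(0, 0, 0.2), S = c(50, 50, 50),
                   flags = "")
  df <- apply_omega_rules(df)
  expect_equal(df$omega, c(0, 5, 0.1))
})

test_that("divergence t follows its definition", {
  r <- ng86_rates(codon_alignment(strrep("ATG", 10), strrep("ATG", 10)))
  r$S <- 100; r$N <- 200; r$dS <- 0.3; r$dN <- 0.03
  expect_equal(divergence_t(r)$t, 0.36)
  r$dN <- 0; r$N <- 100; r$dS <- 0.3
  expect_equal(divergence_t(r)$t, 1.5 * 0.3)
})

test_that("transition/transversion tallies follow the substitution classes", {
  a <- codon_alignment("AAAAAA", "GAAAAA")  # A<->G transition
  expect_equal(ts_tv_counts(a)$ts_count, 1)
  expect_equal(ts_tv_counts(a)$tv_count, 0)
  b <- codon_alignment("AAAAAA", "ATAAAA")  # A<->T transversion
  expect_equal(ts_tv_counts(b)$ts_count, 0)
  expect_equal(ts_tv_counts(b)$tv_count, 1)
  cc <- codon_alignment("AAAAAA", "AAAAAA")
  expect_equal(ts_tv_counts(cc)$ts_count, 0)
  expect_equal(ts_tv_counts(cc)$tv_count, 0)
  ## ts + tv always equals the number of mismatched sites
  set.seed(33)
  for (k in 1:20) {
    p <- evolve_codon_pair(random_coding_sequence(100), 0.5, 1, 2)
    tt <- ts_tv_counts(codon_alignment(p$seq_a, p$seq_b))
    mism <- sum(strsplit(p$seq_a, "")[[1]] != strsplit(p$seq_b, "")[[1]])
    expect_equal(tt$ts_count + tt$tv_count, mism)
  }
})

test_that("mean estimated divergence is monotone in the true divergence", {
  set.seed(37)
  means <- vapply(c(0.05, 0.2, 0.5), function(tt) {
    est <- vapply(1:60, function(k) {
      r <- divergence_t(apply_omega_rules(yn00_rates(sim_alignment(300, tt, 0.3, 2))))
      r$t
    }, numeric(1))
    mean(est, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
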