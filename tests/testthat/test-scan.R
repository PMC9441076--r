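test_that("genes are ordered by midpoint and short scaffolds excluded", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      scaffold_id = c("s1", "s1", "s1", "s2"),
                      start = c(9000, 4000, 19000, 100),
                      end = c(11000, 6000, 21000, 1000),
                      t = c(0.1, 0.2, 0.3, 0.4), omega = c(1, 2, 3, 4))
  scf <- data.frame(scaffold_id = c("s1", "s2"),
                    length_bp = c(500000, 250000))
  scans <- order_genes_on_scaffolds(genes, scf)
  expect_length(scans, 1)                       # s2 < 300 kb excluded
  expect_equal(scans[[1]]$genes$gene_id, c("g2", "g1", "g3"))
  expect_error(order_genes_on_scaffolds(
    transform(genes, scaffold_id = "nope"), scf), "unknown")
})

test_that("pattern classification follows the run/isolation rules", {
  expect_equal(classify_pattern(rep(0.01, 20)), "A_none")
  expect_equal(classify_pattern(c(rep(0.01, 19), 0.5)), "B_isolated")
  expect_equal(classify_pattern(c(0.5, rep(0.01, 18), 0.5)), "B_isolated")
  ## a run of >= 3 consecutive divergent genes is an island
  expect_equal(classify_pattern(c(rep(0.01, 5), rep(0.5, 4), rep(0.01, 5))),
               "C_island")
  ## more than max_isolated divergent genes, even scattered
  expect_equal(classify_pattern(c(0.5, 0.01, 0.5, 0.01, 0.5)), "C_island")
  expect_equal(classify_pattern(make_scan(rep(0.01, 10))), "A_none")
})

test_that("the dispersion index matches its definition and scales linearly", {
  expect_equal(dispersion_index(c(0, 1, 2, 3)), 0)       # equal spacing
  ## distances 1, 1, 10: mean 4, sample variance 27
  expect_equal(dispersion_index(c(0, 1, 2, 12)), 6.75)
  expect_equal(dispersion_index(10 * c(0, 1, 2, 12)),
               10 * 6.75)
  expect_length(dispersion_index(c(5, 9)), 0)            # < 2 distances
  ## order invariance
  expect_equal(dispersion_index(c(12, 0, 2, 1)), 6.75)
})

test_that("per-scaffold correlation handles exact and degenerate cases", {
  sc1 <- make_scan(t = seq(0, 0.5, 0.1), omega = seq(0.5, 0, -0.1))
  sc2 <- make_scan(t = seq(0, 0.5, 0.1), omega = 1 + 2 * seq(0, 0.5, 0.1))
  sc3 <- make_scan(t = seq(0, 0.5, 0.1), omega = rep(0.3, 6))
  sc4 <- make_scan(t = c(0.1, 0.2), omega = c(0.1, 0.2))
  out <- correlate_t_omega(list(sc1, sc2, sc3, sc4))
  expect_equal(out$r[1], -1)
  expect_equal(out$r[2], 1)
  expect_equal(out$flag[3], "zero_variance")
  expect_equal(out$flag[4], "too_few")
  h <- attr(out, "hist")
  expect_equal(sum(h$counts), 2)
})

test_that("dN on dS regression matches the closed-form normal equations", {
  d <- data.frame(dS = c(0.1, 0.2, 0.3, 0.5, 0.8),
                  dN = c(0.03, 0.02, 0.08, 0.1, 0.12))
  fit <- dn_ds_regression(d)
  o <- oracle_ols(d$dS, d$dN)
  expect_equal(fit$slope, unname(o["slope"]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(o["intercept"]), tolerance = 1e-12)
  ## exact proportionality
  d2 <- data.frame(dS = c(0.1, 0.2, 0.4), dN = 0.2 * c(0.1, 0.2, 0.4))
  fit2 <- dn_ds_regression(d2)
  expect_equal(fit2$slope, 0.2, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0, tolerance = 1e-12)
  expect_error(dn_ds_regression(data.frame(dS = c(0.1, 0.1, 0.1),
                                           dN = c(0, 0.1, 0.2))), "variance")
  expect_error(dn_ds_regression(d[1:2, ]), ">= 3")
})

test_that("divergence summaries bin genes as defined", {
  s <- divergence_summary(c(0, 0, 0.02, 0.06), class_edges = c(0.01, 0.05))
  expect_equal(s$identical_fraction, 0.5)
  expect_equal(unname(s$t_bins), c(0, 0.25, 0.25))
  expect_equal(sum(s$t_bins) + s$identical_fraction, 1)
  s2 <- divergence_summary(rep(0, 10))
  expect_equal(s2$identical_fraction, 1)
  df <- data.frame(t = c(0, 0.1, 0.9), omega = c(0, 0.3, 1.2))
  s3 <- divergence_summary(df)
  expect_equal(unname(s3$omega_bins),
               c(1 / 3, 1 / 3, 0, 1 / 3))
  expect_error(divergence_summary(c(0.1), class_edges = c(0.5, 0.2)),
               "increasing")
})

test_that("scaffold scans aggregate pattern, dispersion and correlation", {
  sc_island <- make_scan(t = c(rep(0.01, 4), rep(0.5, 4), rep(0.01, 4)),
                         omega = runif(12))
  sc_none <- make_scan(t = rep(0.01, 12), omega = runif(12))
  out <- scan_scaffolds(list(sc_island, sc_none))
  expect_equal(out$pattern, c("C_island", "A_none"))
  expect_equal(out$n_divergent, c(4, 0))
  expect_true(is.na(out$dispersion_index[2]))
  ## consecutive equally-spaced divergent genes: zero dispersion
  expect_equal(out$dispersion_index[1], 0)
  ## pattern proportions over examined scaffolds sum to one
  expect_equal(sum(table(out$pattern)) / nrow(out), 1)
})

test_that("the fixed-substitution load reproduces the worked arithmetic", {
  expect_equal(fixed_substitution_load(1000, 0.5, 100, 0.01), 500)
})
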