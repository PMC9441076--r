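# Significance of positive selection.
#
# Each alignment's codon columns are resampled with replacement (the same
# columns in both sequences) to produce bootstrap replicates of dN and dS;
# the observed difference D = dN - dS is standardized by the bootstrap
# standard deviation and referred to a one-sided normal test (the replicate
# mean is numerically near-identical to D_obs and is available as an
# alternative centering).  P-values are adjusted across genes with the
# Benjamini-Hochberg step-up (Benjamini-Yekutieli behind a flag), and a gene
# is called positively selected when omega > 1 and q < alpha.
#
# Numerical note: codon resampling is a multinomial draw over the alignment's
# distinct codon pairs, so replicates are computed by linear tallies over
# pair counts.  For the Yang-Nielsen method the per-gene nuisance parameters
# (kappa, codon frequencies) are estimated once from the observed alignment
# and held fixed across replicates; sites, difference counts, dN, dS and D
# are recomputed per replicate.

gene_boot_vectors <- function(aln, method) {
  tabs <- codon_tables()
  pr <- aln_pairs(aln)
  ij <- cbind(pr$i, pr$j)
  if (method == "yn00") {
    kap <- estimate_kappa(pr)
    pi <- f3x4_frequencies(pr)
    s61 <- yn00_site_vector(kap$kappa, pi)
    s_pair <- (s61[pr$i] + s61[pr$j]) / 2
  } else {
    s_pair <- (tabs$svec[pr$i] + tabs$svec[pr$j]) / 2
  }
  list(w = pr$w, L = pr$L, method = method,
       V = cbind(s = s_pair,
                 sdts = tabs$SDts[ij], sdtv = tabs$SDtv[ij],
                 ndts = tabs$NDts[ij], ndtv = tabs$NDtv[ij]))
}

boot_rates_from_counts <- function(counts, bv) {
  ## counts: npairs x nreps; returns data.frame(dS, dN) per replicate
  st <- crossprod(counts, bv$V)     # nreps x 5
  S <- st[, "s"]; N <- 3 * bv$L - S
  if (bv$method == "yn00") {
    dS <- k80_dist(st[, "sdts"] / S, st[, "sdtv"] / S)
    dN <- k80_dist(st[, "ndts"] / N, st[, "ndtv"] / N)
  } else {
    dS <- jc_correct((st[, "sdts"] + st[, "sdtv"]) / S)
    dN <- jc_correct((st[, "ndts"] + st[, "ndtv"]) / N)
  }
  list(dS = dS, dN = dN)
}

#' Codon-bootstrap test of D = dN - dS
#'
#' Produces `n_reps` bootstrap replicates of the alignment by resampling
#' codon columns with replacement (jointly in both sequences), recomputes dN
#' and dS for each replicate with the chosen counting method, and performs a
#' one-sided z-test of whether the observed D = dN - dS exceeds zero:
#' z = D_obs / sd(D_reps) (sample standard deviation), p = 1 - Phi(z).
#' When the bootstrap distribution is degenerate (sd = 0), p is 0 if
#' D_obs > 0 and 1 otherwise, with a `degenerate_sd` flag.
#'
#' @param aln a [codon_alignment()]
#' @param n_reps number of bootstrap replicates (default 1000; >= 2)
#' @param method `"yn00"` or `"ng86"` (must match the main run)
#' @param seed optional integer seed for the resampling
#' @param center `"observed"` (default: z = D_obs / sd) or
#'   `"replicate_mean"` (z = mean(D_reps) / sd)
#' @return object of class `selection_test`: `gene_id`, `D_obs`, `n_reps`,
#'   `D_reps`, `z`, `p`, `seed`, `flags`
#' @export
bootstrap_D <- function(aln, n_reps = 1000L, method = c("yn00", "ng86"),
                        seed = NULL, center = c("observed", "replicate_mean")) {
  method <- match.arg(method)
  center <- match.arg(center)
  if (!is_count(n_reps) || n_reps < 2L)
    stopf("n_reps must be an integer >= 2")
  if (aln$n_codons < 2L) stopf("alignment must have >= 2 codons")
  if (!is.null(seed)) set.seed(seed)
  flags <- character()
  bv <- gene_boot_vectors(aln, method)
  obs <- boot_rates_from_counts(matrix(bv$w, ncol = 1), bv)
  if (is.na(obs$dS) || is.na(obs$dN)) {
    return(structure(list(gene_id = aln$gene_id, D_obs = NA_real_,
                          n_reps = as.integer(n_reps), D_reps = numeric(),
                          z = NA_real_, p = NA_real_, seed = seed,
                          method = method, center = center,
                          flags = "saturated"), class = "selection_test"))
  }
  D_obs <- obs$dN - obs$dS
  counts <- rmultinom(n_reps, size = bv$L, prob = bv$w / sum(bv$w))
  reps <- boot_rates_from_counts(counts, bv)
  D <- reps$dN - reps$dS
  if (anyNA(D)) {
    flags <- c(flags, "replicates_dropped")
    D <- D[!is.na(D)]
  }
  s <- if (length(D) >= 2L) sd(D) else 0
  if (is.na(s) || s == 0) {
    flags <- c(flags, "degenerate_sd")
    z <- NA_real_
    p <- if (D_obs > 0) 0 else 1
  } else {
    num <- if (center == "observed") D_obs else mean(D)
    z <- num / s
    p <- 1 - pnorm(z)
  }
  structure(list(gene_id = aln$gene_id, D_obs = D_obs,
                 n_reps = as.integer(n_reps), D_reps = D, z = z, p = p,
                 seed = seed, method = method, center = center,
                 flags = flags), class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat(sprintf("selection test '%s': D = %s, z = %s, p = %s (%d reps)\n",
              x$gene_id, format(x$D_obs, digits = 4),
              format(x$z, digits = 4), format(x$p, digits = 4), x$n_reps))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up adjusted p-values (q-values), returned in input
#' order; Benjamini-Yekutieli available via `method = "BY"`.
#'
#' @param p_values numeric vector of p-values (each between 0 and 1)
#' @param method `"BH"` (default) or `"BY"`
#' @return q-values, same length and order as the input
#' @export
bh_adjust <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1] with no missing values")
  p.adjust(p_values, method = method)
}

#' Call positively selected genes
#'
#' A gene is called positively selected when its omega exceeds one and its
#' FDR-adjusted p-value is below `alpha`.  Output is ordered by q, then
#' gene_id.
#'
#' @param rates data frame with `gene_id`, `omega`
#' @param tests data frame with `gene_id`, `p`, `q`
#' @param alpha significance level (default 0.05)
#' @return data frame `gene_id`, `omega`, `p`, `q`, `significant`
#' @export
call_positive_selection <- function(rates, tests, alpha = 0.05) {
  orphan_r <- setdiff(rates$gene_id, tests$gene_id)
  orphan_t <- setdiff(tests$gene_id, rates$gene_id)
  if (length(orphan_r) || length(orphan_t))
    stopf("gene_id mismatch between rates and tests (rates-only: %s; tests-only: %s)",
          paste(head(orphan_r, 5), collapse = ","),
          paste(head(orphan_t, 5), collapse = ","))
  m <- merge(rates[, c("gene_id", "omega")],
             tests[, c("gene_id", "p", "q")], by = "gene_id")
  m$significant <- !is.na(m$omega) & !is.na(m$q) &
    m$omega > 1 & m$q < alpha
  m <- m[order(m$q, m$gene_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Run the selection test over a batch of alignments
#'
#' Tests every gene whose omega is positive and finite (identical genes and
#' saturated estimates are not testable), derives a per-gene seed from
#' `seed`, adjusts p-values across all tested genes and merges the calls.
#'
#' @param alignments named or ordered list of [codon_alignment()]s
#' @param rates data frame from [estimate_rates()] over the same genes
#' @param n_reps bootstrap replicates per gene
#' @param alpha significance level for the call
#' @param method counting method (matching the main run)
#' @param seed integer seed; gene i uses seed + i
#' @param fdr_method `"BH"` or `"BY"`
#' @return data frame `gene_id`, `D_obs`, `z`, `p`, `q`, `significant`,
#'   `tested`, `n_reps`, `seed`
#' @export
run_selection_tests <- function(alignments, rates, n_reps = 1000L,
                                alpha = 0.05, method = c("yn00", "ng86"),
                                seed = 1L, fdr_method = "BH") {
  method <- match.arg(method)
  ids <- vapply(alignments, function(a) a$gene_id, "")
  out <- data.frame(gene_id = rates$gene_id, D_obs = NA_real_, z = NA_real_,
                    p = NA_real_, q = NA_real_, significant = FALSE,
                    tested = FALSE, n_reps = as.integer(n_reps),
                    seed = NA_integer_, stringsAsFactors = FALSE)
  testable <- which(!is.na(rates$omega) & rates$omega > 0)
  for (k in testable) {
    a <- alignments[[match(rates$gene_id[k], ids)]]
    gseed <- (seed + k) %% .Machine$integer.max
    st <- bootstrap_D(a, n_reps = n_reps, method = method, seed = gseed)
    out$D_obs[k] <- st$D_obs; out$z[k] <- st$z; out$p[k] <- st$p
    out$seed[k] <- gseed
    out$tested[k] <- !is.na(st$p)
  }
  tested <- which(out$tested)
  if (length(tested))
    out$q[tested] <- bh_adjust(out$p[tested], method = fdr_method)
  out$significant <- out$tested & !is.na(rates$omega) & rates$omega > 1 &
    !is.na(out$q) & out$q < alpha
  out
}
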