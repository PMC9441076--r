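# Pairwise substitution-rate engine.
#
# Two counting estimators of synonymous (dS) and nonsynonymous (dN)
# substitution rates from a gap-free in-frame pair of coding sequences:
#
#   * ng86_rates(): Nei & Gojobori (1986).  Sites are counted by codon
#     degeneracy fractions with equal weighting; differences are averaged over
#     all equal-weight minimal mutational pathways between codons, excluding
#     pathways through stop codons; a Jukes-Cantor correction is applied to
#     the proportions of synonymous and nonsynonymous differences.
#
#   * yn00_rates(): Yang & Nielsen (2000) style counting.  Codon frequencies
#     are estimated from the pair by position-specific nucleotide frequencies
#     (F3x4); the transition/transversion rate ratio kappa is estimated from
#     fourfold-degenerate and nondegenerate sites with a K80 correction; site
#     counts are weighted by kappa and codon usage; differences are counted
#     with equal pathway weighting and corrected per site class (K80 on the
#     transition/transversion partition within synonymous and nonsynonymous
#     differences).
#
# omega (dN/dS) is finalized by apply_omega_rules(), which implements the
# scan's edge conventions: identical pairs get omega = 0; dN > 0 with dS = 0
# resets S*dS to 1; non-finite estimates are flagged, never emitted as
# sentinel numbers.

#' Construct a codon alignment
#'
#' A codon alignment is a pair of equal-length, gap-free, in-frame coding
#' sequences without ambiguous bases or internal stop codons.  It is the unit
#' of comparison for the rate estimators and the bootstrap selection test.
#'
#' @param seq_a,seq_b nucleotide strings (A/C/G/T), equal length, multiple of 3
#' @param gene_id identifier carried through to results
#' @return an object of class `codon_alignment` with elements `gene_id`,
#'   `seq_a`, `seq_b`, `n_codons`
#' @examples
#' codon_alignment("ATGAAA", "ATGAAG", "g1")
#' @export
codon_alignment <- function(seq_a, seq_b, gene_id = "gene") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stopf("codon_alignment: sequences differ in length (%d vs %d)",
          nchar(seq_a), nchar(seq_b))
  if (nchar(seq_a) %% 3L != 0L)
    stopf("codon_alignment: length %d is not a multiple of 3", nchar(seq_a))
  if (nchar(seq_a) < 6L)
    stopf("codon_alignment: need at least 2 codons")
  if (grepl("[^ACGT]", seq_a) || grepl("[^ACGT]", seq_b))
    stopf("codon_alignment: sequences must be gap-free A/C/G/T only")
  ia <- codon_index(seq_a); ib <- codon_index(seq_b)
  if (anyNA(ia) || anyNA(ib))
    stopf("codon_alignment: internal stop codon in input")
  structure(list(gene_id = gene_id, seq_a = seq_a, seq_b = seq_b,
                 n_codons = length(ia), .ia = ia, .ib = ib),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon alignment '%s': %d codons\n", x$gene_id, x$n_codons))
  invisible(x)
}

## distinct codon pairs and their multiplicities
aln_pairs <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  codes <- pair_codes(aln$.ia, aln$.ib)
  u <- sort(unique(codes))
  w <- tabulate(match(codes, u), nbins = length(u))
  list(i = ((u - 1L) %/% 61L) + 1L, j = ((u - 1L) %% 61L) + 1L,
       w = w, L = aln$n_codons)
}

jc_correct <- function(p) {
  d <- rep(NA_real_, length(p))
  ok <- !is.na(p) & (4 * p / 3) < 1
  d[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  d
}

jc_se <- function(p, n) {
  se <- rep(NA_real_, length(p))
  ok <- !is.na(p) & (4 * p / 3) < 1 & n > 0
  se[ok] <- sqrt(p[ok] * (1 - p[ok]) / n[ok]) / (1 - 4 * p[ok] / 3)
  se
}

## K80 distance from transition (P) and transversion (Q) proportions;
## returns NA when saturated.  Vectorized.
k80_dist <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  d <- rep(NA_real_, length(P))
  ok <- !is.na(a1) & !is.na(a2) & a1 > 0 & a2 > 0
  d[ok] <- -0.5 * log(a1[ok]) - 0.25 * log(a2[ok])
  d
}

k80_se <- function(P, Q, n) {
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  se <- rep(NA_real_, length(P))
  ok <- !is.na(a1) & !is.na(a2) & a1 > 0 & a2 > 0 & n > 0
  gP <- 1 / a1[ok]
  gQ <- 0.5 / a1[ok] + 0.5 / a2[ok]
  vP <- P[ok] * (1 - P[ok]) / n[ok]
  vQ <- Q[ok] * (1 - Q[ok]) / n[ok]
  cPQ <- -P[ok] * Q[ok] / n[ok]
  se[ok] <- sqrt(pmax(0, gP^2 * vP + gQ^2 * vQ + 2 * gP * gQ * cPQ))
  se
}

## K80 transition-distance (A = alpha*t) and transversion-distance (B = 2*beta*t)
## components, used for kappa estimation.
k80_components <- function(P, Q) {
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  if (is.na(a1) || is.na(a2) || a1 <= 0 || a2 <= 0)
    return(c(A = NA_real_, B = NA_real_))
  c(A = -0.5 * log(a1) + 0.25 * log(a2), B = -0.5 * log(a2))
}

## kappa from fourfold-degenerate and nondegenerate sites, K80-corrected and
## weighted by the number of sites in each class.  Falls back to 1 when the
## estimate degenerates (no usable variation).
estimate_kappa <- function(pr) {
  tabs <- codon_tables()
  ij <- cbind(pr$i, pr$j)
  l4 <- sum(pr$w * tabs$L4[ij]); p4 <- sum(pr$w * tabs$P4[ij])
  q4 <- sum(pr$w * tabs$Q4[ij])
  l0 <- sum(pr$w * tabs$L0[ij]); p0 <- sum(pr$w * tabs$P0[ij])
  q0 <- sum(pr$w * tabs$Q0[ij])
  comp4 <- if (l4 > 0) k80_components(p4 / l4, q4 / l4) else c(A = NA, B = NA)
  comp0 <- if (l0 > 0) k80_components(p0 / l0, q0 / l0) else c(A = NA, B = NA)
  w4 <- if (is.na(comp4[1])) 0 else l4
  w0 <- if (is.na(comp0[1])) 0 else l0
  if (w4 + w0 == 0)
    return(list(kappa = 1, fallback = TRUE))
  A <- (w4 * ifelse(is.na(comp4[1]), 0, comp4[1]) +
        w0 * ifelse(is.na(comp0[1]), 0, comp0[1])) / (w4 + w0)
  B <- (w4 * ifelse(is.na(comp4[2]), 0, comp4[2]) +
        w0 * ifelse(is.na(comp0[2]), 0, comp0[2])) / (w4 + w0)
  if (!is.finite(A) || !is.finite(B) || B <= 0 || A <= 0)
    return(list(kappa = 1, fallback = TRUE))
  list(kappa = 2 * A / B, fallback = FALSE)
}

## F3x4 codon frequencies over sense codons, from both sequences.
f3x4_frequencies <- function(pr) {
  tabs <- codon_tables()
  f <- matrix(0, 3L, 4L)
  for (p in 1:3) {
    for (nt in 1:4) {
      f[p, nt] <- sum(pr$w * ((tabs$ntidx[pr$i, p] == nt) +
                              (tabs$ntidx[pr$j, p] == nt)) / 2)
    }
    f[p, ] <- f[p, ] / sum(f[p, ])
  }
  pi <- f[1, tabs$ntidx[, 1]] * f[2, tabs$ntidx[, 2]] * f[3, tabs$ntidx[, 3]]
  pi / sum(pi)
}

## Per-codon synonymous site counts (length 61) under kappa and codon-usage
## weighting: at each codon position the fraction of mutational opportunity
## that is synonymous, with weight pi[target] * kappa^is_transition and stop
## codons inaccessible.
yn00_site_vector <- function(kappa, pi) {
  tabs <- codon_tables()
  cand <- tabs$cand
  wc <- pi[cand$tgt] * ifelse(cand$ts == 1L, kappa, 1)
  num <- rep(0, 183); den <- rep(0, 183)
  a <- rowsum(wc * cand$syn, cand$site)
  num[as.integer(rownames(a))] <- a[, 1]
  b <- rowsum(wc, cand$site)
  den[as.integer(rownames(b))] <- b[, 1]
  frac <- ifelse(den > 0, num / den, 0)
  rowSums(matrix(frac, 61L, 3L, byrow = TRUE))
}

new_pairwise_rates <- function(gene_id, method, L, S, N, Sd, Nd, dS, dN,
                               kappa, se_dS, se_dN, ts, tv, flags) {
  structure(list(gene_id = gene_id, method = method, n_codons = L,
                 S = S, N = N, Sd = Sd, Nd = Nd, dS = dS, dN = dN,
                 kappa = kappa, omega = NA_real_, t = NA_real_,
                 se_dS = se_dS, se_dN = se_dN,
                 ts_count = ts, tv_count = tv, flags = flags),
            class = "pairwise_rates")
}

#' @export
print.pairwise_rates <- function(x, ...) {
  cat(sprintf("pairwise rates [%s] '%s' (%d codons)\n", x$method, x$gene_id,
              x$n_codons))
  cat(sprintf("  S = %.2f  N = %.2f  Sd = %.3f  Nd = %.3f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  dS = %s  dN = %s  kappa = %s  omega = %s  t = %s\n",
              format(x$dS, digits = 4), format(x$dN, digits = 4),
              format(x$kappa, digits = 4), format(x$omega, digits = 4),
              format(x$t, digits = 4)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Nei-Gojobori (1986) pairwise rates
#'
#' Counts synonymous and nonsynonymous sites by codon degeneracy fractions
#' (equal weighting, mutations to stop codons excluded) and differences by
#' averaging over all equal-weight minimal pathways between observed codons
#' that avoid stop codons, then applies the Jukes-Cantor correction to the
#' proportions of differences.  The `saturated` flag is set when a proportion
#' admits no finite corrected estimate (4p/3 >= 1).
#'
#' @param aln a [codon_alignment()]
#' @return a `pairwise_rates` object (omega and t unset; see
#'   [apply_omega_rules()] and [divergence_t()])
#' @export
ng86_rates <- function(aln) {
  tabs <- codon_tables()
  pr <- aln_pairs(aln)
  ij <- cbind(pr$i, pr$j)
  S <- sum(pr$w * (tabs$svec[pr$i] + tabs$svec[pr$j]) / 2)
  N <- 3 * pr$L - S
  Sd <- sum(pr$w * tabs$SD[ij]); Nd <- sum(pr$w * tabs$ND[ij])
  pS <- Sd / S; pN <- Nd / N
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  flags <- character()
  if (Sd == 0 && Nd == 0) flags <- c(flags, "identical")
  if (is.na(dS) || is.na(dN)) flags <- c(flags, "saturated")
  new_pairwise_rates(aln$gene_id, "ng86", pr$L, S, N, Sd, Nd, dS, dN,
                     kappa = NA_real_,
                     se_dS = jc_se(pS, S), se_dN = jc_se(pN, N),
                     ts = sum(pr$w * tabs$TSdir[ij]),
                     tv = sum(pr$w * tabs$TVdir[ij]), flags = flags)
}

#' Yang-Nielsen (2000) style pairwise rates
#'
#' Counting method accounting for the transition/transversion rate ratio and
#' codon usage.  Codon frequencies are estimated from the aligned pair by
#' position-specific nucleotide frequencies (F3x4); kappa is estimated from
#' fourfold-degenerate and nondegenerate sites (K80-corrected, site-number
#' weighted); synonymous/nonsynonymous site counts weight each mutational
#' opportunity by kappa and the target-codon frequency; differences are
#' counted with equal pathway weighting and the distance correction is applied
#' per site class (K80 on the transition/transversion partition of synonymous
#' and of nonsynonymous differences).  When kappa estimation degenerates
#' (no usable fourfold/nondegenerate variation) kappa falls back to 1 and the
#' `kappa_fallback` flag is recorded.
#'
#' @inheritParams ng86_rates
#' @return a `pairwise_rates` object with `kappa` reported
#' @export
yn00_rates <- function(aln) {
  tabs <- codon_tables()
  pr <- aln_pairs(aln)
  ij <- cbind(pr$i, pr$j)
  kap <- estimate_kappa(pr)
  pi <- f3x4_frequencies(pr)
  s61 <- yn00_site_vector(kap$kappa, pi)
  S <- sum(pr$w * (s61[pr$i] + s61[pr$j]) / 2)
  N <- 3 * pr$L - S
  Sdts <- sum(pr$w * tabs$SDts[ij]); Sdtv <- sum(pr$w * tabs$SDtv[ij])
  Ndts <- sum(pr$w * tabs$NDts[ij]); Ndtv <- sum(pr$w * tabs$NDtv[ij])
  Sd <- Sdts + Sdtv; Nd <- Ndts + Ndtv
  dS <- k80_dist(Sdts / S, Sdtv / S)
  dN <- k80_dist(Ndts / N, Ndtv / N)
  flags <- character()
  if (Sd == 0 && Nd == 0) flags <- c(flags, "identical")
  if (kap$fallback) flags <- c(flags, "kappa_fallback")
  if (is.na(dS) || is.na(dN)) flags <- c(flags, "saturated")
  new_pairwise_rates(aln$gene_id, "yn00", pr$L, S, N, Sd, Nd, dS, dN,
                     kappa = kap$kappa,
                     se_dS = k80_se(Sdts / S, Sdtv / S, S),
                     se_dN = k80_se(Ndts / N, Ndtv / N, N),
                     ts = sum(pr$w * tabs$TSdir[ij]),
                     tv = sum(pr$w * tabs$TVdir[ij]), flags = flags)
}

## core omega edge rules, vectorized over parallel vectors
omega_rules_core <- function(dN, dS, S) {
  n <- length(dN)
  omega <- rep(NA_real_, n)
  dS_out <- dS
  flag <- vector("list", n)
  for (k in seq_len(n)) {
    f <- character()
    if (is.na(dN[k]) || is.na(dS[k])) {
      f <- "infinite_filtered"
    } else if (dN[k] == 0 && dS[k] == 0) {
      omega[k] <- 0; f <- "identical"
    } else if (dN[k] > 0 && dS[k] == 0) {
      dS_out[k] <- 1 / S[k]          # S * dS reset to 1
      omega[k] <- dN[k] * S[k]
      f <- "dS_zero_reset"
    } else if (dN[k] == 0) {
      omega[k] <- 0
    } else {
      omega[k] <- dN[k] / dS[k]
    }
    flag[[k]] <- f
  }
  list(omega = omega, dS = dS_out, flags = flag)
}

#' Apply the omega edge rules
#'
#' Finalizes dN/dS with the scan's conventions for degenerate estimates:
#' when both dN and dS are null, omega is reset to zero (`identical` flag);
#' when dN > 0 but dS = 0, S*dS is reset to 1 (i.e. dS := 1/S) so that
#' omega = dN*S (`dS_zero_reset` flag); non-finite (saturated) estimates are
#' filtered and flagged (`infinite_filtered`) instead of being written as
#' sentinel values.
#'
#' @param x a `pairwise_rates` object or a data frame with columns
#'   `dN`, `dS`, `S` (and optionally `flags`)
#' @return the input with `omega` set, `dS` possibly adjusted, flags extended
#' @export
apply_omega_rules <- function(x) {
  if (inherits(x, "pairwise_rates")) {
    res <- omega_rules_core(x$dN, x$dS, x$S)
    x$omega <- res$omega
    x$dS <- res$dS
    x$flags <- unique(c(x$flags, res$flags[[1]]))
    return(x)
  }
  stopifnot(is.data.frame(x), all(c("dN", "dS", "S") %in% names(x)))
  res <- omega_rules_core(x$dN, x$dS, x$S)
  x$omega <- res$omega
  x$dS <- res$dS
  newf <- vapply(res$flags, paste, character(1), collapse = ",")
  if (!is.null(x$flags)) {
    x$flags <- ifelse(newf == "", x$flags,
                      ifelse(x$flags == "", newf, paste(x$flags, newf, sep = ",")))
    x$flags <- vapply(strsplit(x$flags, ","),
                      function(f) paste(unique(f[f != ""]), collapse = ","),
                      character(1))
  } else {
    x$flags <- newf
  }
  x
}

#' Divergence in substitutions per codon
#'
#' t = 3 (S dS + N dN) / (S + N), the expected number of nucleotide
#' substitutions per codon implied by the estimated per-site rates.  Saturated
#' inputs (non-finite dS or dN) yield NA with the `saturated` flag.
#'
#' @param x a `pairwise_rates` object or data frame with `S`, `N`, `dS`, `dN`
#' @return input with `t` set
#' @export
divergence_t <- function(x) {
  if (inherits(x, "pairwise_rates")) {
    x$t <- if (is.na(x$dS) || is.na(x$dN)) NA_real_ else
      3 * (x$S * x$dS + x$N * x$dN) / (x$S + x$N)
    return(x)
  }
  stopifnot(is.data.frame(x), all(c("S", "N", "dS", "dN") %in% names(x)))
  x$t <- ifelse(is.na(x$dS) | is.na(x$dN), NA_real_,
                3 * (x$S * x$dS + x$N * x$dN) / (x$S + x$N))
  x
}

#' Transition and transversion difference counts
#'
#' Site-by-site tally of mismatched nucleotide positions into transitions
#' (A<->G, C<->T) and transversions (all purine<->pyrimidine changes), with
#' per-nucleotide-site rates.
#'
#' @inheritParams ng86_rates
#' @return list with `ts_count`, `tv_count`, `ts_rate`, `tv_rate`
#' @export
ts_tv_counts <- function(aln) {
  tabs <- codon_tables()
  pr <- aln_pairs(aln)
  ij <- cbind(pr$i, pr$j)
  ts <- sum(pr$w * tabs$TSdir[ij]); tv <- sum(pr$w * tabs$TVdir[ij])
  list(ts_count = ts, tv_count = tv,
       ts_rate = ts / (3 * pr$L), tv_rate = tv / (3 * pr$L))
}

#' Estimate rates for a batch of codon alignments
#'
#' Runs the chosen counting method over a list of alignments, applies the
#' omega edge rules and the per-codon divergence, and returns one row per
#' gene.
#'
#' @param alignments list of [codon_alignment()] objects
#' @param method `"yn00"` (default) or `"ng86"`
#' @return data frame with columns gene_id, n_codons, S, N, Sd, Nd, dS, dN,
#'   kappa, omega, t, se_dS, se_dN, ts, tv, flags
#' @export
estimate_rates <- function(alignments, method = c("yn00", "ng86")) {
  method <- match.arg(method)
  fn <- if (method == "yn00") yn00_rates else ng86_rates
  rows <- lapply(alignments, function(a) {
    r <- fn(a)
    data.frame(gene_id = r$gene_id, n_codons = r$n_codons, S = r$S, N = r$N,
               Sd = r$Sd, Nd = r$Nd, dS = r$dS, dN = r$dN, kappa = r$kappa,
               se_dS = r$se_dS, se_dN = r$se_dN,
               ts = r$ts_count, tv = r$tv_count,
               flags = paste(r$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- apply_omega_rules(out)
  out <- divergence_t(out)
  out
}
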