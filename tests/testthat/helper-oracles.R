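# Independent oracles used by the tests.  These deliberately re-derive the
# expected quantities by brute force (recursive enumeration, literal
# definitions) without touching the package's lookup tables.

.GC <- Biostrings::GENETIC_CODE

## all permutations of a vector, by recursion
perm_all <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perm_all(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

## exhaustive pathway enumeration for one codon pair: average synonymous and
## nonsynonymous step counts over all orderings of the differing positions,
## excluding orderings that pass through a stop codon (all orderings if none
## avoids stops)
oracle_pair_diffs <- function(c1, c2) {
  x <- strsplit(c1, "")[[1]]; y <- strsplit(c2, "")[[1]]
  pos <- which(x != y)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  acc <- matrix(0, 0, 3)
  for (pth in perm_all(pos)) {
    cur <- x; sd <- nd <- 0; valid <- TRUE
    for (p in pth) {
      nxt <- cur; nxt[p] <- y[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (.GC[[to]] == "*") valid <- FALSE
      if (.GC[[from]] == .GC[[to]] && .GC[[to]] != "*") sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    acc <- rbind(acc, c(sd, nd, valid))
  }
  use <- if (any(acc[, 3] == 1)) acc[acc[, 3] == 1, , drop = FALSE] else acc
  c(sd = mean(use[, 1]), nd = mean(use[, 2]))
}

## total pathway-averaged differences over an alignment
oracle_total_diffs <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  tot <- c(sd = 0, nd = 0)
  for (k in seq_along(ca)) tot <- tot + oracle_pair_diffs(ca[k], cb[k])
  tot
}

## literal Benjamini-Hochberg step-up: q(i) = min over j >= i (sorted order)
## of min(1, p(j) * m / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) min(1, p[o[j]] * m / j), numeric(1))
    q[o[i]] <- min(cand)
  }
  q
}

## ordinary least squares via the normal equations
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

## all stop-bounded codon runs (in codons) across the six frames of a
## sequence: independent scan used for the ORF-length property
oracle_orf_runs <- function(seq) {
  runs <- integer()
  for (s in c(seq, divscan:::revcomp(seq))) {
    for (off in 0:2) {
      n <- (nchar(s) - off) %/% 3L
      if (n < 1L) next
      cod <- substring(s, off + 3 * seq_len(n) - 2, off + 3 * seq_len(n))
      aa <- unname(.GC[cod])
      stops <- which(aa == "*")
      if (!length(stops)) next
      bounds <- c(0L, stops, n + 1L)
      for (k in seq_len(length(bounds) - 1L)) {
        len <- bounds[k + 1L] - bounds[k] - 1L
        bounded <- (bounds[k] %in% stops) || (bounds[k + 1L] %in% stops)
        if (len > 0L && bounded) runs <- c(runs, len)
      }
    }
  }
  runs
}
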