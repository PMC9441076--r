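# Precomputed codon-level lookup tables shared by the rate estimators, the
# bootstrap and the sequence simulator.  Everything is derived from the
# universal genetic code once per session and cached in a package environment:
# pathway-averaged difference counts (Nei-Gojobori style, equal pathway
# weighting, pathways through stop codons excluded), per-codon synonymous site
# fractions, degeneracy classes used for kappa estimation, and the
# single-nucleotide neighbor graph over sense codons used by the simulator.

.divscan_cache <- new.env(parent = emptyenv())

NTS <- c("T", "C", "A", "G")
.purine <- c(T = FALSE, C = FALSE, A = TRUE, G = TRUE)

is_transition <- function(a, b) .purine[a] == .purine[b]

#' Codon lookup tables (internal)
#'
#' Builds (once) and returns the package's codon tables: sense codon list,
#' amino-acid translations, Nei-Gojobori pathway-averaged difference matrices
#' split by synonymous/nonsynonymous and transition/transversion, direct
#' per-site transition/transversion tallies, degeneracy classes and the
#' fourfold/nondegenerate site tallies used for kappa estimation, the
#' mutation-candidate table used for Yang-Nielsen site counting, and the sense
#' codon neighbor graph for the simulator.
#'
#' @return an environment-cached list of lookup tables
#' @keywords internal
codon_tables <- function() {
  if (!is.null(.divscan_cache$tables)) return(.divscan_cache$tables)

  code <- Biostrings::GENETIC_CODE  # universal code, names are DNA codons
  g <- expand.grid(p3 = NTS, p2 = NTS, p1 = NTS, stringsAsFactors = FALSE)
  codons64 <- paste0(g$p1, g$p2, g$p3)
  aa64 <- unname(code[codons64])
  sense <- codons64[aa64 != "*"]
  n <- length(sense)                     # 61
  aa <- unname(code[sense])
  idx64 <- setNames(rep(NA_integer_, 64L), codons64)
  idx64[sense] <- seq_len(n)
  cmat <- do.call(rbind, strsplit(sense, ""))  # 61 x 3 characters

  is_stop <- function(cod) code[cod] == "*"

  ## --- per-codon synonymous site fractions, equal weighting (NG86) --------
  svec <- numeric(n)
  deg <- matrix(0L, n, 3L)  # degeneracy class per position: 0, 2 or 4
  for (i in seq_len(n)) {
    for (p in 1:3) {
      tgt <- setdiff(NTS, cmat[i, p])
      newcod <- vapply(tgt, function(nt) {
        ch <- cmat[i, ]; ch[p] <- nt; paste(ch, collapse = "")
      }, character(1))
      syn_all <- code[newcod] == aa[i]          # change to stop is nonsyn
      nsyn <- sum(syn_all)
      deg[i, p] <- if (nsyn == 3L) 4L else if (nsyn == 0L) 0L else 2L
      keep <- !is_stop(newcod)
      if (any(keep)) svec[i] <- svec[i] + sum(syn_all[keep]) / sum(keep)
    }
  }

  ## --- pathway-averaged difference counts ---------------------------------
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  zero <- matrix(0, n, n)
  SDts <- zero; SDtv <- zero; NDts <- zero; NDtv <- zero
  TSdir <- zero; TVdir <- zero
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dpos <- which(cmat[i, ] != cmat[j, ])
      ## direct site-by-site transition/transversion tally
      ts <- sum(is_transition(cmat[i, dpos], cmat[j, dpos]))
      TSdir[i, j] <- ts
      TVdir[i, j] <- length(dpos) - ts
      if (j < i) next  # pathway counts are symmetric, fill mirror below
      ords <- lapply(perms[[as.character(length(dpos))]],
                     function(o) dpos[o])
      acc <- matrix(0, length(ords), 4L)  # sd_ts sd_tv nd_ts nd_tv
      ok <- logical(length(ords))
      for (k in seq_along(ords)) {
        cur <- cmat[i, ]
        valid <- TRUE
        for (p in ords[[k]]) {
          nxt <- cur; nxt[p] <- cmat[j, p]
          c_from <- paste(cur, collapse = ""); c_to <- paste(nxt, collapse = "")
          if (is_stop(c_to)) valid <- FALSE
          syn <- code[c_from] == code[c_to] && code[c_to] != "*"
          tsx <- is_transition(cur[p], nxt[p])
          col <- if (syn) (if (tsx) 1L else 2L) else (if (tsx) 3L else 4L)
          acc[k, col] <- acc[k, col] + 1
          cur <- nxt
        }
        ok[k] <- valid
      }
      use <- if (any(ok)) acc[ok, , drop = FALSE] else acc
      m <- colMeans(use)
      SDts[i, j] <- SDts[j, i] <- m[1]
      SDtv[i, j] <- SDtv[j, i] <- m[2]
      NDts[i, j] <- NDts[j, i] <- m[3]
      NDtv[i, j] <- NDtv[j, i] <- m[4]
    }
  }

  ## --- tallies for kappa estimation (fourfold / nondegenerate sites) ------
  L4 <- zero; P4 <- zero; Q4 <- zero
  L0 <- zero; P0 <- zero; Q0 <- zero
  for (i in seq_len(n)) {
    for (j in i:n) {
      l4 <- p4 <- q4 <- l0 <- p0 <- q0 <- 0L
      for (p in 1:3) {
        if (deg[i, p] != deg[j, p]) next
        diffp <- cmat[i, p] != cmat[j, p]
        tsx <- diffp && is_transition(cmat[i, p], cmat[j, p])
        if (deg[i, p] == 4L) {
          l4 <- l4 + 1L
          if (diffp) { if (tsx) p4 <- p4 + 1L else q4 <- q4 + 1L }
        } else if (deg[i, p] == 0L) {
          l0 <- l0 + 1L
          if (diffp) { if (tsx) p0 <- p0 + 1L else q0 <- q0 + 1L }
        }
      }
      L4[i, j] <- L4[j, i] <- l4; P4[i, j] <- P4[j, i] <- p4
      Q4[i, j] <- Q4[j, i] <- q4; L0[i, j] <- L0[j, i] <- l0
      P0[i, j] <- P0[j, i] <- p0; Q0[i, j] <- Q0[j, i] <- q0
    }
  }

  ## --- mutation-candidate table (all non-stop single-nt changes) ----------
  rows <- list()
  for (i in seq_len(n)) {
    for (p in 1:3) {
      for (nt in setdiff(NTS, cmat[i, p])) {
        ch <- cmat[i, ]; ch[p] <- nt
        cod <- paste(ch, collapse = "")
        if (is_stop(cod)) next
        rows[[length(rows) + 1L]] <- data.frame(
          cod = i, pos = p, tgt = idx64[[cod]],
          syn = as.integer(code[cod] == aa[i]),
          ts = as.integer(is_transition(cmat[i, p], nt))
        )
      }
    }
  }
  cand <- do.call(rbind, rows)
  cand$site <- (cand$cod - 1L) * 3L + cand$pos   # grouping id, 1..183

  ## nucleotide index (1..4 over NTS) per codon position, for F3x4 tallies
  ntidx <- matrix(match(cmat, NTS), n, 3L)

  tabs <- list(
    codons = sense, aa = aa, idx64 = idx64, cmat = cmat, ntidx = ntidx,
    svec = svec, deg = deg,
    SDts = SDts, SDtv = SDtv, NDts = NDts, NDtv = NDtv,
    SD = SDts + SDtv, ND = NDts + NDtv,
    TSdir = TSdir, TVdir = TVdir,
    L4 = L4, P4 = P4, Q4 = Q4, L0 = L0, P0 = P0, Q0 = Q0,
    cand = cand
  )
  .divscan_cache$tables <- tabs
  tabs
}

## Map a pair of equal-length codon index vectors to pair codes (i-1)*61+j.
pair_codes <- function(ia, ib) (ia - 1L) * 61L + ib

codon_index <- function(seq) {
  tabs <- codon_tables()
  idx <- tabs$idx64[split_codons(toupper(seq))]
  unname(idx)
}
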