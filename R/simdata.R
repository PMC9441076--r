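# Synthetic-data generator.
#
# Emulates the inputs of the divergence scan without any external data: a
# reference genome layout (scaffold lengths, gene loci), two transcript
# collections that diverged from common ancestral coding sequences under a
# codon-level substitution process with per-gene divergence t (substitutions
# per codon), selection ratio omega and transition/transversion ratio kappa,
# genome-anchored tabular hit records realizing the positional paralog
# categories (scaffold paralogs, tandem duplicates, allelic variants,
# intron-split anchors), a protein-annotation table, and a truth table for
# every gene.
#
# Two named regimes parameterize the marginal structure of an early and a
# late stage of speciation: "early" has a majority of zero-divergence genes
# with scattered weakly divergent ones (plus one configurable island of
# divergence), "late" has near-universal high divergence clustered along the
# whole genome.

#' Simulation configuration
#'
#' @param regime `"early"`, `"late"` or `"custom"`.  The named regimes fill
#'   defaults reproducing the marginal divergence structure of an early
#'   (allopatric populations) and a late (sister species) stage of
#'   speciation; `"custom"` requires `frac_zero_divergence` and
#'   `t_distribution`.
#' @param n_scaffolds number of scaffolds
#' @param scaffold_length_bp scaffold length in bp: a scalar or a
#'   `c(min, max)` range sampled uniformly
#' @param genes_per_scaffold genes per scaffold: scalar or `c(min, max)`
#' @param gene_length_codons coding length of every gene, in codons
#' @param frac_zero_divergence proportion of genes with true t = 0
#' @param t_distribution function(n) drawing per-gene true divergence
#'   (substitutions per codon) for non-zero-divergence genes
#' @param omega_distribution function(n) drawing per-gene true dN/dS
#' @param kappa transition/transversion rate ratio of the mutation process
#' @param island_spec list of `c(scaffold, first_gene, run_length, t_level)`
#'   placing runs of consecutive divergent genes ("islands") exactly
#' @param complication_rates named proportions for
#'   `scaffold_paralog`, `tandem_paralog`, `allelic`, `intron_split`
#'   (mutually exclusive per gene, sum <= 1)
#' @param annotated_frac fraction of transcripts given a strong
#'   protein-annotation hit
#' @param seed integer seed; every quantity drawn by the generator is a
#'   deterministic function of the configuration and this seed
#' @return an object of class `sim_config`
#' @export
sim_config <- function(regime = c("early", "late", "custom"),
                       n_scaffolds = NULL, scaffold_length_bp = NULL,
                       genes_per_scaffold = NULL, gene_length_codons = 300L,
                       frac_zero_divergence = NULL, t_distribution = NULL,
                       omega_distribution = NULL, kappa = 2,
                       island_spec = NULL, complication_rates = NULL,
                       annotated_frac = 0.7, seed = 1L) {
  regime <- match.arg(regime)
  defaults <- switch(regime,
    early = list(
      n_scaffolds = 24L, scaffold_length_bp = 400000L,
      genes_per_scaffold = 21L, frac_zero_divergence = 0.58,
      # gamma with mode ~0.025 subs/codon and overall mean t ~0.016,
      # reproducing a negative-exponential-like tail of outliers
      t_distribution = function(n) rgamma(n, shape = 2.5, scale = 0.0152),
      omega_distribution = function(n) {
        cls <- sample.int(4L, n, replace = TRUE,
                          prob = c(0.55, 0.36, 0.03, 0.06))
        out <- numeric(n)
        out[cls == 1L] <- rgamma(sum(cls == 1L), shape = 2, scale = 0.06)
        out[cls == 2L] <- runif(sum(cls == 2L), 0.25, 0.5)
        out[cls == 3L] <- runif(sum(cls == 3L), 0.5, 1)
        out[cls == 4L] <- runif(sum(cls == 4L), 1, 2)
        out
      },
      island_spec = list(c(1L, 5L, 3L, 0.5))
    ),
    late = list(
      n_scaffolds = 24L, scaffold_length_bp = 400000L,
      genes_per_scaffold = 21L, frac_zero_divergence = 0.004,
      # near-universal high divergence: ~96% of genes above t = 0.75
      t_distribution = function(n) {
        cls <- runif(n)
        out <- pmax(0, rnorm(n, mean = 1.1, sd = 0.15))
        mid <- cls < 0.031  # 3% of the non-identical mass in (0.25, 0.75)
        out[mid] <- runif(sum(mid), 0.25, 0.75)
        out
      },
      omega_distribution = function(n) {
        cls <- sample.int(4L, n, replace = TRUE,
                          prob = c(0.30, 0.53, 0.15, 0.02))
        out <- numeric(n)
        out[cls == 1L] <- runif(sum(cls == 1L), 0, 0.02)
        out[cls == 2L] <- rgamma(sum(cls == 2L), shape = 2, scale = 0.05)
        out[cls == 3L] <- runif(sum(cls == 3L), 0.4, 0.9)
        out[cls == 4L] <- runif(sum(cls == 4L), 1, 1.6)
        out
      },
      island_spec = NULL
    ),
    custom = list(n_scaffolds = 10L, scaffold_length_bp = 400000L,
                  genes_per_scaffold = 10L, frac_zero_divergence = NULL,
                  t_distribution = NULL, omega_distribution = NULL,
                  island_spec = NULL)
  )
  cfg <- list(
    regime = regime,
    n_scaffolds = n_scaffolds %||% defaults$n_scaffolds,
    scaffold_length_bp = scaffold_length_bp %||% defaults$scaffold_length_bp,
    genes_per_scaffold = genes_per_scaffold %||% defaults$genes_per_scaffold,
    gene_length_codons = as.integer(gene_length_codons),
    frac_zero_divergence = frac_zero_divergence %||% defaults$frac_zero_divergence,
    t_distribution = t_distribution %||% defaults$t_distribution,
    omega_distribution = omega_distribution %||%
      defaults$omega_distribution %||% (function(n) rep(0.2, n)),
    kappa = kappa,
    island_spec = if (missing(island_spec)) defaults$island_spec else island_spec,
    complication_rates = complication_rates %||%
      c(scaffold_paralog = 0.02, tandem_paralog = 0.02, allelic = 0.02,
        intron_split = 0.10),
    annotated_frac = annotated_frac,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_scaffolds)) stopf("n_scaffolds must be a count")
  if (cfg$gene_length_codons < 2L) stopf("gene_length_codons must be >= 2")
  if (is.null(cfg$frac_zero_divergence) || !is_prop(cfg$frac_zero_divergence))
    stopf("frac_zero_divergence must be a proportion in [0, 1]")
  if (!is.function(cfg$t_distribution))
    stopf("t_distribution must be a function(n)")
  cr <- cfg$complication_rates
  need <- c("scaffold_paralog", "tandem_paralog", "allelic", "intron_split")
  if (!all(need %in% names(cr)) || !is_prop(unname(cr[need])))
    stopf("complication_rates must name proportions for %s",
          paste(need, collapse = ", "))
  if (sum(cr[need]) > 1) stopf("complication rates must sum to <= 1")
  if (!is_prop(cfg$annotated_frac)) stopf("annotated_frac must be in [0, 1]")
  if (cfg$kappa < 0) stopf("kappa must be >= 0")
  ngmax <- max(cfg$genes_per_scaffold)
  for (isl in cfg$island_spec %||% list()) {
    if (length(isl) != 4L)
      stopf("island_spec entries must be c(scaffold, first_gene, run, t)")
    if (isl[1] > cfg$n_scaffolds)
      stopf("island_spec: scaffold %d exceeds n_scaffolds", isl[1])
    if (isl[2] + isl[3] - 1 > ngmax)
      stopf("island_spec: island run exceeds genes_per_scaffold")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: regime=%s, %d scaffolds, %s genes/scaffold, %d codons/gene, seed=%d\n",
              x$regime, x$n_scaffolds,
              paste(x$genes_per_scaffold, collapse = "-"),
              x$gene_length_codons, x$seed))
  invisible(x)
}

draw_scalar_or_range <- function(x, n) {
  if (length(x) == 1L) rep(as.integer(x), n)
  else as.integer(round(runif(n, x[1], x[2])))
}

#' Random stop-free coding sequence
#'
#' Uniform draws over the 61 sense codons of the universal code.
#'
#' @param n_codons number of codons
#' @return nucleotide string of length `3 * n_codons`
#' @export
random_coding_sequence <- function(n_codons) {
  tabs <- codon_tables()
  paste(tabs$codons[sample.int(61L, n_codons, replace = TRUE)], collapse = "")
}

## Build the simulator's per-codon neighbor structure for a given (omega,
## kappa): single-nucleotide steps among sense codons, rate kappa for
## transitions, multiplied by omega for nonsynonymous changes, stop codons
## inaccessible; normalized so that the mean exit rate over a uniform codon
## distribution is 1 (one expected substitution per codon per unit time).
sim_process <- function(omega, kappa) {
  tabs <- codon_tables()
  cand <- tabs$cand
  rate <- ifelse(cand$ts == 1L, kappa, 1) * ifelse(cand$syn == 1L, 1, omega)
  nbr <- matrix(1L, 61L, 9L)
  rmat <- matrix(0, 61L, 9L)
  cnt <- integer(61L)
  for (k in seq_len(nrow(cand))) {
    c0 <- cand$cod[k]
    cnt[c0] <- cnt[c0] + 1L
    nbr[c0, cnt[c0]] <- cand$tgt[k]
    rmat[c0, cnt[c0]] <- rate[k]
  }
  exit <- rowSums(rmat)
  scale <- mean(exit)
  if (scale <= 0) stopf("degenerate substitution process (zero total rate)")
  exit <- exit / scale
  rmat <- rmat / scale
  cum <- t(apply(rmat, 1L, cumsum))
  cum <- cum / ifelse(exit > 0, exit, 1)   # normalized within row
  cum[exit == 0, ] <- 1                    # absorbing states never sampled
  cum[cbind(seq_len(61L), pmax(cnt, 1L))] <- 1  # guard rounding
  list(nbr = nbr, cum = cum, exit = exit)
}

## Vectorized Gillespie over codon sites: evolve each state for its own time.
evolve_states <- function(states, tau, proc) {
  idx <- which(proc$exit[states] > 0 & tau > 0)
  while (length(idx)) {
    r <- proc$exit[states[idx]]
    dt <- rexp(length(idx), r)
    hit <- dt < tau[idx]
    if (!any(hit)) break
    idx <- idx[hit]
    tau[idx] <- tau[idx] - dt[hit]
    s <- states[idx]
    u <- runif(length(idx))
    j <- rowSums(proc$cum[s, , drop = FALSE] < u) + 1L
    states[idx] <- proc$nbr[cbind(s, j)]
  }
  states
}

#' Evolve a pair of descendant coding sequences from an ancestor
#'
#' Continuous-time codon process with single-nucleotide steps: transitions at
#' rate proportional to kappa, nonsynonymous changes scaled by omega, changes
#' creating stop codons forbidden.  Rates are rescaled so that the expected
#' number of substitutions per codon per unit time is one (over a uniform
#' codon distribution), and each descendant evolves independently for t/2 so
#' that the total expected path length between the pair is t substitutions
#' per codon.
#'
#' @param ancestor_cds nucleotide string, length a multiple of 3, no internal
#'   stop codons
#' @param t total expected substitutions per codon between the descendants
#' @param omega nonsynonymous/synonymous rate ratio
#' @param kappa transition/transversion rate ratio
#' @param seed optional integer seed (uses the current RNG stream if NULL)
#' @return list with `seq_a`, `seq_b`
#' @export
evolve_codon_pair <- function(ancestor_cds, t, omega, kappa = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nchar(ancestor_cds) %% 3L != 0L)
    stopf("ancestor length %d is not a multiple of 3", nchar(ancestor_cds))
  anc <- codon_index(ancestor_cds)
  if (anyNA(anc)) stopf("ancestor contains an internal stop codon")
  if (t < 0) stopf("t must be >= 0")
  tabs <- codon_tables()
  if (t == 0)
    return(list(seq_a = ancestor_cds, seq_b = ancestor_cds))
  proc <- sim_process(omega, kappa)
  a <- evolve_states(anc, rep(t / 2, length(anc)), proc)
  b <- evolve_states(anc, rep(t / 2, length(anc)), proc)
  list(seq_a = paste(tabs$codons[a], collapse = ""),
       seq_b = paste(tabs$codons[b], collapse = ""))
}

#' Generate the per-gene truth table and scaffold layout
#'
#' Lays out non-overlapping gene loci along scaffolds, draws per-gene true
#' divergence and omega under the configured regime, places islands exactly
#' as requested, and assigns mutually exclusive complications (scaffold
#' paralog, tandem duplicate, allelic variant, intron-split anchor).
#' Deterministic for a fixed configuration and seed.
#'
#' @param config a [sim_config()]
#' @return object of class `truth_set`: list with `truth` (one row per gene:
#'   gene_id, scaffold_id, start_bp, end_bp, strand, true_t, true_omega,
#'   category_label, n_segments, complication_side), `scaffolds`
#'   (scaffold_id, length_bp), `segments` (per-segment anchor layout for
#'   intron-split genes) and the config
#' @export
make_truth_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_scaffolds
  slen <- draw_scalar_or_range(config$scaffold_length_bp, ns)
  ngen <- draw_scalar_or_range(config$genes_per_scaffold, ns)
  scf <- data.frame(scaffold_id = sprintf("scf%03d", seq_len(ns)),
                    length_bp = slen, stringsAsFactors = FALSE)
  glen_bp <- 3L * config$gene_length_codons
  rows <- list(); segrows <- list()
  gid <- 0L
  for (s in seq_len(ns)) {
    usable <- floor(0.85 * slen[s])
    slot <- usable %/% ngen[s]
    if (slot < glen_bp + 1000L)
      stopf("scaffold %d too short for %d genes of %d bp", s, ngen[s], glen_bp)
    for (i in seq_len(ngen[s])) {
      gid <- gid + 1L
      gene_id <- sprintf("g%05d", gid)
      start <- (i - 1L) * slot + 101L
      strand <- sample(c("+", "-"), 1L)
      ## complications, mutually exclusive
      cr <- config$complication_rates
      u <- runif(1)
      cuts <- cumsum(cr[c("scaffold_paralog", "tandem_paralog", "allelic",
                          "intron_split")])
      category <- if (u < cuts[1]) "scaffold_paralog"
        else if (u < cuts[2]) "tandem_paralog"
        else if (u < cuts[3]) "allelic"
        else if (u < cuts[4]) "exon" else "uniq"
      nseg <- 1L
      end <- start + glen_bp - 1L
      if (category == "exon") {
        nseg <- sample(2:3, 1L)
        introns <- sample(150:400, nseg - 1L, replace = TRUE)
        ## split the coding region at random interior points
        cutpts <- sort(sample(seq(30L, glen_bp - 30L, by = 3L), nseg - 1L))
        qb <- c(0L, cutpts, glen_bp)       # transcript offsets of segments
        spos <- start
        for (k in seq_len(nseg)) {
          seg_len <- qb[k + 1L] - qb[k]
          segrows[[length(segrows) + 1L]] <- data.frame(
            gene_id = gene_id, seg = k,
            q_off_start = qb[k], q_off_end = qb[k + 1L] - 1L,
            s_start = spos, s_end = spos + seg_len - 1L,
            stringsAsFactors = FALSE)
          spos <- spos + seg_len + if (k < nseg) introns[k] else 0L
        }
        end <- spos - 1L
      }
      tval <- if (runif(1) < config$frac_zero_divergence) 0 else
        config$t_distribution(1L)
      rows[[gid]] <- data.frame(
        gene_id = gene_id, scaffold_id = scf$scaffold_id[s],
        start_bp = start, end_bp = end, strand = strand,
        true_t = tval, true_omega = config$omega_distribution(1L),
        category_label = category, n_segments = nseg,
        complication_side = if (category %in%
          c("scaffold_paralog", "tandem_paralog", "allelic"))
          sample(c("A", "B"), 1L) else NA_character_,
        scaffold_index = s, gene_index = i,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  ## islands placed exactly as specified; island genes are kept uncomplicated
  ## so that the divergence run is visible to the downstream scan
  for (isl in config$island_spec %||% list()) {
    sel <- truth$scaffold_index == isl[1] &
      truth$gene_index >= isl[2] & truth$gene_index <= isl[2] + isl[3] - 1
    truth$true_t[sel] <- isl[4]
    changed <- sel & truth$category_label != "uniq"
    truth$category_label[sel] <- "uniq"
    truth$n_segments[sel] <- 1L
    truth$complication_side[sel] <- NA_character_
    truth$end_bp[sel] <- truth$start_bp[sel] + glen_bp - 1L
    if (any(changed)) {
      keepseg <- !vapply(segrows, function(d) d$gene_id[1] %in%
                           truth$gene_id[changed], logical(1))
      segrows <- segrows[keepseg]
    }
  }
  truth <- truth[order(truth$scaffold_index, truth$start_bp), ]
  rownames(truth) <- NULL
  segments <- if (length(segrows)) do.call(rbind, segrows) else
    data.frame(gene_id = character(), seg = integer(), q_off_start = integer(),
               q_off_end = integer(), s_start = integer(), s_end = integer())
  structure(list(truth = truth, scaffolds = scf, segments = segments,
                 config = config),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d genes on %d scaffolds (regime %s)\n",
              nrow(x$truth), nrow(x$scaffolds), x$config$regime))
  print(table(x$truth$category_label))
  invisible(x)
}

## transcript = 5' guard (in-frame stop just upstream) + CDS + 3' guard
.UTR5 <- "CGTAA"
.UTR3 <- "TAAGC"

hit_row <- function(qid, sid, qs, qe, ss, se, pident, evalue = 1e-180) {
  len <- qe - qs + 1L
  data.frame(qseqid = qid, sseqid = sid, pident = round(pident, 2),
             length = len, mismatch = round(len * (1 - pident / 100)),
             gapopen = 0L, qstart = qs, qend = qe, sstart = ss, send = se,
             evalue = evalue, bitscore = round(1.9 * len, 1),
             stringsAsFactors = FALSE)
}

## hit rows for one transcript over (possibly several) gene segments
anchor_hits <- function(qid, sid, segs, strand, q_base, pident) {
  n <- nrow(segs)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    qs <- q_base + segs$q_off_start[k]
    qe <- q_base + segs$q_off_end[k]
    if (strand == "+") {
      ss <- segs$s_start[k]; se <- segs$s_end[k]
    } else {
      ## transcript runs 3'->5' along the scaffold: first transcript segment
      ## maps to the highest scaffold coordinates
      kk <- n - k + 1L
      ss <- segs$s_end[kk]; se <- segs$s_start[kk]
    }
    out[[k]] <- hit_row(qid, sid, qs, qe, ss, se, pident)
  }
  do.call(rbind, out)
}

#' Write the synthetic input bundle to disk
#'
#' Evolves a transcript pair for every gene of the truth set and writes the
#' complete file bundle the pipeline consumes: two transcript FASTA files, a
#' scaffold length table, one tabular hit file per transcript collection
#' (12-column outfmt-6 dialect, including decoy rows above the e-value
#' cutoff), an annotation table, the truth table, the configuration and a
#' JSON manifest recording seed and config hash.
#'
#' @param ts a [make_truth_set()] result
#' @param dir output directory (created if missing)
#' @return invisibly, a named list of file paths plus the truth set
#' @export
emit_inputs <- function(ts, dir) {
  stopifnot(inherits(ts, "truth_set"))
  cfg <- ts$config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed((cfg$seed %% 1000003L) + 1L)
  truth <- ts$truth
  glen_bp <- 3L * cfg$gene_length_codons
  q_base <- nchar(.UTR5) + 1L    # transcript coordinate of the first CDS base

  seqs_a <- character(); seqs_b <- character()
  hits_a <- list(); hits_b <- list()
  ann <- list()
  ## per-scaffold cursor for placing paralog copies in the reserved tail
  tail_cursor <- setNames(floor(0.88 * ts$scaffolds$length_bp),
                          ts$scaffolds$scaffold_id)

  for (r in seq_len(nrow(truth))) {
    g <- truth[r, ]
    anc <- random_coding_sequence(cfg$gene_length_codons)
    pair <- evolve_codon_pair(anc, g$true_t, g$true_omega, cfg$kappa)
    ta <- paste0(.UTR5, pair$seq_a, .UTR3)
    tb <- paste0(.UTR5, pair$seq_b, .UTR3)
    ida <- paste0("A_", g$gene_id); idb <- paste0("B_", g$gene_id)
    seqs_a[ida] <- ta; seqs_b[idb] <- tb
    pident <- max(70, 100 * (1 - min(g$true_t, 1) / 3))

    segs <- if (g$category_label == "exon")
      ts$segments[ts$segments$gene_id == g$gene_id, ] else
      data.frame(q_off_start = 0L, q_off_end = glen_bp - 1L,
                 s_start = g$start_bp, s_end = g$end_bp)
    hits_a[[length(hits_a) + 1L]] <-
      anchor_hits(ida, g$scaffold_id, segs, g$strand, q_base, pident)
    hits_b[[length(hits_b) + 1L]] <-
      anchor_hits(idb, g$scaffold_id, segs, g$strand, q_base, pident)

    if (g$category_label %in% c("scaffold_paralog", "tandem_paralog")) {
      side <- g$complication_side
      qid <- if (side == "A") ida else idb
      if (g$category_label == "scaffold_paralog") {
        tgt <- ts$scaffolds$scaffold_id[
          (match(g$scaffold_id, ts$scaffolds$scaffold_id) %% nrow(ts$scaffolds)) + 1L]
      } else tgt <- g$scaffold_id
      ps <- tail_cursor[tgt]
      tail_cursor[tgt] <- tail_cursor[tgt] + glen_bp + 200L
      extra <- hit_row(qid, tgt, q_base, q_base + glen_bp - 1L,
                       ps, ps + glen_bp - 1L, pident - 2)
      if (side == "A") hits_a[[length(hits_a) + 1L]] <- extra
      else hits_b[[length(hits_b) + 1L]] <- extra
    }
    if (g$category_label == "allelic") {
      ## a second transcript of the same gene anchored at exactly the same
      ## position (extreme of the allelic definition)
      side <- g$complication_side
      alt_id <- paste0(if (side == "A") ida else idb, "_alt")
      if (side == "A") {
        seqs_a[alt_id] <- ta
        hits_a[[length(hits_a) + 1L]] <-
          anchor_hits(alt_id, g$scaffold_id, segs, g$strand, q_base, pident)
      } else {
        seqs_b[alt_id] <- tb
        hits_b[[length(hits_b) + 1L]] <-
          anchor_hits(alt_id, g$scaffold_id, segs, g$strand, q_base, pident)
      }
    }
    ## occasional redundant overlapping lower-score row (best-hit dedup work)
    if (g$category_label == "uniq" && r %% 37L == 0L) {
      dup <- hit_row(ida, g$scaffold_id, q_base + 30L, q_base + glen_bp - 1L,
                     if (g$strand == "+") g$start_bp + 30L else g$end_bp - 30L,
                     if (g$strand == "+") g$end_bp else g$start_bp,
                     pident - 5)
      dup$bitscore <- dup$bitscore * 0.6
      hits_a[[length(hits_a) + 1L]] <- dup
    }
    for (qid in c(ida, idb)) {
      u <- runif(1)
      if (u < cfg$annotated_frac) {
        ann[[length(ann) + 1L]] <- data.frame(
          query_id = qid, subject_id = sprintf("sp|P%05d|SYNT", r),
          evalue = 1e-30, bitscore = 250, stringsAsFactors = FALSE)
      } else if (u < cfg$annotated_frac + 0.1) {
        ## weak hit above the annotation cutoff
        ann[[length(ann) + 1L]] <- data.frame(
          query_id = qid, subject_id = sprintf("sp|Q%05d|WEAK", r),
          evalue = 1e-4, bitscore = 35, stringsAsFactors = FALSE)
      }
    }
  }

  ## decoy hit rows above the e-value cutoff: must be dropped on read
  decoys <- rbind(
    hit_row(names(seqs_a)[1], ts$scaffolds$scaffold_id[1], 1, 60, 1000, 1059,
            80, evalue = 1e-10),
    hit_row(names(seqs_b)[1], ts$scaffolds$scaffold_id[1], 1, 60, 2000, 2059,
            80, evalue = 1e-5))

  ha <- rbind(do.call(rbind, hits_a), decoys[1, ])
  hb <- rbind(do.call(rbind, hits_b), decoys[2, ])

  paths <- list(
    transcripts_a = file.path(dir, "transcripts_A.fasta"),
    transcripts_b = file.path(dir, "transcripts_B.fasta"),
    scaffolds = file.path(dir, "scaffolds.tsv"),
    hits_a = file.path(dir, "hits_A.tsv"),
    hits_b = file.path(dir, "hits_B.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml"),
    manifest = file.path(dir, "manifest.json"))

  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs_a),
                              paths$transcripts_a)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs_b),
                              paths$transcripts_b)
  write.table(ts$scaffolds, paths$scaffolds, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ha, paths$hits_a, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(hb, paths$hits_b, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  anndf <- if (length(ann)) do.call(rbind, ann) else
    data.frame(query_id = character(), subject_id = character(),
               evalue = numeric(), bitscore = numeric())
  write.table(anndf, paths$annotations, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg_plain <- cfg
  cfg_plain$t_distribution <- NULL
  cfg_plain$omega_distribution <- NULL
  cfg_plain$island_spec <- lapply(cfg$island_spec %||% list(), as.numeric)
  yaml::write_yaml(unclass(cfg_plain), paths$config)
  jsonlite::write_json(
    list(seed = cfg$seed, regime = cfg$regime,
         config_hash = config_hash(cfg_plain),
         n_genes = nrow(truth), n_scaffolds = nrow(ts$scaffolds)),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, list(truth_set = ts)))
}

#' Simulate a complete input bundle
#'
#' Convenience wrapper: [make_truth_set()] then [emit_inputs()].
#'
#' @inheritParams make_truth_set
#' @inheritParams emit_inputs
#' @return invisible list of paths plus the truth set
#' @export
simulate_bundle <- function(config, dir) {
  emit_inputs(make_truth_set(config), dir)
}
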