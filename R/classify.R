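# Positional ortholog/paralog classification.
#
# Transcripts are discriminated by their position and number of occurrences
# on the reference genome, from tabular alignment hits:
#   scaffold_paralog  hits on >= 2 distinct scaffolds
#   tandem_paralog    >= 2 non-overlapping loci on one scaffold
#   allelic           >= 2 transcripts whose loci reciprocally overlap
#   exon              single locus split into co-linear segments separated on
#                     the scaffold by more than the gap tolerance (introns)
#   uniq              single locus, single segment
# Only exon/uniq transcripts anchored at the same locus in both collections
# are paired as orthologs; paralog and allelic transcripts are excluded.

.hit_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a tabular alignment hit file
#'
#' Reads an outfmt-6-style tab-separated hit table (12 standard columns;
#' extended columns are tolerated and ignored), drops rows above the e-value
#' cutoff, reports malformed rows with their line numbers, and normalizes
#' strand: minus-strand rows (sstart > send) are stored with
#' `s_start < s_end` plus a strand flag.
#'
#' @param path file path
#' @param evalue_max retain only rows with evalue <= this cutoff
#'   (default 1e-15)
#' @return data frame of hit records with columns `qseqid`, `sseqid`,
#'   `pident`, `length`, `qstart`, `qend`, `s_start`, `s_end`, `strand`,
#'   `evalue`, `bitscore`
#' @export
read_hit_table <- function(path, evalue_max = 1e-15) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 12L)
    stopf("hit table %s: %d columns found, 12 required (missing: %s)",
          path, ncol(raw),
          paste(.hit_cols[seq(ncol(raw) + 1L, 12L)], collapse = ", "))
  raw <- raw[, 1:12]
  names(raw) <- .hit_cols
  num_cols <- setdiff(.hit_cols, c("qseqid", "sseqid"))
  suppressWarnings(for (cc in num_cols) raw[[cc]] <- as.numeric(raw[[cc]]))
  bad <- !complete.cases(raw[num_cols]) |
    raw$qstart < 1 | raw$sstart < 1 | raw$send < 1 |
    raw$qstart > raw$qend | raw$evalue < 0
  if (any(bad))
    warnf("hit table %s: dropping %d malformed row(s) at line(s) %s",
          path, sum(bad), paste(which(bad), collapse = ", "))
  h <- raw[!bad, , drop = FALSE]
  h <- h[h$evalue <= evalue_max, , drop = FALSE]
  h$strand <- ifelse(h$sstart <= h$send, "+", "-")
  h$s_start <- pmin(h$sstart, h$send)
  h$s_end <- pmax(h$sstart, h$send)
  h$sstart <- NULL; h$send <- NULL
  for (cc in c("length", "qstart", "qend", "s_start", "s_end"))
    h[[cc]] <- as.integer(h[[cc]])
  rownames(h) <- NULL
  h
}

## chain the hits of one query on one scaffold into loci: segments that are
## contiguous on the transcript (within +-transcript_gap_bp) and ordered,
## non-overlapping on the scaffold (strand-consistently) belong to one locus
chain_loci <- function(h, transcript_gap_bp = 10L) {
  h <- h[order(h$qstart, h$s_start), , drop = FALSE]
  locus <- integer(nrow(h))
  locus[1] <- 1L
  if (nrow(h) > 1L) for (k in 2:nrow(h)) {
    prev <- which(locus == locus[k - 1L])
    p <- prev[length(prev)]
    contig <- abs(h$qstart[k] - h$qend[p] - 1L) <= transcript_gap_bp
    same_strand <- h$strand[k] == h$strand[p]
    ord <- if (h$strand[k] == "+") h$s_start[k] > h$s_end[p]
           else h$s_end[k] < h$s_start[p]
    locus[k] <- if (contig && same_strand && ord) locus[k - 1L]
                else locus[k - 1L] + 1L
  }
  split(h, locus)
}

locus_span <- function(l) {
  c(start = min(l$s_start), end = max(l$s_end))
}

## merge redundant loci of one query (overlapping spans on the scaffold),
## keeping the chain with the best total bitscore: honors a best-hit-per-locus
## convention when input tables carry multiple rows per query
dedup_loci <- function(loci) {
  repeat {
    n <- length(loci)
    if (n < 2L) return(loci)
    spans <- t(vapply(loci, locus_span, numeric(2)))
    merged <- FALSE
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        if (overlap_len(spans[a, 1], spans[a, 2], spans[b, 1], spans[b, 2]) > 0) {
          keep <- if (sum(loci[[a]]$bitscore) >= sum(loci[[b]]$bitscore)) a else b
          loci <- loci[-setdiff(c(a, b), keep)]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(loci)
  }
}

classify_one <- function(h, gap_tolerance_bp, transcript_gap_bp) {
  if (length(unique(h$sseqid)) >= 2L) {
    return(data.frame(category = "scaffold_paralog", scaffold_id = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      strand = NA_character_, n_segments = NA_integer_,
                      q_start = NA_integer_, q_end = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  loci <- dedup_loci(chain_loci(h, transcript_gap_bp))
  if (length(loci) >= 2L) {
    return(data.frame(category = "tandem_paralog", scaffold_id = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      strand = NA_character_, n_segments = NA_integer_,
                      q_start = NA_integer_, q_end = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  l <- loci[[1]]
  l <- l[order(l$s_start), , drop = FALSE]
  ## merge segments separated on the scaffold by <= gap tolerance
  if (nrow(l) > 1L) {
    gaps <- l$s_start[-1L] - l$s_end[-nrow(l)] - 1L
    grp <- cumsum(c(1L, as.integer(gaps > gap_tolerance_bp)))
    nseg <- max(grp)
  } else nseg <- 1L
  data.frame(category = if (nseg >= 2L) "exon" else "uniq",
             scaffold_id = l$sseqid[1], start = min(l$s_start),
             end = max(l$s_end), strand = l$strand[1],
             n_segments = nseg,
             q_start = min(l$qstart), q_end = max(l$qend),
             stringsAsFactors = FALSE)
}

#' Classify transcripts by genomic position and occurrence
#'
#' Partitions every transcript with at least one retained hit into exactly
#' one of five categories (see module header).  Classification is invariant
#' to input row order; redundant overlapping hits of one query at one locus
#' are reduced to the best-bitscore chain.
#'
#' @param hits data frame from [read_hit_table()] (one transcript collection
#'   against one genome)
#' @param overlap_frac minimum reciprocal locus overlap for two transcripts
#'   to be called allelic (default 0.9)
#' @param gap_tolerance_bp scaffold gap between co-linear segments above
#'   which the segments are taken as separate exons (default 30)
#' @param transcript_gap_bp tolerated jitter for transcript-side contiguity
#'   of consecutive segments (default 10)
#' @return data frame with one row per transcript: `transcript_id`,
#'   `category`, `scaffold_id`, `start`, `end`, `strand`, `n_segments`,
#'   `q_start`, `q_end`
#' @export
classify_transcripts <- function(hits, overlap_frac = 0.9,
                                 gap_tolerance_bp = 30L,
                                 transcript_gap_bp = 10L) {
  if (nrow(hits) == 0L) {
    warnf("classify_transcripts: empty hit list")
    return(data.frame(transcript_id = character(), category = character(),
                      scaffold_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_segments = integer(), q_start = integer(),
                      q_end = integer(), stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$qseqid, hits$qstart, hits$s_start), , drop = FALSE]
  byq <- split(hits, hits$qseqid)
  out <- do.call(rbind, lapply(byq, classify_one,
                               gap_tolerance_bp = gap_tolerance_bp,
                               transcript_gap_bp = transcript_gap_bp))
  out <- cbind(data.frame(transcript_id = names(byq),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL

  ## allelic pass: anchored transcripts whose loci reciprocally overlap
  anch <- which(!is.na(out$scaffold_id))
  if (length(anch) > 1L) {
    key <- paste(out$scaffold_id[anch], out$strand[anch])
    for (grp in split(anch, key)) {
      if (length(grp) < 2L) next
      st <- out$start[grp]; en <- out$end[grp]
      ## union-find over reciprocal-overlap edges
      parent <- seq_along(grp)
      findp <- function(k) { while (parent[k] != k) k <- parent[k]; k }
      for (a in seq_along(grp)) for (b in seq_along(grp)) {
        if (a >= b) next
        ov <- overlap_len(st[a], en[a], st[b], en[b])
        if (ov / (en[a] - st[a] + 1) >= overlap_frac &&
            ov / (en[b] - st[b] + 1) >= overlap_frac)
          parent[findp(b)] <- findp(a)
      }
      roots <- vapply(seq_along(grp), findp, integer(1))
      for (rt in unique(roots)) {
        mem <- grp[roots == rt]
        if (length(mem) >= 2L) {
          out$category[mem] <- "allelic"
          out$n_segments[mem] <- 1L
        }
      }
    }
  }
  out
}

#' Pair orthologous transcripts from two classified collections
#'
#' Forms one ortholog pair per locus between transcripts of category
#' `exon`/`uniq` whose anchors lie on the same scaffold and strand and
#' reciprocally overlap at least `overlap_frac`.  Scaffold paralogs, tandem
#' paralogs and allelic transcripts never pair.  Loci with more than one
#' candidate partner on either side are dropped and logged as ambiguous
#' (attribute `"dropped"`).
#'
#' @param classified_a,classified_b outputs of [classify_transcripts()] for
#'   the two collections, against the same genome
#' @param overlap_frac minimum reciprocal anchor overlap (default 0.9)
#' @return data frame of anchored pairs: `gene_id`, `transcript_a`,
#'   `transcript_b`, `scaffold_id`, `start`, `end`, `strand`, `has_introns`
#'   plus per-side anchor columns used downstream; attribute `"dropped"`
#'   records ambiguous loci
#' @export
pair_orthologs <- function(classified_a, classified_b, overlap_frac = 0.9) {
  a <- classified_a[classified_a$category %in% c("uniq", "exon"), , drop = FALSE]
  b <- classified_b[classified_b$category %in% c("uniq", "exon"), , drop = FALSE]
  edges <- list()
  for (scf in intersect(unique(a$scaffold_id), unique(b$scaffold_id))) {
    for (strd in c("+", "-")) {
      ai <- which(a$scaffold_id == scf & a$strand == strd)
      bi <- which(b$scaffold_id == scf & b$strand == strd)
      for (x in ai) for (y in bi) {
        ov <- overlap_len(a$start[x], a$end[x], b$start[y], b$end[y])
        if (ov / (a$end[x] - a$start[x] + 1) >= overlap_frac &&
            ov / (b$end[y] - b$start[y] + 1) >= overlap_frac)
          edges[[length(edges) + 1L]] <- c(x, y)
      }
    }
  }
  if (!length(edges)) {
    out <- data.frame(gene_id = character(), transcript_a = character(),
                      transcript_b = character(), scaffold_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      has_introns = logical())
    attr(out, "dropped") <- data.frame(transcript_a = character(),
                                       transcript_b = character(),
                                       reason = character())
    return(out)
  }
  em <- do.call(rbind, edges)
  degA <- table(em[, 1]); degB <- table(em[, 2])
  ambiguous <- as.integer(names(degA)[degA > 1])
  ambiguousB <- as.integer(names(degB)[degB > 1])
  bad <- em[, 1] %in% ambiguous | em[, 2] %in% ambiguousB
  dropped <- data.frame(
    transcript_a = a$transcript_id[em[bad, 1]],
    transcript_b = b$transcript_id[em[bad, 2]],
    reason = rep("ambiguous", sum(bad)), stringsAsFactors = FALSE)
  em <- em[!bad, , drop = FALSE]
  if (nrow(em)) {
    x <- em[, 1]; y <- em[, 2]
    start <- pmax(a$start[x], b$start[y])
    end <- pmin(a$end[x], b$end[y])
    out <- data.frame(
      gene_id = sprintf("%s:%d-%d", a$scaffold_id[x], start, end),
      transcript_a = a$transcript_id[x], transcript_b = b$transcript_id[y],
      scaffold_id = a$scaffold_id[x], start = start, end = end,
      strand = a$strand[x],
      has_introns = a$category[x] == "exon" | b$category[y] == "exon",
      a_start = a$start[x], a_end = a$end[x],
      a_qstart = a$q_start[x], a_qend = a$q_end[x],
      a_nseg = a$n_segments[x],
      b_start = b$start[y], b_end = b$end[y],
      b_qstart = b$q_start[y], b_qend = b$q_end[y],
      b_nseg = b$n_segments[y],
      stringsAsFactors = FALSE)
    out <- out[order(out$scaffold_id, out$start), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(gene_id = character(), transcript_a = character(),
                      transcript_b = character(), scaffold_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      has_introns = logical())
  }
  attr(out, "dropped") <- dropped
  out
}
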