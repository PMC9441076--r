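# Coding-sequence extraction and codon-alignment construction.
#
# Each transcript is translated in the six reading frames and the longest
# stop-bounded run of codons is taken as its CDS (no start codon required;
# sequence ends may close a run, but runs from frames containing no stop
# codon at all are only a flagged fallback and are removed by the filter, so
# that untrustworthy "alternative frames without stop" never reach the rate
# estimators).  Quality filters remove CDSs with gaps or ambiguous bases,
# short CDSs, and (optionally) CDSs without a protein annotation.  Kept pairs
# are trimmed to their common in-frame overlap using the genome anchor
# coordinates to form gap-free codon alignments.

translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"     # codons containing N or gap characters
  aa
}

frame_runs <- function(seq, frame_label, offset, L_orig, minus) {
  n_cod <- (nchar(seq) - offset) %/% 3L
  if (n_cod < 1L) return(NULL)
  s <- substr(seq, offset + 1L, offset + 3L * n_cod)
  codons <- split_codons(s)
  aa <- translate_codons(codons)
  stops <- which(aa == "*")
  bounds <- c(0L, stops, n_cod + 1L)
  out <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    from <- bounds[k] + 1L; to <- bounds[k + 1L] - 1L
    if (to < from) next
    ## positions on the read strand (1-based nt)
    nt_from <- offset + 3L * (from - 1L) + 1L
    nt_to <- offset + 3L * to
    start <- if (minus) L_orig - nt_to + 1L else nt_from
    end <- if (minus) L_orig - nt_from + 1L else nt_to
    out[[length(out) + 1L]] <- list(
      frame = frame_label, n_codons = to - from + 1L,
      start = start, end = end,
      nt_seq = paste(codons[from:to], collapse = ""),
      aa_seq = paste(aa[from:to], collapse = ""),
      stop_bounded = (bounds[k] %in% stops) || (bounds[k + 1L] %in% stops),
      read_pos = nt_from)
  }
  out
}

#' Longest CDS across the six reading frames
#'
#' Translates the sequence in all six frames and returns the longest run of
#' codons bounded by stop codons (sequence ends may close one side of a run;
#' a start codon is not required).  Runs from frames that contain no stop
#' codon anywhere are returned only when no stop-bounded run exists, flagged
#' `no_stop`, and are dropped by [filter_cds()].  Ties are broken by frame
#' order (+1, +2, +3, -1, -2, -3), then leftmost position.
#'
#' @param nt_seq nucleotide string over A/C/G/T/N/-
#' @param transcript_id identifier carried along
#' @return object of class `cds_candidate`: `transcript_id`, `frame` (one of
#'   "+1","+2","+3","-1","-2","-3"), `start`/`end` (1-based coordinates on
#'   the input sequence), `n_codons`, `nt_seq`, `aa_seq`, and logical flags
#'   `has_N`, `has_gap`, `no_stop`; or `NULL` when every frame is wall-to-wall
#'   stop codons
#' @examples
#' longest_orf_6frame("ATGAAATAA")
#' @export
longest_orf_6frame <- function(nt_seq, transcript_id = "transcript") {
  nt_seq <- toupper(nt_seq)
  if (nchar(nt_seq) < 3L)
    stopf("sequence '%s' shorter than one codon", transcript_id)
  if (grepl("[^ACGTN-]", nt_seq))
    stopf("sequence '%s' contains characters outside A/C/G/T/N/-",
          transcript_id)
  L <- nchar(nt_seq)
  rc <- revcomp(nt_seq)
  cands <- list()
  for (f in 1:3) {
    cands <- c(cands, lapply(frame_runs(nt_seq, sprintf("+%d", f), f - 1L,
                                        L, FALSE),
                             function(x) x))
    cands <- c(cands, lapply(frame_runs(rc, sprintf("-%d", f), f - 1L,
                                        L, TRUE),
                             function(x) x))
  }
  if (!length(cands)) return(NULL)
  frame_rank <- setNames(1:6, c("+1", "+2", "+3", "-1", "-2", "-3"))
  ord <- order(-vapply(cands, `[[`, 0L, "n_codons"),
               frame_rank[vapply(cands, `[[`, "", "frame")],
               vapply(cands, `[[`, 0L, "read_pos"))
  cands <- cands[ord]
  bounded <- vapply(cands, `[[`, TRUE, "stop_bounded")
  best <- if (any(bounded)) cands[bounded][[1]] else cands[[1]]
  structure(list(
    transcript_id = transcript_id, frame = best$frame,
    start = best$start, end = best$end, n_codons = best$n_codons,
    nt_seq = best$nt_seq, aa_seq = best$aa_seq,
    has_N = grepl("N", best$nt_seq, fixed = TRUE),
    has_gap = grepl("-", best$nt_seq, fixed = TRUE),
    no_stop = !best$stop_bounded), class = "cds_candidate")
}

#' @export
print.cds_candidate <- function(x, ...) {
  cat(sprintf("CDS candidate '%s': frame %s, %d codons [%d..%d]%s\n",
              x$transcript_id, x$frame, x$n_codons, x$start, x$end,
              if (x$no_stop) " (no stop in frame)" else ""))
  invisible(x)
}

#' Quality/annotation filter for CDS candidates
#'
#' Applies the scan's retention rules: drop CDSs containing gap characters or
#' ambiguous bases (N), drop CDSs from frames with no stop codon, drop CDSs
#' shorter than `min_len_nt`, and — when `require_annotation` is TRUE — drop
#' CDSs whose transcript has no annotation row at `evalue <= evalue_max`.
#' Every drop carries a machine-readable reason.  The filter is pure,
#' idempotent and order-independent.
#'
#' @param cds a `cds_candidate` (or NULL)
#' @param annotations data frame with columns `query_id`, `evalue` (best-hit
#'   protein annotation records); may be NULL when `require_annotation` is
#'   FALSE
#' @param min_len_nt minimum CDS length in nucleotides (default 300)
#' @param evalue_max annotation e-value cutoff (default 1e-10)
#' @param require_annotation whether an annotation is required for retention
#' @return list with `keep` (logical) and `reason` (NA when kept; one of
#'   `no_cds`, `gap`, `ambiguous_base`, `no_stop_frame`, `too_short`,
#'   `unannotated`)
#' @export
filter_cds <- function(cds, annotations = NULL, min_len_nt = 300L,
                       evalue_max = 1e-10, require_annotation = FALSE) {
  if (is.null(cds)) return(list(keep = FALSE, reason = "no_cds"))
  if (cds$has_gap) return(list(keep = FALSE, reason = "gap"))
  if (cds$has_N) return(list(keep = FALSE, reason = "ambiguous_base"))
  if (cds$no_stop) return(list(keep = FALSE, reason = "no_stop_frame"))
  if (3L * cds$n_codons < min_len_nt)
    return(list(keep = FALSE, reason = "too_short"))
  if (require_annotation) {
    ok <- !is.null(annotations) &&
      any(annotations$query_id == cds$transcript_id &
            annotations$evalue <= evalue_max)
    if (!ok) return(list(keep = FALSE, reason = "unannotated"))
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Read a protein-annotation table
#'
#' Tab-separated best-hit records with a header:
#' `query_id`, `subject_id`, `evalue`, `bitscore`.
#'
#' @param path file path
#' @return data frame
#' @export
read_annotation_table <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "evalue")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stopf("annotation table %s: missing column(s) %s", path,
          paste(miss, collapse = ", "))
  ann
}

## map a scaffold position to a transcript position for a single-segment
## anchor (strand-aware); minus strand: transcript runs against the scaffold
anchor_to_transcript <- function(spos, s_start, s_end, q_start, q_end, strand) {
  if (strand == "+") q_start + (spos - s_start) else q_start + (s_end - spos)
}

#' Build a gap-free in-frame codon alignment for an anchored pair
#'
#' Trims the two retained CDSs to their common in-frame overlap using the
#' genome anchor coordinates (no re-alignment: orthologous pairs are
#' near-identical by construction of the upstream filters).  Emitted only if
#' the trimmed sequences are equal length, gap-free and frame-compatible;
#' otherwise the pair is dropped with a reason.
#'
#' @param pair one row of the [pair_orthologs()] data frame
#' @param cds_a,cds_b `cds_candidate` objects of the two transcripts
#' @param min_codons minimum alignment length in codons (default 100)
#' @return list with either `alignment` (a [codon_alignment()]) or `reason`
#'   (`frame_mismatch`, `length_mismatch`, `segment_mismatch`, `too_short`)
#' @export
build_codon_alignment <- function(pair, cds_a, cds_b, min_codons = 100L) {
  if (is.na(pair$strand)) stopf("pair %s: missing strand", pair$gene_id)
  ## identical anchors + equal CDS length: use the CDSs directly
  if (nchar(cds_a$nt_seq) == nchar(cds_b$nt_seq) &&
      pair$a_start == pair$b_start && pair$a_end == pair$b_end) {
    if (cds_a$n_codons < min_codons)
      return(list(reason = "too_short"))
    return(list(alignment = codon_alignment(cds_a$nt_seq, cds_b$nt_seq,
                                            pair$gene_id)))
  }
  ## multi-segment anchors with unequal structure cannot be trimmed linearly
  if ((pair$a_nseg > 1L || pair$b_nseg > 1L))
    return(list(reason = "segment_mismatch"))
  if (cds_a$frame %in% c("-1", "-2", "-3") ||
      cds_b$frame %in% c("-1", "-2", "-3"))
    return(list(reason = "frame_mismatch"))
  m1 <- max(pair$a_start, pair$b_start)
  m2 <- min(pair$a_end, pair$b_end)
  if (m2 < m1) return(list(reason = "length_mismatch"))
  ## transcript coordinates of the shared scaffold window, per side
  ta <- sort(c(anchor_to_transcript(m1, pair$a_start, pair$a_end,
                                    pair$a_qstart, pair$a_qend, pair$strand),
               anchor_to_transcript(m2, pair$a_start, pair$a_end,
                                    pair$a_qstart, pair$a_qend, pair$strand)))
  tb <- sort(c(anchor_to_transcript(m1, pair$b_start, pair$b_end,
                                    pair$b_qstart, pair$b_qend, pair$strand),
               anchor_to_transcript(m2, pair$b_start, pair$b_end,
                                    pair$b_qstart, pair$b_qend, pair$strand)))
  ## clip jointly so both windows fall inside their CDS
  lo <- max(cds_a$start - ta[1], cds_b$start - tb[1], 0L)
  hi <- max(ta[2] - cds_a$end, tb[2] - cds_b$end, 0L)
  len <- (ta[2] - ta[1] + 1L) - lo - hi
  if (len < 3L) return(list(reason = "length_mismatch"))
  ## codon phase within each CDS at the window start
  offA <- (ta[1] + lo) - cds_a$start
  offB <- (tb[1] + lo) - cds_b$start
  k <- (3L - offA %% 3L) %% 3L
  if ((offB + k) %% 3L != 0L) return(list(reason = "frame_mismatch"))
  len <- ((len - k) %/% 3L) * 3L
  if (len < 3L * min_codons) return(list(reason = "too_short"))
  sub_a <- substr(cds_a$nt_seq, offA + k + 1L, offA + k + len)
  sub_b <- substr(cds_b$nt_seq, offB + k + 1L, offB + k + len)
  list(alignment = codon_alignment(sub_a, sub_b, pair$gene_id))
}
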