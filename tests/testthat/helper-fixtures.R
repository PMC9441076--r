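# Small fixture builders used across the tests.

`%||%` <- divscan:::`%||%`

## one simulated codon alignment (uses the current RNG stream)
sim_alignment <- function(n_codons, t, omega, kappa = 2, gene_id = "g") {
  p <- evolve_codon_pair(random_coding_sequence(n_codons), t, omega, kappa)
  codon_alignment(p$seq_a, p$seq_b, gene_id)
}

## hand-built hit table rows in the post-read_hit_table layout
make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    strand <- if (r$sstart <= r$send) "+" else "-"
    data.frame(qseqid = r$q, sseqid = r$s, pident = 98, length = r$qe - r$qs + 1,
               mismatch = 0, gapopen = 0, qstart = r$qs, qend = r$qe,
               evalue = 1e-50, bitscore = r$bs %||% 100,
               strand = strand,
               s_start = min(r$sstart, r$send), s_end = max(r$sstart, r$send),
               stringsAsFactors = FALSE)
  }))
}

hit <- function(q, s, qs, qe, sstart, send, bs = 100) {
  list(q = q, s = s, qs = qs, qe = qe, sstart = sstart, send = send, bs = bs)
}

## small scaffold-scan object for scan-module tests
make_scan <- function(t, omega = NULL, midpoint = NULL,
                      scaffold_id = "scf", length_bp = 500000L) {
  n <- length(t)
  structure(list(scaffold_id = scaffold_id, length_bp = length_bp,
                 genes = data.frame(gene_id = sprintf("g%d", seq_len(n)),
                                    midpoint = midpoint %||% seq_len(n) * 1e4,
                                    t = t,
                                    omega = omega %||% rep(0.2, n))),
            class = "scaffold_scan")
}
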