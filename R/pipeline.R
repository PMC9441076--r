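# Orchestration of the whole scan: simulate (or read) inputs, classify and
# pair transcripts, extract and filter CDSs, build codon alignments, estimate
# rates, test for positive selection, scan scaffolds, and write a consolidated
# report (per-gene table, tests table, scaffold table, summary JSON, BED
# track, manifest with config hash, seed and per-stage record counts).

#' Pipeline configuration
#'
#' Either a [sim_config()] (inputs are generated) or a named list of input
#' `paths` with elements `transcripts_a`, `transcripts_b`, `hits_a`,
#' `hits_b`, `scaffolds`, and optionally `annotations`.
#'
#' @param sim a [sim_config()] or NULL
#' @param paths named list of input paths (ignored when `sim` is given)
#' @param evalue_max hit-table e-value cutoff (default 1e-15)
#' @param overlap_frac reciprocal overlap threshold for allelic calls and
#'   ortholog pairing (default 0.9)
#' @param gap_tolerance_bp intron gap tolerance (default 30)
#' @param min_len_nt minimum CDS length (default 300)
#' @param annotation_evalue_max annotation e-value cutoff (default 1e-10)
#' @param require_annotation drop unannotated CDSs (default FALSE)
#' @param min_codons minimum alignment length in codons (default 100)
#' @param method rate estimator: `"yn00"` (default) or `"ng86"`
#' @param n_reps bootstrap replicates (default 1000)
#' @param alpha significance level (default 0.05)
#' @param t_div divergent-gene threshold (default 0.1)
#' @param min_scaffold_bp minimum scaffold length for the scan
#'   (default 300000)
#' @param min_genes correlation gene-count threshold (default 5)
#' @param class_edges divergence bin edges (default `c(0.05, 0.75)`)
#' @param seed integer seed for every stochastic step
#' @param out_dir output directory, or NULL to skip writing files
#' @return object of class `run_config`
#' @export
run_config <- function(sim = NULL, paths = NULL, evalue_max = 1e-15,
                       overlap_frac = 0.9, gap_tolerance_bp = 30L,
                       min_len_nt = 300L, annotation_evalue_max = 1e-10,
                       require_annotation = FALSE, min_codons = 100L,
                       method = c("yn00", "ng86"), n_reps = 1000L,
                       alpha = 0.05, t_div = 0.1, min_scaffold_bp = 300000L,
                       min_genes = 5L, class_edges = c(0.05, 0.75),
                       seed = 1L, out_dir = NULL) {
  method <- match.arg(method)
  if (is.null(sim) && is.null(paths))
    stopf("run_config: provide either a sim_config or input paths")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  stopifnot(is_prop(overlap_frac), is_prop(alpha), n_reps >= 2L)
  structure(list(sim = sim, paths = paths, evalue_max = evalue_max,
                 overlap_frac = overlap_frac,
                 gap_tolerance_bp = as.integer(gap_tolerance_bp),
                 min_len_nt = as.integer(min_len_nt),
                 annotation_evalue_max = annotation_evalue_max,
                 require_annotation = require_annotation,
                 min_codons = as.integer(min_codons),
                 method = method, n_reps = as.integer(n_reps),
                 alpha = alpha, t_div = t_div,
                 min_scaffold_bp = as.integer(min_scaffold_bp),
                 min_genes = as.integer(min_genes),
                 class_edges = class_edges,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

read_fasta_named <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Run the full divergence scan
#'
#' Executes every stage over simulated or provided inputs and assembles the
#' per-gene, test and scaffold tables plus the summary statistics.  With
#' `out_dir` set, writes `genes.tsv`, `tests.tsv`, `scaffolds.tsv`,
#' `summary.json`, `tracks.bed`, `classification_A/B.tsv`, `pairs.tsv`,
#' `drop_log.tsv` and `manifest.json` (config hash, seed, per-stage record
#' counts).  Reruns with the same configuration and seed are byte-identical.
#'
#' @param config a [run_config()]
#' @return object of class `divscan_result`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stages <- list()

  ## stage 0: inputs
  if (!is.null(config$sim)) {
    sim_dir <- if (!is.null(config$out_dir))
      file.path(config$out_dir, "inputs") else tempfile("divscan_sim_")
    bundle <- simulate_bundle(config$sim, sim_dir)
    paths <- bundle[setdiff(names(bundle), "truth_set")]
    truth <- bundle$truth_set
  } else {
    paths <- config$paths
    truth <- NULL
  }

  scaffolds <- read.delim(paths$scaffolds, stringsAsFactors = FALSE)
  hits_a <- read_hit_table(paths$hits_a, config$evalue_max)
  hits_b <- read_hit_table(paths$hits_b, config$evalue_max)
  stages$hits <- c(a = nrow(hits_a), b = nrow(hits_b))

  ## stage 1: classification and pairing
  cls_a <- classify_transcripts(hits_a, config$overlap_frac,
                                config$gap_tolerance_bp)
  cls_b <- classify_transcripts(hits_b, config$overlap_frac,
                                config$gap_tolerance_bp)
  pairs <- pair_orthologs(cls_a, cls_b, config$overlap_frac)
  stages$classified <- c(a = nrow(cls_a), b = nrow(cls_b))
  stages$pairs <- nrow(pairs)

  ## stage 2: CDS extraction, filtering, codon alignments
  seqs_a <- read_fasta_named(paths$transcripts_a)
  seqs_b <- read_fasta_named(paths$transcripts_b)
  ann <- if (!is.null(paths$annotations) && file.exists(paths$annotations))
    read_annotation_table(paths$annotations) else NULL
  alignments <- list()
  drop_log <- list()
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    reason <- NA_character_
    cds_a <- longest_orf_6frame(seqs_a[[p$transcript_a]], p$transcript_a)
    cds_b <- longest_orf_6frame(seqs_b[[p$transcript_b]], p$transcript_b)
    fa <- filter_cds(cds_a, ann, config$min_len_nt,
                     config$annotation_evalue_max, config$require_annotation)
    fb <- filter_cds(cds_b, ann, config$min_len_nt,
                     config$annotation_evalue_max, config$require_annotation)
    if (!fa$keep) reason <- paste0("a:", fa$reason)
    else if (!fb$keep) reason <- paste0("b:", fb$reason)
    else {
      built <- build_codon_alignment(p, cds_a, cds_b, config$min_codons)
      if (is.null(built$alignment)) reason <- built$reason
      else alignments[[p$gene_id]] <- built$alignment
    }
    if (!is.na(reason))
      drop_log[[length(drop_log) + 1L]] <-
        data.frame(gene_id = p$gene_id, stage = "cds", reason = reason,
                   stringsAsFactors = FALSE)
  }
  drop_log <- do.call(rbind, drop_log) %||%
    data.frame(gene_id = character(), stage = character(),
               reason = character())
  stages$alignments <- length(alignments)
  stages$dropped_cds <- nrow(drop_log)

  if (!length(alignments))
    stopf("no codon alignments survive the filters")

  ## stage 3: rates
  rates <- estimate_rates(alignments, config$method)
  genes <- merge(pairs[, c("gene_id", "transcript_a", "transcript_b",
                           "scaffold_id", "start", "end", "strand",
                           "has_introns")],
                 rates, by = "gene_id")
  genes <- genes[order(genes$scaffold_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  stages$rates <- nrow(genes)

  ## stage 4: selection tests
  tests <- run_selection_tests(alignments, genes, n_reps = config$n_reps,
                               alpha = config$alpha, method = config$method,
                               seed = config$seed)
  calls <- call_positive_selection(genes, tests, config$alpha)
  stages$tested <- sum(tests$tested)
  stages$significant <- sum(tests$significant)

  ## stage 5: scaffold scan
  scans <- order_genes_on_scaffolds(genes, scaffolds, config$min_scaffold_bp)
  scaffold_table <- scan_scaffolds(scans, config$t_div, min_genes = config$min_genes)
  summary_stats <- list(
    divergence = divergence_summary(genes, config$class_edges),
    regression = tryCatch(dn_ds_regression(genes), error = function(e) NULL),
    patterns = as.list(prop.table(table(factor(scaffold_table$pattern,
      levels = c("A_none", "B_isolated", "C_island"))))),
    n_scaffolds_examined = nrow(scaffold_table),
    r_distribution = attr(scaffold_table, "hist"),
    n_significant = sum(tests$significant),
    n_tested = sum(tests$tested))
  stages$scaffolds_examined <- nrow(scaffold_table)

  cfg_plain <- config
  cfg_plain$sim <- if (!is.null(config$sim)) {
    s <- unclass(config$sim)
    s$t_distribution <- NULL; s$omega_distribution <- NULL
    s
  } else NULL
  manifest <- list(seed = config$seed, method = config$method,
                   config_hash = config_hash(cfg_plain),
                   stages = stages)

  res <- structure(list(genes = genes, tests = tests, calls = calls,
                        scaffolds = scaffold_table, summary = summary_stats,
                        manifest = manifest, truth = truth,
                        drop_log = drop_log, config = config,
                        alignments = alignments,
                        classification = list(a = cls_a, b = cls_b),
                        pairs = pairs),
                   class = "divscan_result")
  if (!is.null(config$out_dir)) write_outputs(res, config$out_dir)
  res
}

## flat, JSON-friendly view of the summary statistics
summary_as_json <- function(s) {
  list(
    n_genes = s$divergence$n,
    identical_fraction = s$divergence$identical_fraction,
    t_bins = as.list(s$divergence$t_bins),
    mean_t = s$divergence$mean_t,
    mean_omega = s$divergence$mean_omega,
    omega_bins = as.list(s$divergence$omega_bins),
    regression = s$regression,
    patterns = s$patterns,
    n_scaffolds_examined = s$n_scaffolds_examined,
    r_hist_breaks = s$r_distribution$breaks,
    r_hist_counts = s$r_distribution$counts,
    n_tested = s$n_tested,
    n_significant = s$n_significant)
}

#' Write the report bundle of a pipeline run
#'
#' @param res a `divscan_result`
#' @param out_dir output directory (created if missing)
#' @return invisibly, the list of written paths
#' @export
write_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genes = file.path(out_dir, "genes.tsv"),
    tests = file.path(out_dir, "tests.tsv"),
    scaffolds = file.path(out_dir, "scaffolds.tsv"),
    summary = file.path(out_dir, "summary.json"),
    manifest = file.path(out_dir, "manifest.json"),
    drop_log = file.path(out_dir, "drop_log.tsv"),
    cls_a = file.path(out_dir, "classification_A.tsv"),
    cls_b = file.path(out_dir, "classification_B.tsv"),
    pairs = file.path(out_dir, "pairs.tsv"))
  wt <- function(d, p) write.table(d, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(res$genes, paths$genes)
  wt(res$tests, paths$tests)
  wt(res$scaffolds, paths$scaffolds)
  wt(res$drop_log, paths$drop_log)
  wt(res$classification$a, paths$cls_a)
  wt(res$classification$b, paths$cls_b)
  wt(res$pairs[, c("gene_id", "transcript_a", "transcript_b", "scaffold_id",
                   "start", "end", "strand", "has_introns")], paths$pairs)
  jsonlite::write_json(summary_as_json(res$summary), paths$summary,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  tr <- write_tracks(res, out_dir)
  invisible(c(paths, tr))
}

#' Write genome-browser tracks of the divergence landscape
#'
#' BED track of per-gene divergence (half-open 0-based coordinates, score =
#' t x 1000 capped at 1000, sorted by scaffold and start) and a per-scaffold
#' pattern table.
#'
#' @param res a `divscan_result`
#' @param out_dir output directory
#' @return invisibly, list of written paths
#' @export
write_tracks <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bed_path <- file.path(out_dir, "tracks.bed")
  g <- res$genes[!is.na(res$genes$t), , drop = FALSE]
  if (nrow(g) == 0L) {
    writeLines("# divergence track: no genes", bed_path)
  } else {
    bed <- data.frame(chrom = g$scaffold_id, start = g$start - 1L,
                      end = g$end, name = g$gene_id,
                      score = pmin(as.integer(round(g$t * 1000)), 1000L),
                      strand = g$strand, stringsAsFactors = FALSE)
    bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  pat_path <- file.path(out_dir, "patterns.tsv")
  write.table(res$scaffolds[, c("scaffold_id", "pattern", "n_divergent",
                                "dispersion_index", "pearson_r")],
              pat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(bed = bed_path, patterns = pat_path))
}

#' @export
print.divscan_result <- function(x, ...) {
  s <- x$summary
  cat("divergence scan result\n")
  cat(sprintf("  genes analyzed: %d  (method %s)\n", nrow(x$genes),
              x$config$method))
  cat(sprintf("  identical fraction: %.3f   mean t: %.4f   mean omega: %.3f\n",
              s$divergence$identical_fraction, s$divergence$mean_t,
              s$divergence$mean_omega %||% NA))
  cat(sprintf("  positively selected (omega > 1, q < %.2g): %d of %d tested\n",
              x$config$alpha, s$n_significant, s$n_tested))
  cat(sprintf("  scaffolds examined: %d  patterns: %s\n",
              s$n_scaffolds_examined,
              paste(sprintf("%s=%.0f%%", names(s$patterns),
                            100 * unlist(s$patterns)), collapse = " ")))
  invisible(x)
}

#' @export
summary.divscan_result <- function(object, ...) {
  object$summary
}

#' @export
plot.divscan_result <- function(x, which = c("divergence", "dnds", "r"), ...) {
  which <- match.arg(which)
  if (which == "divergence") {
    graphics::hist(x$genes$t, breaks = 40, main = "Per-gene divergence",
                   xlab = "t (substitutions per codon)")
  } else if (which == "dnds") {
    plot(x$genes$dS, x$genes$dN, xlab = "dS", ylab = "dN",
         main = "dN vs dS", pch = 20)
    if (!is.null(x$summary$regression))
      graphics::abline(x$summary$regression$intercept,
                       x$summary$regression$slope, col = 2)
  } else {
    h <- x$summary$r_distribution
    graphics::barplot(h$counts, names.arg = sprintf("%.1f", h$breaks[-1]),
                      main = "Per-scaffold cor(t, omega)", xlab = "r")
  }
  invisible(x)
}
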