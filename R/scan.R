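# Genomic-architecture stage: the divergence landscape along scaffolds.
#
# Genes are positioned by anchor midpoint along the longest scaffolds and
# each scaffold is assigned a divergence pattern: A_none (no divergent gene),
# B_isolated (one or two isolated divergent genes), C_island (a run of
# consecutive divergent genes, or more than the isolated allowance).
# Clustering of divergent genes is quantified with Fisher's index of
# dispersion on consecutive inter-divergent-gene distances; the coupling of
# divergence and selection is summarized by the per-scaffold Pearson
# correlation of t and omega, a genome-wide regression of dN on dS, and
# binned divergence-class fractions.

#' Order genes along scaffolds
#'
#' Keeps scaffolds of at least `min_scaffold_bp` and emits per-scaffold gene
#' lists ordered by anchor midpoint.
#'
#' @param genes data frame with `gene_id`, `scaffold_id`, `start`, `end`,
#'   `t`, `omega`
#' @param scaffold_lengths data frame with `scaffold_id`, `length_bp`
#' @param min_scaffold_bp minimum scaffold length (default 300000)
#' @return list of `scaffold_scan` objects: `scaffold_id`, `length_bp`,
#'   `genes` (gene_id, midpoint, t, omega, ordered by midpoint)
#' @export
order_genes_on_scaffolds <- function(genes, scaffold_lengths,
                                     min_scaffold_bp = 300000L) {
  unknown <- setdiff(genes$scaffold_id, scaffold_lengths$scaffold_id)
  if (length(unknown))
    stopf("genes anchored to unknown scaffold(s): %s",
          paste(unique(unknown), collapse = ", "))
  keep <- scaffold_lengths[scaffold_lengths$length_bp >= min_scaffold_bp, ,
                           drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(keep))) {
    g <- genes[genes$scaffold_id == keep$scaffold_id[k], , drop = FALSE]
    if (nrow(g) == 0L) next
    g$midpoint <- (g$start + g$end) / 2
    g <- g[order(g$midpoint), , drop = FALSE]
    out[[length(out) + 1L]] <- structure(
      list(scaffold_id = keep$scaffold_id[k],
           length_bp = keep$length_bp[k],
           genes = data.frame(gene_id = g$gene_id, midpoint = g$midpoint,
                              t = g$t, omega = g$omega,
                              stringsAsFactors = FALSE)),
      class = "scaffold_scan")
  }
  out
}

#' @export
print.scaffold_scan <- function(x, ...) {
  cat(sprintf("scaffold %s (%d bp): %d genes\n", x$scaffold_id,
              x$length_bp, nrow(x$genes)))
  invisible(x)
}

#' Classify the divergence pattern of a scaffold
#'
#' `A_none` if no gene exceeds the divergence threshold; `C_island` if there
#' is a run of at least `min_run` consecutive divergent genes or more than
#' `max_isolated` divergent genes in total; `B_isolated` otherwise.  (An
#' automated surrogate for an inspection-based pattern call; the run length
#' and isolated allowance are configurable.)
#'
#' @param scan a `scaffold_scan` (or a numeric vector of ordered gene t
#'   values)
#' @param t_div divergence threshold defining a divergent gene (default 0.1)
#' @param max_isolated maximum number of isolated divergent genes for
#'   pattern B (default 2)
#' @param min_run run length of consecutive divergent genes defining an
#'   island (default 3)
#' @return one of `"A_none"`, `"B_isolated"`, `"C_island"`
#' @export
classify_pattern <- function(scan, t_div = 0.1, max_isolated = 2L,
                             min_run = 3L) {
  tvals <- if (inherits(scan, "scaffold_scan")) scan$genes$t else scan
  div <- !is.na(tvals) & tvals > t_div
  n_div <- sum(div)
  if (n_div == 0L) return("A_none")
  runs <- rle(div)
  longest <- max(runs$lengths[runs$values], 0L)
  if (longest >= min_run || n_div > max_isolated) return("C_island")
  "B_isolated"
}

#' Fisher's index of dispersion of inter-divergent-gene distances
#'
#' Sample variance (n-1 denominator) of consecutive distances between
#' divergent-gene midpoints, divided by their mean.  Values above one
#' indicate aggregation of divergent genes, below one over-dispersion.
#' Undefined (empty result) with fewer than two distances.
#'
#' @param midpoints positions of the divergent genes on one scaffold (any
#'   order; sorted internally)
#' @return numeric scalar, or `numeric(0)` when undefined
#' @export
dispersion_index <- function(midpoints) {
  midpoints <- sort(midpoints)
  d <- diff(midpoints)
  if (length(d) < 2L) return(numeric(0))
  var(d) / mean(d)
}

#' Per-scaffold correlation between divergence and omega
#'
#' Pearson product-moment correlation of t and omega over the genes of each
#' scaffold with more than `min_genes` genes carrying finite values;
#' scaffolds with zero variance in either variable are skipped with a flag.
#' The cross-scaffold histogram of r is attached as attribute `"hist"`.
#'
#' @param scans list of `scaffold_scan` objects
#' @param min_genes scaffolds need strictly more genes than this (default 5)
#' @return data frame `scaffold_id`, `n_genes`, `r`, `flag` (`ok`,
#'   `too_few`, `zero_variance`)
#' @export
correlate_t_omega <- function(scans, min_genes = 5L) {
  rows <- lapply(scans, function(sc) {
    g <- sc$genes[is.finite(sc$genes$t) & is.finite(sc$genes$omega), ,
                  drop = FALSE]
    n <- nrow(g)
    if (n <= min_genes)
      return(data.frame(scaffold_id = sc$scaffold_id, n_genes = n,
                        r = NA_real_, flag = "too_few",
                        stringsAsFactors = FALSE))
    if (var(g$t) == 0 || var(g$omega) == 0)
      return(data.frame(scaffold_id = sc$scaffold_id, n_genes = n,
                        r = NA_real_, flag = "zero_variance",
                        stringsAsFactors = FALSE))
    data.frame(scaffold_id = sc$scaffold_id, n_genes = n,
               r = cor(g$t, g$omega), flag = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(scaffold_id = character(), n_genes = integer(),
               r = numeric(), flag = character())
  rvals <- out$r[out$flag == "ok"]
  breaks <- seq(-1, 1, by = 0.2)
  counts <- if (length(rvals))
    as.integer(table(cut(rvals, breaks, include.lowest = TRUE)))
  else integer(length(breaks) - 1L)
  attr(out, "hist") <- list(breaks = breaks, counts = counts)
  out
}

#' Genome-wide regression of dN on dS
#'
#' Ordinary least squares of dN on dS over all genes with finite rates, with
#' the Pearson correlation across genes.
#'
#' @param rates data frame with `dN`, `dS`
#' @return list `slope`, `intercept`, `r`, `n`
#' @export
dn_ds_regression <- function(rates) {
  d <- rates[is.finite(rates$dN) & is.finite(rates$dS), , drop = FALSE]
  if (nrow(d) < 3L) stopf("need >= 3 genes with finite dN and dS")
  if (var(d$dS) == 0) stopf("zero variance in dS: regression undefined")
  fit <- lm(dN ~ dS, data = d)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = cor(d$dS, d$dN), n = nrow(d))
}

#' Divergence-class and omega-class summary
#'
#' Fraction of strictly identical genes (t = 0), fractions per divergence
#' bin (half-open `(edge_i, edge_{i+1}]`, plus the mass above the last
#' edge), mean t and mean omega, and omega-bin fractions.
#'
#' @param rates data frame with `t` and `omega` (or a numeric t vector)
#' @param class_edges strictly increasing divergence bin edges starting at 0
#'   (a leading 0 is implied; default `c(0.05, 0.75)`)
#' @param omega_edges omega bin edges (default `c(0.25, 0.5, 1)`)
#' @return list `n`, `identical_fraction`, `t_bins` (named fractions),
#'   `mean_t`, `mean_omega`, `omega_bins`
#' @export
divergence_summary <- function(rates, class_edges = c(0.05, 0.75),
                               omega_edges = c(0.25, 0.5, 1)) {
  tvals <- if (is.data.frame(rates)) rates$t else rates
  ovals <- if (is.data.frame(rates) && !is.null(rates$omega)) rates$omega
           else NULL
  class_edges <- class_edges[class_edges > 0]
  if (is.unsorted(class_edges, strictly = TRUE))
    stopf("class_edges must be strictly increasing")
  tvals <- tvals[is.finite(tvals)]
  n <- length(tvals)
  if (n == 0L) stopf("no finite divergence values")
  ident <- mean(tvals == 0)
  edges <- c(0, class_edges, Inf)
  labs <- c(sprintf("(%g,%g]", edges[seq_len(length(edges) - 2L)],
                    edges[seq(2L, length(edges) - 1L)]),
            sprintf(">%g", class_edges[length(class_edges)]))
  bins <- table(cut(tvals[tvals > 0], edges, labels = labs)) / n
  out <- list(n = n, identical_fraction = ident,
              t_bins = setNames(as.numeric(bins), labs),
              mean_t = mean(tvals))
  if (!is.null(ovals)) {
    ov <- ovals[is.finite(ovals)]
    oedges <- c(0, omega_edges, Inf)
    olabs <- c(sprintf("<=%g", omega_edges[1]),
               sprintf("(%g,%g]", omega_edges[-length(omega_edges)],
                       omega_edges[-1]),
               sprintf(">%g", omega_edges[length(omega_edges)]))
    out$mean_omega <- mean(ov)
    out$omega_bins <- setNames(
      as.numeric(table(cut(ov, oedges, labels = olabs,
                           include.lowest = TRUE))) / length(ov), olabs)
  }
  out
}

#' Scan a set of scaffolds
#'
#' Applies [classify_pattern()], [dispersion_index()] and the per-scaffold
#' correlation to ordered scaffold gene lists.
#'
#' @param scans list from [order_genes_on_scaffolds()]
#' @param t_div divergence threshold (default 0.1)
#' @param max_isolated,min_run pattern parameters, see [classify_pattern()]
#' @param min_genes correlation gene-count threshold, see
#'   [correlate_t_omega()]
#' @return data frame, one row per scaffold: `scaffold_id`, `length_bp`,
#'   `n_genes`, `n_divergent`, `pattern`, `dispersion_index`, `pearson_r`,
#'   `r_flag`
#' @export
scan_scaffolds <- function(scans, t_div = 0.1, max_isolated = 2L,
                           min_run = 3L, min_genes = 5L) {
  cors <- correlate_t_omega(scans, min_genes = min_genes)
  rows <- lapply(seq_along(scans), function(k) {
    sc <- scans[[k]]
    div <- !is.na(sc$genes$t) & sc$genes$t > t_div
    di <- dispersion_index(sc$genes$midpoint[div])
    data.frame(scaffold_id = sc$scaffold_id, length_bp = sc$length_bp,
               n_genes = nrow(sc$genes), n_divergent = sum(div),
               pattern = classify_pattern(sc, t_div, max_isolated, min_run),
               dispersion_index = if (length(di)) di else NA_real_,
               pearson_r = cors$r[k], r_flag = cors$flag[k],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(scaffold_id = character(), length_bp = integer(),
               n_genes = integer(), n_divergent = integer(),
               pattern = character(), dispersion_index = numeric(),
               pearson_r = numeric(), r_flag = character())
  attr(out, "hist") <- attr(cors, "hist")
  out
}

#' Fixed-substitution load implied by a divergence scan
#'
#' The number of fixed coding substitutions implied by a set of orthologous
#' genes: the number of divergent genes (rounded from `n_genes *
#' frac_divergent`) times gene length in codons times the modal divergence
#' in substitutions per codon, rounded to the nearest ten.
#'
#' @param n_genes number of orthologous genes examined
#' @param frac_divergent fraction of genes carrying fixed divergence
#' @param gene_length_codons typical gene length in codons
#' @param subs_per_codon modal divergence of the divergent genes
#' @return estimated count of fixed substitutions (nearest ten)
#' @examples
#' fixed_substitution_load(6916, 0.30, 300, 0.025)
#' @export
fixed_substitution_load <- function(n_genes, frac_divergent,
                                    gene_length_codons, subs_per_codon) {
  round(round(frac_divergent * n_genes) * gene_length_codons *
          subs_per_codon, -1)
}
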