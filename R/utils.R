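#' @importFrom stats cor cor.test lm coef pnorm rexp rgamma rnorm runif rmultinom
#'   sd var rbinom p.adjust setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

is_prop <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)

#' Reverse-complement of a nucleotide string
#' @param x character scalar over A/C/G/T/N/-
#' @return reverse complement, same alphabet
#' @keywords internal
revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")
  chars <- strsplit(toupper(x), "")[[1]]
  paste(rev(unname(map[chars])), collapse = "")
}

split_codons <- function(x) {
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

## A small stable hash for manifests: md5 of the serialized object written to a
## temporary file (tools::md5sum is file-based).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x, control = "all"), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

## 1-based inclusive interval overlap length (0 if disjoint)
overlap_len <- function(a1, a2, b1, b2) {
  pmax(0L, pmin(a2, b2) - pmax(a1, b1) + 1L)
}
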