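#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats aggregate as.dist binom.test cor cutree hclust median
#'   p.adjust plogis pnorm pwilcox rnbinom runif setNames wilcox.test
#' @importFrom utils write.table read.table head packageVersion
NULL

BASES <- c("A", "C", "G", "T")

## reverse complement for plain character vectors (delegates to Biostrings)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Hamming distance between two equal-length DNA strings
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    stop("hamming(): sequences must have equal length")
  }
  sum(ra != rb)
}

random_dna <- function(n, prob = NULL) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

## Deterministic, locale-independent TSV writer used for all pipeline output.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "", ...)
}

## radix sort order: byte-wise, independent of collation locale
ord <- function(...) order(..., method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
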