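## Novel piRNA-like discovery: a transparent k-mer discriminant stands in
## for an external piRNA prediction tool, exact-match genome placement
## stands in for a short-read aligner run, and strand-aware interval
## merging builds the piR_LLi loci.

## per-k-mer log-odds (positives vs negatives), shrunk toward the pooled
## frequency with 4^k pseudo-observations: k-mers unseen in both classes
## contribute ~0 instead of Laplace noise
kmer_logodds <- function(positives, negatives, k) {
  cp <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(positives), width = k))
  cn <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(negatives), width = k))
  pool <- (cp + cn + 1) / sum(cp + cn + 1)
  tau <- 4^k
  log((cp + tau * pool) / (sum(cp) + tau)) -
    log((cn + tau * pool) / (sum(cn) + tau))
}

shuffle_seq <- function(s) {
  paste(sample(strsplit(s, "")[[1]]), collapse = "")
}

#' Score sequences with a k-mer piRNA discriminant
#'
#' Fits a naive-Bayes-style log-odds discriminant on k-mer frequencies
#' (k = 1..kmax) of a positive training set (known piRNAs) versus a
#' negative set (decoy sncRNAs; per-sequence shuffles of the positives when
#' no negatives are given), then scores query sequences on \[0, 1\] via the
#' logistic of the total log-odds. Training and scoring are deterministic;
#' the seed only controls shuffle-generated negatives.
#'
#' @param sequences character vector of query sequences (the unannotated
#'   pool, 25--35 nt).
#' @param positives training positives (known piRNA sequences).
#' @param negatives training negatives; \code{NULL} to use shuffles of the
#'   positives.
#' @param threshold retain candidates with score >= threshold.
#' @param kmax largest k-mer size (default 5).
#' @param min_train minimum training-set size per class.
#' @param seed seed for shuffle-generated negatives.
#' @return data.frame (sequence, score, retained), one row per query, in
#'   input order.
#' @export
score_pirna_like <- function(sequences, positives, negatives = NULL,
                             threshold = 0.5, kmax = 5L, min_train = 10L,
                             seed = 1L) {
  if (is.null(negatives)) {
    set.seed(derive_seed(seed, 66L))
    negatives <- vapply(positives, shuffle_seq, "", USE.NAMES = FALSE)
  }
  if (length(positives) < min_train || length(negatives) < min_train) {
    stop("training sets must contain at least ", min_train,
         " sequences each")
  }
  ks <- seq_len(kmax)
  weights <- lapply(ks, function(k) kmer_logodds(positives, negatives, k))
  qry <- Biostrings::DNAStringSet(sequences)
  lo <- rep(0, length(sequences))
  for (k in ks) {
    cnt <- Biostrings::oligonucleotideFrequency(qry, width = k)
    lo <- lo + as.vector(cnt %*% weights[[k]])
  }
  ## total log-odds through the logistic: score 0.5 is the naive-Bayes
  ## decision boundary at equal priors
  score <- stats::plogis(lo)
  data.frame(sequence = sequences, score = score,
             retained = score >= threshold, stringsAsFactors = FALSE)
}

#' Map candidate sequences to the genome by exact match
#'
#' Reports every perfect-match placement of each candidate on either
#' strand. Candidates with no placement, or with more placements than
#' \code{max_placements}, are dropped and listed in the report.
#'
#' @param candidates character vector of candidate sequences.
#' @param genome named character vector of contig sequences.
#' @param max_placements placement cap (default 30).
#' @return list with \code{alignments} (sequence, contig, start, end,
#'   strand; 0-based half-open), \code{unmapped} and \code{overmapped}
#'   sequence vectors.
#' @export
map_candidates <- function(candidates, genome, max_placements = 30L) {
  subjects <- lapply(genome, Biostrings::DNAString)
  rows <- list()
  unmapped <- character(0)
  overmapped <- character(0)
  for (cand in candidates) {
    hits <- list()
    rc <- revcomp(cand)
    for (ctg in names(subjects)) {
      fwd <- Biostrings::matchPattern(cand, subjects[[ctg]])
      if (length(fwd) > 0L) {
        hits[[length(hits) + 1L]] <- data.frame(
          sequence = cand, contig = ctg,
          start = Biostrings::start(fwd) - 1L,
          end = Biostrings::end(fwd), strand = "+",
          stringsAsFactors = FALSE)
      }
      rev <- Biostrings::matchPattern(rc, subjects[[ctg]])
      if (length(rev) > 0L) {
        hits[[length(hits) + 1L]] <- data.frame(
          sequence = cand, contig = ctg,
          start = Biostrings::start(rev) - 1L,
          end = Biostrings::end(rev), strand = "-",
          stringsAsFactors = FALSE)
      }
    }
    if (length(hits) == 0L) {
      unmapped <- c(unmapped, cand)
      next
    }
    h <- do.call(rbind, hits)
    ## a palindromic candidate matches both strands at the same interval;
    ## keep both placements (strand-distinct), like an aligner would
    if (nrow(h) > max_placements) {
      overmapped <- c(overmapped, cand)
      next
    }
    rows[[length(rows) + 1L]] <- h
  }
  alignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  rownames(alignments) <- NULL
  list(alignments = alignments, unmapped = unmapped,
       overmapped = overmapped)
}

#' Build piR_LLi loci from genomic alignments
#'
#' Alignments on the same contig and strand whose intervals overlap or lie
#' within \code{merge_distance} bases are merged into one locus (union
#' span). Per-sample locus coverage sums the counts of every member
#' placement (multi-mapping sequences contribute their full count to every
#' locus they map in); a per-locus multimap fraction is reported so users
#' can filter. Loci are numbered \code{piR_LLi_N} in (contig, start)
#' order.
#'
#' @param alignments data.frame from [map_candidates()].
#' @param counts integer matrix sequence x sample.
#' @param merge_distance nonnegative merge gap (default 0).
#' @param contig_class optional named vector contig -> class for the
#'   mitochondrial flag.
#' @param min_coverage drop loci with total coverage below this (default 1).
#' @return object of class \code{pi_loci}: list with \code{loci}
#'   (locus_id, contig, start, end, strand, representative_sequence,
#'   member_count, multimap_fraction, is_mito, total_coverage) and
#'   \code{coverage} (locus x sample matrix).
#' @export
build_loci <- function(alignments, counts, merge_distance = 0L,
                       contig_class = NULL, min_coverage = 1L) {
  if (merge_distance < 0L) stop("merge_distance must be nonnegative")
  empty <- list(
    loci = data.frame(locus_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(),
                      representative_sequence = character(),
                      member_count = integer(),
                      multimap_fraction = numeric(), is_mito = logical(),
                      total_coverage = numeric(), stringsAsFactors = FALSE),
    coverage = matrix(0, 0, ncol(counts),
                      dimnames = list(character(), colnames(counts))))
  class(empty) <- "pi_loci"
  if (nrow(alignments) == 0L) return(empty)

  gr <- GenomicRanges::GRanges(
    seqnames = alignments$contig,
    ranges = IRanges::IRanges(start = alignments$start + 1L,
                              end = alignments$end),
    strand = alignments$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_distance + 1L)
  locus_order <- ord(as.character(GenomicRanges::seqnames(red)),
                     GenomicRanges::start(red),
                     as.character(GenomicRanges::strand(red)))
  red <- red[locus_order]
  hits <- GenomicRanges::findOverlaps(gr, red)
  aln_locus <- rep(NA_integer_, nrow(alignments))
  aln_locus[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)

  placements_per_seq <- table(alignments$sequence)
  n_loci <- length(red)
  samples <- colnames(counts)
  coverage <- matrix(0, n_loci, length(samples),
                     dimnames = list(NULL, samples))
  rep_seq <- character(n_loci)
  member_count <- integer(n_loci)
  multimap_frac <- numeric(n_loci)
  for (i in seq_len(n_loci)) {
    mem <- alignments$sequence[which(aln_locus == i)]
    cts <- counts[mem, , drop = FALSE]
    coverage[i, ] <- colSums(cts)
    totals <- rowSums(cts)
    best <- ord(-totals, mem)[1]
    rep_seq[i] <- mem[best]
    member_count[i] <- length(unique(mem))
    mm <- placements_per_seq[mem] > 1L
    multimap_frac[i] <- if (sum(totals) > 0) {
      sum(totals[mm]) / sum(totals)
    } else 0
  }

  keep <- rowSums(coverage) >= min_coverage
  red <- red[keep]
  coverage <- coverage[keep, , drop = FALSE]
  loci <- data.frame(
    locus_id = sprintf("piR_LLi_%d", seq_len(sum(keep))),
    contig = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    strand = as.character(GenomicRanges::strand(red)),
    representative_sequence = rep_seq[keep],
    member_count = member_count[keep],
    multimap_fraction = multimap_frac[keep],
    is_mito = if (is.null(contig_class)) FALSE else
      unname(contig_class[as.character(GenomicRanges::seqnames(red))] ==
               "mitochondrial-like"),
    total_coverage = rowSums(coverage),
    stringsAsFactors = FALSE)
  rownames(coverage) <- loci$locus_id
  structure(list(loci = loci, coverage = coverage), class = "pi_loci")
}

#' @export
print.pi_loci <- function(x, ...) {
  cat(sprintf("piR_LLi loci: %d (%d mitochondrial-like)\n",
              nrow(x$loci), sum(x$loci$is_mito)))
  if (nrow(x$loci) > 0) {
    cat(sprintf("  width: %d-%d bp; coverage total: %s\n",
                min(x$loci$end - x$loci$start),
                max(x$loci$end - x$loci$start),
                format(sum(x$coverage), big.mark = ",")))
  }
  invisible(x)
}
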