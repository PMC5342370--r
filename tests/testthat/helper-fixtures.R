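# Shared fixtures: small configurations and hand-built inputs.

# a compact study: 2 contigs, few samples, everything expressed
small_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_contigs = 2L, contig_length = 40000L,
                   n_genes = 6L, n_known_pirnas = 30L,
                   n_decoy_sncrnas = 10L, n_planted_loci = 8L,
                   n_samples_per_stage = c(CN = 3L, pHCC = 3L),
                   nb_mean = 20, low_expression_frac = 0,
                   n_transcripts = 10L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# write a 4-line-per-record FASTQ
write_fastq <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  path
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force position-by-position Hamming scan: the target-search oracle.
# Slides over every window; per-window mismatch counts accumulated with one
# vectorised comparison per guide position.
brute_force_sites <- function(guide, transcripts, max_mismatches = 3L,
                              pirna_id = "guide") {
  target <- chartr("ACGT", "TGCA", paste(rev(strsplit(guide, "")[[1]]),
                                         collapse = ""))
  traw <- charToRaw(target)
  out <- list()
  for (i in seq_len(nrow(transcripts))) {
    xraw <- charToRaw(transcripts$sequence[i])
    L <- length(xraw)
    if (L < 20L) next
    nw <- L - 19L
    mm <- integer(nw)
    for (j in 1:20) {
      mm <- mm + (xraw[j:(j + nw - 1L)] != traw[j])
    }
    hits <- which(mm <= max_mismatches)
    for (w in hits) {
      mid <- w - 1L + 10L
      region <- if (mid < transcripts$utr5_end[i]) "five_prime_utr"
        else if (mid < transcripts$cds_end[i]) "CDS"
        else "three_prime_utr"
      out[[length(out) + 1L]] <- data.frame(
        pirna_id = pirna_id, transcript_id = transcripts$transcript_id[i],
        start = w - 1L, end = w + 19L, mismatches = mm[w], region = region,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(pirna_id = character(), transcript_id = character(),
               start = integer(), end = integer(), mismatches = integer(),
               region = character(), stringsAsFactors = FALSE)
}

site_key <- function(df) {
  sort(sprintf("%s|%s|%d|%d", df$pirna_id, df$transcript_id, df$start,
               df$mismatches))
}
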