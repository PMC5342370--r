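## piRNA -> transcript target prediction: a 20-nt guide taken from piRNA
## position 2 is matched against the reverse complement of each transcript
## window with up to max_mismatches mismatches (antisense pairing with the
## mRNA; gapless, sense strand of the transcript only).
##
## The search is seed-and-extend: the matching target (the reverse
## complement of the guide) is partitioned into max_mismatches + 1
## non-overlapping pieces; by pigeonhole, any window within the mismatch
## budget contains at least one piece exactly, so exact piece hits are
## expanded to candidate windows and verified by Hamming count. The result
## is identical to a full position-by-position scan.

#' Extract the 20-nt guide of a piRNA
#'
#' The guide is positions 2..21 (1-based) of the piRNA sequence; piRNAs
#' shorter than 21 nt cannot yield one.
#'
#' @param pirna_seq piRNA sequence.
#' @return the 20-nt guide, or \code{NA_character_} (with a
#'   \code{"reason"} attribute) for too-short piRNAs.
#' @export
extract_guide <- function(pirna_seq) {
  if (nchar(pirna_seq) < 21L) {
    return(structure(NA_character_, reason = "too short for guide"))
  }
  substr(pirna_seq, 2L, 21L)
}

#' Build the guide table for a set of piRNAs
#'
#' @param pirna_seqs named character vector (id -> sequence).
#' @return list with \code{guides} (named vector of 20-nt guides) and
#'   \code{skipped} (data.frame id, reason).
#' @export
extract_guides <- function(pirna_seqs) {
  g <- vapply(pirna_seqs, extract_guide, "")
  ok <- !is.na(g)
  list(guides = g[ok],
       skipped = data.frame(pirna_id = names(pirna_seqs)[!ok],
                            reason = rep("too short for guide", sum(!ok)),
                            stringsAsFactors = FALSE))
}

## split 1..20 into n_pieces contiguous pieces of near-equal length
guide_pieces <- function(n_pieces, guide_len = 20L) {
  sizes <- rep(guide_len %/% n_pieces, n_pieces)
  extra <- guide_len %% n_pieces
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  data.frame(start = ends - sizes + 1L, end = ends)
}

region_of <- function(mid, utr5_end, cds_end) {
  if (mid < utr5_end) "five_prime_utr"
  else if (mid < cds_end) "CDS"
  else "three_prime_utr"
}

#' Find target sites of one guide across transcripts
#'
#' Reports every 20-nt transcript window whose reverse complement is
#' within Hamming distance \code{max_mismatches} of the guide, with the
#' exact mismatch count and the region containing the window midpoint.
#'
#' @param guide 20-nt guide sequence.
#' @param transcripts data.frame: transcript_id, sequence, utr5_end,
#'   cds_end, length (boundaries 0-based).
#' @param max_mismatches mismatch budget (default 3).
#' @param pirna_id identifier recorded in the output.
#' @return data.frame of TargetSite rows: pirna_id, transcript_id, start,
#'   end (0-based half-open), mismatches, region.
#' @export
find_sites <- function(guide, transcripts, max_mismatches = 3L,
                       pirna_id = "guide") {
  stopifnot(nchar(guide) == 20L)
  target <- revcomp(guide)   # what the site looks like on the transcript
  pieces <- guide_pieces(max_mismatches + 1L)
  target_raw <- charToRaw(target)
  out <- list()
  for (i in seq_len(nrow(transcripts))) {
    txs <- transcripts$sequence[i]
    txlen <- nchar(txs)
    if (txlen < 20L) {
      warning("transcript ", transcripts$transcript_id[i],
              " shorter than 20 nt; skipped")
      next
    }
    subj <- Biostrings::DNAString(txs)
    cand <- integer(0)
    for (p in seq_len(nrow(pieces))) {
      piece <- substr(target, pieces$start[p], pieces$end[p])
      m <- Biostrings::matchPattern(piece, subj)
      if (length(m) > 0L) {
        cand <- c(cand, Biostrings::start(m) - pieces$start[p] + 1L)
      }
    }
    cand <- sort(unique(cand))
    cand <- cand[cand >= 1L & cand + 19L <= txlen]
    if (length(cand) == 0L) next
    tx_raw <- charToRaw(txs)
    for (w in cand) {
      mm <- sum(tx_raw[w:(w + 19L)] != target_raw)
      if (mm <= max_mismatches) {
        start0 <- w - 1L
        out[[length(out) + 1L]] <- data.frame(
          pirna_id = pirna_id,
          transcript_id = transcripts$transcript_id[i],
          start = start0, end = start0 + 20L, mismatches = mm,
          region = region_of(start0 + 10L, transcripts$utr5_end[i],
                             transcripts$cds_end[i]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(pirna_id = character(), transcript_id = character(),
               start = integer(), end = integer(), mismatches = integer(),
               region = character(), stringsAsFactors = FALSE)
}

#' Find target sites for many guides
#'
#' @param guides named character vector of 20-nt guides.
#' @param transcripts transcript table (see [find_sites()]).
#' @param max_mismatches mismatch budget.
#' @return combined TargetSite data.frame.
#' @export
find_all_sites <- function(guides, transcripts, max_mismatches = 3L) {
  res <- lapply(names(guides), function(id) {
    find_sites(guides[[id]], transcripts, max_mismatches, pirna_id = id)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(pirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      mismatches = integer(), region = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Summarise predicted target sites
#'
#' @param sites TargetSite data.frame.
#' @return list: \code{by_region} site counts per region,
#'   \code{per_pirna} distinct target transcripts per piRNA,
#'   \code{per_transcript} distinct piRNAs per transcript,
#'   \code{pair_multiplicity} sites per (piRNA, transcript) pair,
#'   \code{n_target_transcripts}.
#' @export
target_summary <- function(sites) {
  regions <- c("five_prime_utr", "CDS", "three_prime_utr")
  by_region <- data.frame(
    region = regions,
    count = vapply(regions, function(r) sum(sites$region == r),
                   integer(1)),
    stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) {
    return(list(by_region = by_region,
                per_pirna = data.frame(pirna_id = character(),
                                       n_targets = integer()),
                per_transcript = data.frame(transcript_id = character(),
                                            n_pirnas = integer()),
                pair_multiplicity = data.frame(pirna_id = character(),
                                               transcript_id = character(),
                                               n_sites = integer()),
                n_target_transcripts = 0L))
  }
  per_pirna <- aggregate(transcript_id ~ pirna_id, sites,
                         function(x) length(unique(x)))
  names(per_pirna)[2] <- "n_targets"
  per_tx <- aggregate(pirna_id ~ transcript_id, sites,
                      function(x) length(unique(x)))
  names(per_tx)[2] <- "n_pirnas"
  pairs <- aggregate(start ~ pirna_id + transcript_id, sites, length)
  names(pairs)[3] <- "n_sites"
  list(by_region = by_region, per_pirna = per_pirna,
       per_transcript = per_tx, pair_multiplicity = pairs,
       n_target_transcripts = length(unique(sites$transcript_id)))
}
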