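## Count simulation, FASTQ emission and target-site planting for the
## synthetic study. Counts follow a negative binomial in the mean/dispersion
## parameterisation (var = mu + dispersion * mu^2); a configured fraction of
## features sits in a near-zero low-expression tail, and a configured
## fraction is planted differential with group mean ratio planted_fc
## between CN and the tumor stages.

#' Feature table for the simulator
#'
#' One row per countable feature of a reference bundle: every known sncRNA
#' (piRNA and decoy classes) and every planted piRNA-like locus.
#'
#' @param ref a \code{pi_reference}.
#' @return data.frame with columns \code{feature_id}, \code{type}.
#' @export
sim_feature_table <- function(ref) {
  rbind(data.frame(feature_id = ref$sncrna$id, type = ref$sncrna$class,
                   stringsAsFactors = FALSE),
        data.frame(feature_id = ref$loci$locus_id, type = "locus",
                   stringsAsFactors = FALSE))
}

#' Simulate per-sample counts with planted ground truth
#'
#' Draws a features x samples count table from the negative-binomial model.
#' Samples follow \code{config$n_samples_per_stage}; each tumor-stage sample
#' shares a patient identifier with one CN sample where available (matched
#' design). A fraction \code{low_expression_frac} of features receives a
#' near-zero mean; of the remaining expressed features,
#' \code{round(frac_differential * n_features)} are planted differential
#' with group mean ratio \code{planted_fc} between CN and every tumor
#' stage, alternating up/down in the tumor direction.
#'
#' @param config a [sim_config()].
#' @param features data.frame with a \code{feature_id} column (see
#'   [sim_feature_table()]).
#' @param stage_multipliers optional numeric matrix (features x stages,
#'   dimnames required) of mean multipliers overriding the default
#'   differential plan; used to plant stage-restricted profiles.
#' @return an object of class \code{pi_sim_counts}: list with
#'   \code{counts} (integer matrix), \code{meta} (sample, patient, stage)
#'   and \code{truth} (differential table, low-tail ids, mean matrix).
#' @export
simulate_counts <- function(config, features, stage_multipliers = NULL) {
  cfg <- validate_sim_config(config)
  if (cfg$planted_fc <= 0) stop("planted_fc must be > 0")
  stages <- names(cfg$n_samples_per_stage)
  n_per <- as.integer(cfg$n_samples_per_stage)
  if (is.null(stage_multipliers) &&
      (length(stages) < 2L || sum(n_per >= 2L) < 2L)) {
    stop("need >= 2 stages with >= 2 samples each for DE exercises")
  }
  set.seed(derive_seed(cfg$seed, 22L))

  meta <- do.call(rbind, lapply(seq_along(stages), function(si) {
    data.frame(sample = sprintf("%s_%02d", stages[si], seq_len(n_per[si])),
               patient = sprintf("P%02d", seq_len(n_per[si])),
               stage = stages[si], stringsAsFactors = FALSE)
  }))

  ids <- features$feature_id
  nf <- length(ids)
  n_low <- round(cfg$low_expression_frac * nf)
  low_idx <- sample.int(nf, n_low)
  expressed_idx <- setdiff(seq_len(nf), low_idx)

  n_diff <- if (cfg$planted_fc == 1) 0L else
    round(cfg$frac_differential * nf)
  if (n_diff > length(expressed_idx)) {
    stop("frac_differential exceeds the expressed (non-tail) fraction")
  }
  diff_idx <- if (n_diff > 0L) sample(expressed_idx, n_diff) else integer(0)
  direction <- rep_len(c(1, -1), length(diff_idx))  # up, down in tumor

  base_mu <- ifelse(seq_len(nf) %in% low_idx, 0.05,
                    cfg$nb_mean * 2^runif(nf, -1, 1))

  mult <- matrix(1, nf, length(stages), dimnames = list(ids, stages))
  tumor <- setdiff(stages, "CN")
  for (k in seq_along(diff_idx)) {
    mult[diff_idx[k], tumor] <- cfg$planted_fc^direction[k]
  }
  if (!is.null(stage_multipliers)) {
    mult[rownames(stage_multipliers), colnames(stage_multipliers)] <-
      stage_multipliers
  }

  mu <- base_mu * mult[, meta$stage, drop = FALSE]
  dimnames(mu) <- list(ids, meta$sample)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = nf, dimnames = list(ids, meta$sample))

  differential <- data.frame(
    feature_id = ids[diff_idx],
    true_log2fc = direction * log2(cfg$planted_fc),
    stringsAsFactors = FALSE)
  structure(list(counts = counts, meta = meta,
                 truth = list(differential = differential,
                              low_tail_ids = ids[low_idx],
                              mu = mu)),
            class = "pi_sim_counts")
}

#' @export
print.pi_sim_counts <- function(x, ...) {
  cat(sprintf("Simulated counts: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$meta$stage), collapse = "/")))
  cat(sprintf("  planted differential: %d; low-expression tail: %d\n",
              nrow(x$truth$differential), length(x$truth$low_tail_ids)))
  invisible(x)
}

#' Emit per-sample FASTQ files from a count table
#'
#' Each known sncRNA emits its annotated sequence count-many times; each
#' planted locus distributes its count over the locus member reads
#' (uniform multinomial). Reads are written adapter-trimmed with a constant
#' quality string ("I" per base).
#'
#' @param sim a \code{pi_sim_counts}.
#' @param ref the \code{pi_reference} the counts refer to.
#' @param dir output directory for \code{<sample>.fastq} files.
#' @return invisibly, named vector of FASTQ paths (one per sample).
#' @export
emit_reads <- function(sim, ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- ref$config
  set.seed(derive_seed(cfg$seed, 33L))
  seq_of <- setNames(ref$sncrna$sequence, ref$sncrna$id)
  members <- split(ref$locus_members$sequence, ref$locus_members$locus_id)

  missing <- setdiff(rownames(sim$counts), c(names(seq_of), names(members)))
  if (length(missing) > 0L) {
    stop("no sequence known for feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }

  paths <- setNames(file.path(dir, paste0(colnames(sim$counts), ".fastq")),
                    colnames(sim$counts))
  for (s in colnames(sim$counts)) {
    recs <- character(0)
    for (f in rownames(sim$counts)) {
      n <- sim$counts[f, s]
      if (n == 0L) next
      if (f %in% names(seq_of)) {
        seqs <- rep(seq_of[[f]], n)
      } else {
        mem <- members[[f]]
        draw <- sample.int(length(mem), n, replace = TRUE)
        seqs <- mem[draw]
      }
      recs <- c(recs, as.vector(rbind(
        sprintf("@%s:%s:%d", f, s, seq_len(n)), seqs, "+",
        strrep("I", nchar(seqs)))))
    }
    writeLines(recs, paths[[s]])
  }
  invisible(paths)
}

#' Generate synthetic target transcripts
#'
#' Random transcripts with explicit region boundaries: 5'UTR is the first
#' 15% of the transcript, CDS runs to 80%, the remainder is 3'UTR.
#'
#' @param config a [sim_config()].
#' @return data.frame (transcript_id, sequence, utr5_end, cds_end, length).
#' @export
generate_transcripts <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(derive_seed(cfg$seed, 44L))
  len <- cfg$transcript_length
  data.frame(
    transcript_id = sprintf("mrna_%03d", seq_len(cfg$n_transcripts)),
    sequence = vapply(seq_len(cfg$n_transcripts),
                      function(i) random_dna(len), ""),
    utr5_end = as.integer(round(0.15 * len)),
    cds_end = as.integer(round(0.80 * len)),
    length = len, stringsAsFactors = FALSE)
}

mutate_positions <- function(seq, m) {
  if (m == 0L) return(seq)
  pos <- sample.int(nchar(seq), m)
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(BASES, cur), 1L)
  }
  seq
}

#' Plant piRNA target sites into transcripts
#'
#' For every (guide, mismatch-count) request, overwrites one 20-nt
#' transcript window with the reverse complement of the guide mutated at
#' exactly that many positions, and records the site (coordinates, true
#' mismatch count, region by window midpoint, detectability at the default
#' threshold of 3).
#'
#' @param transcripts data.frame as from [generate_transcripts()].
#' @param guides named character vector of 20-nt guides (names = piRNA ids).
#' @param config a [sim_config()]; \code{planted_site_mismatches} gives the
#'   mismatch counts planted per guide.
#' @return list with \code{transcripts} (modified) and \code{sites}
#'   (ground-truth table).
#' @export
plant_target_sites <- function(transcripts, guides, config) {
  cfg <- validate_sim_config(config)
  if (any(nchar(guides) != 20L)) stop("every guide must be exactly 20 nt")
  if (any(cfg$planted_site_mismatches > 4L)) {
    stop("planted mismatch counts beyond 4 are outside the design range")
  }
  set.seed(derive_seed(cfg$seed, 55L))

  plan <- expand.grid(guide = names(guides),
                      m = cfg$planted_site_mismatches,
                      stringsAsFactors = FALSE)
  n_tx <- nrow(transcripts)
  slot_count <- integer(n_tx)  # planted windows per transcript
  ## slot offsets (fractions of transcript length) cycle through the three
  ## regions so planted sites exercise 5'UTR, CDS and 3'UTR alike
  slot_frac <- c(0.02, 0.40, 0.85, 0.24, 0.62)
  sites <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    tx_i <- (i - 1L) %% n_tx + 1L
    slot_count[tx_i] <- slot_count[tx_i] + 1L
    if (slot_count[tx_i] > length(slot_frac)) {
      stop("transcript too short to host the requested number of sites")
    }
    ## rotate the slot sequence by transcript so every region is hit even
    ## when most transcripts host only one or two sites
    frac <- slot_frac[(tx_i - 1L + slot_count[tx_i] - 1L) %%
                        length(slot_frac) + 1L]
    start <- as.integer(round(frac * transcripts$length[tx_i]))
    if (start + 20L > transcripts$length[tx_i]) {
      stop("transcript too short to host the requested number of sites")
    }
    window <- mutate_positions(revcomp(guides[[plan$guide[i]]]), plan$m[i])
    substr(transcripts$sequence[tx_i], start + 1L, start + 20L) <- window
    mid <- start + 10L
    region <- if (mid < transcripts$utr5_end[tx_i]) "five_prime_utr"
      else if (mid < transcripts$cds_end[tx_i]) "CDS" else "three_prime_utr"
    sites[[i]] <- data.frame(
      pirna_id = plan$guide[i], transcript_id = transcripts$transcript_id[tx_i],
      start = start, end = start + 20L, mismatches = plan$m[i],
      region = region, detectable = plan$m[i] <= 3L,
      stringsAsFactors = FALSE)
  }
  list(transcripts = transcripts,
       sites = if (length(sites)) do.call(rbind, sites) else
         data.frame(pirna_id = character(), transcript_id = character(),
                    start = integer(), end = integer(),
                    mismatches = integer(), region = character(),
                    detectable = logical(), stringsAsFactors = FALSE))
}
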