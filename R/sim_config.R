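#' Simulation configuration
#'
#' Builds and validates the configuration object that drives the synthetic
#' dataset generator. The defaults emulate the design of a matched-lesion
#' liver small RNA-seq study at toy genome scale: five histological stages
#' (CN, LGDN, HGDN, eHCC, pHCC) with the study's sample counts per stage,
#' piRNA-sized reads of 25--35 nt carrying a tunable 5'-U bias,
#' negative-binomial counts with a dominant low-expression tail (81% of
#' features), and planted differential features, unannotated loci and
#' transcript target sites with recorded ground truth.
#'
#' @param seed integer seed; every downstream draw is a pure function of it.
#' @param n_contigs number of nuclear contigs in the toy genome.
#' @param contig_length length of each nuclear contig in bases.
#' @param n_genes number of gene models (5'UTR / CDS / intron / 3'UTR).
#' @param n_known_pirnas number of annotated piRNA sequences.
#' @param n_decoy_sncrnas decoy sequences per non-piRNA class
#'   (miRNA, rRNA, tRNA, snoRNA).
#' @param n_planted_loci number of unannotated piRNA-like loci written into
#'   the genome.
#' @param n_samples_per_stage named integer vector, one entry per stage.
#' @param nb_mean expected negative-binomial count for expressed features.
#' @param nb_dispersion negative-binomial dispersion (var = mu + disp*mu^2).
#' @param planted_fc fold change planted on differential features (> 0).
#' @param frac_differential fraction of features planted differential, in
#'   \[0, 1\].
#' @param low_expression_frac fraction of features assigned to the
#'   near-zero low-expression tail.
#' @param u1_prob probability that a generated piRNA-like sequence starts
#'   with T (the 5'-U bias on the read).
#' @param read_length_range integer \code{c(min, max)} for piRNA-like read
#'   lengths; must lie within \[18, 40\] and planted piRNA-like lengths
#'   within \[25, 35\].
#' @param n_transcripts number of target transcripts.
#' @param transcript_length length of each transcript in nt.
#' @param planted_site_mismatches integer vector in 0..4; one target site is
#'   planted per (guide, mismatch) request.
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 4L,
                       contig_length = 125000L,
                       n_genes = 12L,
                       n_known_pirnas = 60L,
                       n_decoy_sncrnas = 15L,
                       n_planted_loci = 40L,
                       n_samples_per_stage = c(CN = 14L, LGDN = 9L,
                                               HGDN = 6L, eHCC = 6L,
                                               pHCC = 20L),
                       nb_mean = 50,
                       nb_dispersion = 0.3,
                       planted_fc = 4,
                       frac_differential = 0.15,
                       low_expression_frac = 0.81,
                       u1_prob = 0.8,
                       read_length_range = c(25L, 35L),
                       n_transcripts = 30L,
                       transcript_length = 1000L,
                       planted_site_mismatches = c(0L, 1L, 2L, 3L)) {
  cfg <- list(seed = as.integer(seed),
              n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              n_genes = as.integer(n_genes),
              n_known_pirnas = as.integer(n_known_pirnas),
              n_decoy_sncrnas = as.integer(n_decoy_sncrnas),
              n_planted_loci = as.integer(n_planted_loci),
              n_samples_per_stage = n_samples_per_stage,
              nb_mean = nb_mean,
              nb_dispersion = nb_dispersion,
              planted_fc = planted_fc,
              frac_differential = frac_differential,
              low_expression_frac = low_expression_frac,
              u1_prob = u1_prob,
              read_length_range = as.integer(read_length_range),
              n_transcripts = as.integer(n_transcripts),
              transcript_length = as.integer(transcript_length),
              planted_site_mismatches = as.integer(planted_site_mismatches))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (length(cfg$read_length_range) != 2L ||
      cfg$read_length_range[1] > cfg$read_length_range[2]) {
    stop("read_length_range must be c(min, max) with min <= max")
  }
  if (cfg$read_length_range[1] < 18L || cfg$read_length_range[2] > 40L) {
    stop("read_length_range must lie within [18, 40]")
  }
  if (cfg$frac_differential < 0 || cfg$frac_differential > 1) {
    stop("frac_differential must be in [0, 1]")
  }
  if (cfg$low_expression_frac < 0 || cfg$low_expression_frac > 1) {
    stop("low_expression_frac must be in [0, 1]")
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$planted_fc <= 0) stop("planted_fc must be > 0")
  if (cfg$u1_prob < 0 || cfg$u1_prob > 1) stop("u1_prob must be in [0, 1]")
  if (any(cfg$planted_site_mismatches < 0L |
          cfg$planted_site_mismatches > 4L)) {
    stop("planted_site_mismatches must lie in 0..4")
  }
  if (is.null(names(cfg$n_samples_per_stage)) ||
      any(!nzchar(names(cfg$n_samples_per_stage)))) {
    stop("n_samples_per_stage must be a named vector (stage -> count)")
  }
  ## rough capacity check: each gene model needs ~700 bp plus spacing
  if (cfg$n_genes > 0L) {
    per_contig <- ceiling(cfg$n_genes / cfg$n_contigs)
    if (per_contig * 1200L > cfg$contig_length) {
      stop("contig_length too short to host the requested number of genes")
    }
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic small RNA-seq study configuration\n")
  cat(sprintf("  genome: %d nuclear contig(s) x %d bp + mitochondrial-like contig\n",
              x$n_contigs, x$contig_length))
  cat(sprintf("  annotation: %d genes, %d known piRNAs, %d decoys/class\n",
              x$n_genes, x$n_known_pirnas, x$n_decoy_sncrnas))
  cat(sprintf("  planted: %d piRNA-like loci; %.0f%% differential at FC %.1f\n",
              x$n_planted_loci, 100 * x$frac_differential, x$planted_fc))
  cat("  samples/stage:",
      paste(sprintf("%s=%d", names(x$n_samples_per_stage),
                    x$n_samples_per_stage), collapse = " "), "\n")
  cat(sprintf("  counts: NB(mean=%.1f, dispersion=%.2f), low tail %.0f%%\n",
              x$nb_mean, x$nb_dispersion, 100 * x$low_expression_frac))
  cat(sprintf("  reads: %d-%d nt, 5'-U probability %.2f\n",
              x$read_length_range[1], x$read_length_range[2], x$u1_prob))
  invisible(x)
}
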