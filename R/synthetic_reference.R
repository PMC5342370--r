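## Synthetic reference generator: toy genome, gene models, known sncRNA set,
## planted piRNA-like loci and piRNA cluster intervals, with ground truth.
##
## piRNA-like sequences are drawn from a first-order Markov chain with a mild
## same-base preference (stationary distribution uniform), a 5'-T with
## probability u1_prob, and an explicitly uniform base at position 10. The
## chain gives known piRNAs and planted loci a dinucleotide signature that a
## k-mer discriminant can learn, while keeping per-position marginals flat --
## the primary-pathway profile (5'-U bias, no 10A bias).

## P(next == prev); the remaining mass is split over the other three bases.
## 0.6 gives single 25-35 nt sequences a clearly learnable dinucleotide
## signature (likelihood-ratio separation d' ~ 2 against iid sequence)
## while keeping the per-position marginals uniform.
MARKOV_SAME <- 0.6

derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + stream) %% 2147483647)
}

markov_next <- function(prev) {
  prob <- rep((1 - MARKOV_SAME) / 3, 4)
  prob[match(prev, BASES)] <- MARKOV_SAME
  sample(BASES, 1L, prob = prob)
}

## one piRNA-like sequence; position 1 is T with probability u1_prob,
## position 10 is drawn uniformly, the rest follow the chain
pirna_like_seq <- function(len, u1_prob) {
  s <- character(len)
  s[1] <- if (runif(1) < u1_prob) "T" else sample(c("A", "C", "G"), 1L)
  for (i in seq_len(len)[-1]) {
    s[i] <- if (i == 10L) sample(BASES, 1L) else markov_next(s[i - 1L])
  }
  paste(s, collapse = "")
}

gene_feature_widths <- function() {
  ## transcription-order widths of one gene model
  data.frame(feature = c("five_prime_utr", "CDS", "intron", "CDS",
                         "intron", "CDS", "three_prime_utr"),
             width = c(60L, 90L, 150L, 90L, 120L, 60L, 80L),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic reference bundle
#'
#' Builds the toy genome (nuclear contigs plus a small mitochondrial-like
#' contig), gene models with explicit 5'UTR/CDS/intron/3'UTR intervals on
#' both strands, a known small ncRNA annotation (piRNAs plus decoy miRNA /
#' rRNA / tRNA / snoRNA classes), piRNA cluster intervals, and the planted
#' ground truth: genomic placements of every known piRNA (cycled across the
#' five context categories) and unannotated piRNA-like loci whose member
#' reads tile each locus.
#'
#' All coordinates are 0-based half-open (BED convention). Byte-identical
#' output is guaranteed for a given config (seed included).
#'
#' @param config a [sim_config()] object.
#' @return an object of class \code{pi_reference}: a list with elements
#'   \code{genome} (named character vector of contig sequences),
#'   \code{contig_class}, \code{gene_models}, \code{sncrna},
#'   \code{clusters}, \code{pirna_placements}, \code{loci},
#'   \code{locus_members} and \code{config}.
#' @export
generate_reference <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(derive_seed(cfg$seed, 11L))

  contigs <- paste0("contig_", seq_len(cfg$n_contigs))
  genome <- vapply(contigs, function(x) random_dna(cfg$contig_length), "")
  mt_len <- 2000L
  genome <- c(genome, contig_MT = random_dna(mt_len))
  contig_class <- c(setNames(rep("nuclear", cfg$n_contigs), contigs),
                    contig_MT = "mitochondrial-like")

  ## --- gene models -------------------------------------------------------
  widths <- gene_feature_widths()
  span <- sum(widths$width)
  gm <- NULL
  if (cfg$n_genes > 0L) {
    rows <- vector("list", cfg$n_genes)
    for (g in seq_len(cfg$n_genes)) {
      contig <- contigs[(g - 1L) %% cfg$n_contigs + 1L]
      slot <- (g - 1L) %/% cfg$n_contigs
      gstart <- 1000L + slot * 1500L
      if (gstart + span > cfg$contig_length) {
        stop("contig too short to host requested genes")
      }
      strand <- if (g %% 2L == 0L) "-" else "+"
      w <- if (strand == "+") widths else widths[rev(seq_len(nrow(widths))), ]
      ends <- gstart + cumsum(w$width)
      starts <- ends - w$width
      rows[[g]] <- data.frame(contig = contig, start = starts, end = ends,
                              strand = strand, feature = w$feature,
                              transcript_id = sprintf("tx_%02d", g),
                              gene_id = sprintf("gene_%02d", g),
                              stringsAsFactors = FALSE)
    }
    gm <- do.call(rbind, rows)
  } else {
    gm <- data.frame(contig = character(), start = integer(),
                     end = integer(), strand = character(),
                     feature = character(), transcript_id = character(),
                     gene_id = character(), stringsAsFactors = FALSE)
  }

  ## --- clusters (germline piRNA cluster stand-ins, intergenic) -----------
  clusters <- data.frame(
    contig = contigs[seq_len(min(2L, cfg$n_contigs))],
    start = 80000L, end = 83000L,
    name = sprintf("cluster_%d", seq_len(min(2L, cfg$n_contigs))),
    score = 0L, strand = ".", stringsAsFactors = FALSE)
  clusters <- clusters[clusters$end <= cfg$contig_length, , drop = FALSE]

  ## intergenic slot allocator: one 200-bp slot per planted element, placed
  ## well away from the gene blocks and (by default) from the clusters
  ig_counter <- setNames(rep(0L, length(contigs)), contigs)
  next_ig_slot <- function(contig) {
    ig_counter[contig] <<- ig_counter[contig] + 1L
    20000L + (ig_counter[contig] - 1L) * 200L
  }
  mt_counter <- 0L
  next_mt_slot <- function() {
    mt_counter <<- mt_counter + 1L
    100L + (mt_counter - 1L) * 100L
  }

  plant <- function(contig, start, fwd_seq) {
    stopifnot(start + nchar(fwd_seq) <= nchar(genome[[contig]]))
    substr(genome[[contig]], start + 1L, start + nchar(fwd_seq)) <<- fwd_seq
  }

  ## --- known piRNAs planted across context categories --------------------
  categories <- c("five_prime_utr", "CDS", "intron", "three_prime_utr",
                  "intergenic")
  region_pool <- lapply(categories[1:4], function(cat) {
    idx <- which(gm$feature == cat)
    idx[sample.int(length(idx))]
  })
  names(region_pool) <- categories[1:4]
  pool_ptr <- setNames(rep(0L, 4L), categories[1:4])

  pir_rows <- vector("list", cfg$n_known_pirnas)
  pir_seqs <- character(cfg$n_known_pirnas)
  for (i in seq_len(cfg$n_known_pirnas)) {
    len <- sample(25:35, 1L)
    s <- pirna_like_seq(len, cfg$u1_prob)
    pir_seqs[i] <- s
    id <- sprintf("piR_L%04d", i)
    cat <- categories[(i - 1L) %% 5L + 1L]
    if (cat != "intergenic") {
      pool_ptr[cat] <- pool_ptr[cat] + 1L
      if (pool_ptr[cat] > length(region_pool[[cat]])) cat <- "intergenic"
    }
    if (cat == "intergenic") {
      contig <- contigs[(i - 1L) %% cfg$n_contigs + 1L]
      start <- next_ig_slot(contig)
      strand <- sample(c("+", "-"), 1L)
      tx <- ""
    } else {
      reg <- gm[region_pool[[cat]][pool_ptr[cat]], ]
      contig <- reg$contig
      start <- reg$start + 5L
      strand <- reg$strand   # sense to the host transcript
      tx <- reg$transcript_id
    }
    fwd <- if (strand == "+") s else revcomp(s)
    plant(contig, start, fwd)
    pir_rows[[i]] <- data.frame(pirna_id = id, contig = contig,
                                start = start, end = start + len,
                                strand = strand, category = cat,
                                host_transcript = tx,
                                stringsAsFactors = FALSE)
  }
  pirna_placements <- if (cfg$n_known_pirnas > 0L) {
    do.call(rbind, pir_rows)
  } else {
    data.frame(pirna_id = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               category = character(), host_transcript = character(),
               stringsAsFactors = FALSE)
  }

  ## --- decoy sncRNAs ------------------------------------------------------
  decoy_len <- list(miRNA = 21:23, rRNA = 30:40, tRNA = 18:22,
                    snoRNA = 25:33)
  snc <- data.frame(id = sprintf("piR_L%04d", seq_len(cfg$n_known_pirnas)),
                    class = rep("piRNA", cfg$n_known_pirnas),
                    sequence = pir_seqs, stringsAsFactors = FALSE)
  for (cl in names(decoy_len)) {
    if (cfg$n_decoy_sncrnas > 0L) {
      seqs <- vapply(seq_len(cfg$n_decoy_sncrnas), function(i) {
        random_dna(sample(decoy_len[[cl]], 1L))
      }, "")
      snc <- rbind(snc, data.frame(
        id = sprintf("%s_%03d", tolower(cl), seq_len(cfg$n_decoy_sncrnas)),
        class = cl, sequence = seqs, stringsAsFactors = FALSE))
    }
  }
  ## exact-match duplicates across the set would be ambiguous; drop them
  snc <- snc[!duplicated(snc$sequence), , drop = FALSE]

  ## --- planted piRNA-like loci -------------------------------------------
  min_rd <- max(25L, cfg$read_length_range[1])
  max_rd <- min(35L, cfg$read_length_range[2])
  n_mt <- if (cfg$n_planted_loci >= 20L) {
    max(1L, floor(0.05 * cfg$n_planted_loci))
  } else 0L
  in_cluster_locus <- cfg$n_planted_loci >= 20L && nrow(clusters) > 0L

  loci_rows <- vector("list", cfg$n_planted_loci)
  member_rows <- list()
  for (j in seq_len(cfg$n_planted_loci)) {
    on_mt <- j > cfg$n_planted_loci - n_mt
    if (on_mt) {
      contig <- "contig_MT"
      start <- next_mt_slot()
    } else if (in_cluster_locus && j == 1L) {
      contig <- clusters$contig[1]
      start <- clusters$start[1] + 500L
    } else {
      contig <- contigs[(j - 1L) %% cfg$n_contigs + 1L]
      start <- next_ig_slot(contig)
    }
    locus_len <- sample(40:60, 1L)
    strand <- sample(c("+", "-"), 1L)
    lseq <- pirna_like_seq(locus_len, 0)   # chain only; 5'-T forced per read

    ## member read offsets tile the locus; first at 0, last ends at locus end
    n_var <- sample(3:5, 1L)
    starts <- unique(as.integer(round(seq(0L, locus_len - min_rd,
                                          length.out = n_var))))
    lens <- vapply(starts, function(st) {
      min(sample(min_rd:max_rd, 1L), locus_len - st)
    }, integer(1))
    lens[length(lens)] <- locus_len - starts[length(starts)]

    ## impose the 5'-U rule at each member read start (strand-aware):
    ## T with probability u1_prob, otherwise uniform over {A,C,G} -- the
    ## same rule the known-piRNA generator uses, so the read-level 5'-T
    ## fraction equals u1_prob exactly
    for (k in seq_along(starts)) {
      b <- if (runif(1) < cfg$u1_prob) "T" else sample(c("A", "C", "G"), 1L)
      if (strand == "+") {
        substr(lseq, starts[k] + 1L, starts[k] + 1L) <- b
      } else {
        pos <- starts[k] + lens[k]       # read 5' end on the minus strand
        substr(lseq, pos, pos) <- chartr("ACGT", "TGCA", b)
      }
    }
    plant(contig, start, lseq)

    member_seq <- vapply(seq_along(starts), function(k) {
      sub <- substr(lseq, starts[k] + 1L, starts[k] + lens[k])
      if (strand == "+") sub else revcomp(sub)
    }, "")
    locus_id <- sprintf("locus_truth_%02d", j)
    loci_rows[[j]] <- data.frame(
      locus_id = locus_id, contig = contig, start = start,
      end = start + locus_len, strand = strand,
      is_mito = contig_class[[contig]] == "mitochondrial-like",
      stringsAsFactors = FALSE)
    member_rows[[j]] <- data.frame(
      locus_id = locus_id, member = seq_along(starts),
      sequence = member_seq, stringsAsFactors = FALSE)
  }
  loci <- if (cfg$n_planted_loci > 0L) do.call(rbind, loci_rows) else
    data.frame(locus_id = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               is_mito = logical(), stringsAsFactors = FALSE)
  locus_members <- if (cfg$n_planted_loci > 0L) do.call(rbind, member_rows)
    else data.frame(locus_id = character(), member = integer(),
                    sequence = character(), stringsAsFactors = FALSE)

  structure(list(genome = genome, contig_class = contig_class,
                 gene_models = gm, sncrna = snc, clusters = clusters,
                 pirna_placements = pirna_placements, loci = loci,
                 locus_members = locus_members, config = cfg),
            class = "pi_reference")
}

#' @export
print.pi_reference <- function(x, ...) {
  cat("Synthetic reference bundle\n")
  cat(sprintf("  contigs: %d (%s bp total), %d mitochondrial-like\n",
              length(x$genome),
              format(sum(nchar(x$genome)), big.mark = ","),
              sum(x$contig_class == "mitochondrial-like")))
  cat(sprintf("  gene models: %d transcripts, %d feature intervals\n",
              length(unique(x$gene_models$transcript_id)),
              nrow(x$gene_models)))
  cat(sprintf("  known sncRNAs: %d (%d piRNA)\n", nrow(x$sncrna),
              sum(x$sncrna$class == "piRNA")))
  cat(sprintf("  planted piRNA-like loci: %d (%d mitochondrial)\n",
              nrow(x$loci), sum(x$loci$is_mito)))
  invisible(x)
}

#' Write a reference bundle to disk
#'
#' Emits the genome FASTA, known sncRNA FASTA (headers \code{>ID|CLASS}),
#' gene-model table, cluster BED6 and ground-truth tables as plain text.
#'
#' @param ref a \code{pi_reference}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             sncrna = file.path(dir, "sncrna.fa"),
             gene_models = file.path(dir, "gene_models.tsv"),
             clusters = file.path(dir, "clusters.bed"),
             pirna_placements = file.path(dir, "truth_pirna_placements.tsv"),
             loci = file.path(dir, "truth_loci.bed"))
  writeLines(as.vector(rbind(paste0(">", names(ref$genome)), ref$genome)),
             paths[["genome"]])
  writeLines(as.vector(rbind(paste0(">", ref$sncrna$id, "|",
                                    ref$sncrna$class),
                             ref$sncrna$sequence)), paths[["sncrna"]])
  write_tsv(ref$gene_models, paths[["gene_models"]])
  writeLines(with(ref$clusters, sprintf("%s\t%d\t%d\t%s\t%d\t%s", contig,
                                        start, end, name, score, strand)),
             paths[["clusters"]])
  write_tsv(ref$pirna_placements, paths[["pirna_placements"]])
  writeLines(with(ref$loci, sprintf("%s\t%d\t%d\t%s\t%d\t%s", contig, start,
                                    end, locus_id, 0L, strand)),
             paths[["loci"]])
  invisible(paths)
}
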