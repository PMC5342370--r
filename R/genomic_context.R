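## Genomic-context annotation of piRNA placements and piR_LLi loci:
## 5'UTR/CDS/3'UTR/intron/intergenic category with exon-over-intron
## precedence, sense/antisense orientation, piRNA-cluster membership and
## nuclear vs mitochondrial-like contig class.

CATEGORY_RANK <- c(five_prime_utr = 1L, CDS = 2L, three_prime_utr = 3L,
                   intron = 4L, intergenic = 5L)

#' Annotate genomic placements against gene models
#'
#' Each placement receives exactly one category by overlap with the gene
#' models, requiring at least 50% of the placement inside the region, with
#' precedence exonic (5'UTR > CDS > 3'UTR) > intron > intergenic.
#' Orientation is sense when the placement strand equals the host
#' transcript strand; intergenic placements have no host and orientation
#' NA. Cluster membership is any overlap with the cluster intervals.
#'
#' @param placements data.frame: feature_id, contig, start, end, strand
#'   (0-based half-open).
#' @param gene_models data.frame: contig, start, end, strand, feature
#'   (five_prime_utr / CDS / intron / three_prime_utr), transcript_id.
#' @param clusters optional data.frame: contig, start, end.
#' @param contig_class optional named vector contig -> class.
#' @param contig_lengths optional named vector for coordinate validation.
#' @return data.frame of \code{ContextAnnotation} rows: placement columns
#'   plus category, host_transcript, orientation, in_cluster,
#'   contig_class.
#' @export
annotate_placement <- function(placements, gene_models, clusters = NULL,
                               contig_class = NULL,
                               contig_lengths = NULL) {
  if (!is.null(contig_lengths)) {
    bad <- !(placements$contig %in% names(contig_lengths)) |
      placements$end > contig_lengths[placements$contig] |
      placements$start < 0L
    if (any(bad)) {
      stop("placement outside contig bounds: ",
           paste(placements$feature_id[bad][1], collapse = ", "))
    }
  }
  np <- nrow(placements)
  category <- rep("intergenic", np)
  host <- rep("", np)
  orientation <- rep(NA_character_, np)

  if (nrow(gene_models) > 0L && np > 0L) {
    pg <- GenomicRanges::GRanges(
      placements$contig,
      IRanges::IRanges(placements$start + 1L, placements$end),
      strand = placements$strand)
    rg <- GenomicRanges::GRanges(
      gene_models$contig,
      IRanges::IRanges(gene_models$start + 1L, gene_models$end),
      strand = gene_models$strand)
    hits <- GenomicRanges::findOverlaps(pg, rg, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ovl <- GenomicRanges::width(GenomicRanges::pintersect(
      pg[qh], rg[sh], ignore.strand = TRUE))
    enough <- ovl >= 0.5 * GenomicRanges::width(pg)[qh]
    qh <- qh[enough]
    sh <- sh[enough]
    if (length(qh) > 0L) {
      rank <- CATEGORY_RANK[gene_models$feature[sh]]
      o <- order(qh, rank, sh)
      best <- o[!duplicated(qh[o])]
      category[qh[best]] <- gene_models$feature[sh[best]]
      host[qh[best]] <- gene_models$transcript_id[sh[best]]
      orientation[qh[best]] <- ifelse(
        placements$strand[qh[best]] == gene_models$strand[sh[best]],
        "sense", "antisense")
    }
  }

  in_cluster <- rep(FALSE, np)
  if (!is.null(clusters) && nrow(clusters) > 0L && np > 0L) {
    pg <- GenomicRanges::GRanges(
      placements$contig,
      IRanges::IRanges(placements$start + 1L, placements$end))
    cg <- GenomicRanges::GRanges(
      clusters$contig, IRanges::IRanges(clusters$start + 1L, clusters$end))
    in_cluster <- GenomicRanges::countOverlaps(pg, cg,
                                               ignore.strand = TRUE) > 0L
  }

  cc <- if (is.null(contig_class)) rep("nuclear", np) else
    unname(contig_class[placements$contig])
  cbind(placements,
        data.frame(category = category, host_transcript = host,
                   orientation = orientation, in_cluster = in_cluster,
                   contig_class = cc, stringsAsFactors = FALSE))
}

#' Summarise context annotations
#'
#' Per-placement distribution tables (category, orientation within
#' category, cluster membership, per-contig, contig class) and a
#' per-feature table where every feature is assigned its precedence-best
#' placement category.
#'
#' @param annotations data.frame from [annotate_placement()].
#' @return list of data.frames: \code{by_category},
#'   \code{orientation_by_category}, \code{cluster}, \code{per_contig},
#'   \code{by_contig_class}, \code{per_feature},
#'   \code{per_feature_category}.
#' @export
context_summary <- function(annotations) {
  n <- nrow(annotations)
  cat_tab <- as.data.frame(table(category = annotations$category),
                           stringsAsFactors = FALSE)
  names(cat_tab)[2] <- "count"
  cat_tab$percent <- 100 * cat_tab$count / max(n, 1L)

  intr <- annotations[annotations$category != "intergenic", , drop = FALSE]
  ori_tab <- as.data.frame(table(category = intr$category,
                                 orientation = intr$orientation),
                           stringsAsFactors = FALSE)
  names(ori_tab)[3] <- "count"

  cluster_tab <- data.frame(
    in_cluster = c(TRUE, FALSE),
    count = c(sum(annotations$in_cluster), sum(!annotations$in_cluster)),
    stringsAsFactors = FALSE)
  cluster_tab$percent <- 100 * cluster_tab$count / max(n, 1L)

  contig_tab <- as.data.frame(table(contig = annotations$contig),
                              stringsAsFactors = FALSE)
  names(contig_tab)[2] <- "count"
  class_tab <- as.data.frame(table(contig_class =
                                     annotations$contig_class),
                             stringsAsFactors = FALSE)
  names(class_tab)[2] <- "count"

  ## per-feature: precedence-best placement
  rank <- CATEGORY_RANK[annotations$category]
  o <- order(annotations$feature_id, rank, method = "radix")
  per_feature <- annotations[o, , drop = FALSE]
  per_feature <- per_feature[!duplicated(per_feature$feature_id), ,
                             drop = FALSE]
  pf_tab <- as.data.frame(table(category = per_feature$category),
                          stringsAsFactors = FALSE)
  names(pf_tab)[2] <- "count"
  pf_tab$percent <- 100 * pf_tab$count / max(nrow(per_feature), 1L)

  list(by_category = cat_tab, orientation_by_category = ori_tab,
       cluster = cluster_tab, per_contig = contig_tab,
       by_contig_class = class_tab, per_feature = per_feature,
       per_feature_category = pf_tab)
}
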