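## End-to-end orchestration: simulate -> classify -> discover -> normalize
## -> de -> stages -> features -> context -> targets -> cluster, with TSV
## outputs, per-stage logging to stderr and a JSON manifest. Every stage is
## a pure function of the config (seed included), so reruns are
## byte-identical.

PIPELINE_STAGES <- c("simulate", "classify", "discover", "normalize", "de",
                     "stages", "features", "context", "targets", "cluster")

stage_log <- function(name, fmt, ...) {
  message(sprintf("[%s] %s", name, sprintf(fmt, ...)))
}

run_stage <- function(name, fun) {
  tryCatch(fun(), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, row.names = NULL,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Run the full profiling pipeline on a synthetic study
#'
#' Executes simulate, classify, discover, normalize, de, stages, features,
#' context, targets and cluster in order, writing plain-text outputs and a
#' JSON manifest under \code{out_dir}. Differential expression compares CN
#' against pHCC; known piRNAs and piR_LLi loci are adjusted separately.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param upto run stages up to and including this one (default: all).
#' @param fc_threshold,fdr_threshold signature thresholds.
#' @param score_threshold k-mer discriminant retention threshold.
#' @param merge_distance locus merge distance in bases.
#' @param max_placements genomic placement cap per candidate.
#' @param discovery_window length window for the unannotated pool.
#' @param rpm_filter_threshold low-expression filter (mean RPM per group).
#' @param high_rpm_cutoff very-high-expression flag cutoff.
#' @return invisibly, an object of class \code{pi_pipeline} with all
#'   intermediate results.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         upto = "cluster", fc_threshold = 1.5,
                         fdr_threshold = 0.05, score_threshold = 0.5,
                         merge_distance = 0L, max_placements = 30L,
                         discovery_window = c(25L, 35L),
                         rpm_filter_threshold = 1, high_rpm_cutoff = 5000) {
  stopifnot(upto %in% PIPELINE_STAGES)
  stages_to_run <- PIPELINE_STAGES[seq_len(match(upto, PIPELINE_STAGES))]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "pirliver",
    version = as.character(utils::packageVersion("pirliver")),
    seed = config$seed,
    thresholds = list(fc = fc_threshold, fdr = fdr_threshold,
                      score = score_threshold,
                      merge_distance = merge_distance,
                      max_placements = max_placements,
                      rpm_filter = rpm_filter_threshold,
                      high_rpm = high_rpm_cutoff),
    notes = paste("Ward linkage applied to the 1 - Kendall tau-b",
                  "dissimilarity directly (non-Euclidean approximation);",
                  "BH adjustment per feature family."),
    stages = list())
  res <- list(config = config)

  note_stage <- function(name, n) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, records = n)
  }

  ## --- simulate ----------------------------------------------------------
  if ("simulate" %in% stages_to_run) run_stage("simulate", function() {
    res$ref <<- generate_reference(config)
    write_reference(res$ref, file.path(out_dir, "reference"))
    feats <- sim_feature_table(res$ref)
    res$sim <<- simulate_counts(config, feats)
    res$fastqs <<- emit_reads(res$sim, res$ref, file.path(out_dir, "reads"))
    tx <- generate_transcripts(config)
    pir_seqs <- setNames(res$ref$sncrna$sequence,
                         res$ref$sncrna$id)[res$ref$sncrna$class == "piRNA"]
    g <- extract_guides(pir_seqs)
    ## plant sites for differential piRNAs first: those drive the
    ## signature whose guides the targets stage searches
    diff_first <- intersect(res$sim$truth$differential$feature_id,
                            names(g$guides))
    pick <- c(diff_first, setdiff(names(g$guides), diff_first))
    planted_guides <- g$guides[pick[seq_len(min(10L, length(pick)))]]
    res$planted <<- plant_target_sites(tx, planted_guides, config)
    matrix_tsv(res$sim$counts, file.path(out_dir, "truth_counts.tsv"))
    write_tsv(res$sim$meta, file.path(out_dir, "sample_sheet.tsv"))
    write_tsv(res$sim$truth$differential,
              file.path(out_dir, "truth_differential.tsv"))
    write_tsv(res$planted$sites, file.path(out_dir, "truth_sites.tsv"))
    write_tsv(res$planted$transcripts[, c("transcript_id", "utr5_end",
                                          "cds_end", "length")],
              file.path(out_dir, "transcript_regions.tsv"))
    writeLines(as.vector(rbind(
      paste0(">", res$planted$transcripts$transcript_id),
      res$planted$transcripts$sequence)),
      file.path(out_dir, "transcripts.fa"))
    stage_log("simulate", "%d features, %d samples, %d transcripts",
              nrow(res$sim$counts), ncol(res$sim$counts), nrow(tx))
    note_stage("simulate", nrow(res$sim$counts))
  })

  ## --- classify ----------------------------------------------------------
  if ("classify" %in% stages_to_run) run_stage("classify", function() {
    idx <- annotation_index(res$ref$sncrna)
    col <- collapse_fastq(res$fastqs)
    res$collapsed <<- assign_classes(col, idx)
    groups <- setNames(res$sim$meta$stage, res$sim$meta$sample)
    res$pirna <<- pirna_count_matrix(res$collapsed, groups)
    matrix_tsv(res$pirna$matrix, file.path(out_dir, "pirna_counts.tsv"),
               "pirna_id")
    write_tsv(class_count_summary(res$collapsed),
              file.path(out_dir, "class_counts.tsv"))
    write_tsv(res$collapsed$discards, file.path(out_dir, "discards.tsv"))
    stage_log("classify", "%d unique sequences, %d known piRNAs detected",
              nrow(res$collapsed$counts), nrow(res$pirna$matrix))
    note_stage("classify", nrow(res$collapsed$counts))
  })

  ## --- discover ----------------------------------------------------------
  if ("discover" %in% stages_to_run) run_stage("discover", function() {
    pool <- unannotated_pool(res$collapsed, discovery_window)
    pir_seqs <- res$ref$sncrna$sequence[res$ref$sncrna$class == "piRNA"]
    decoys <- res$ref$sncrna$sequence[res$ref$sncrna$class != "piRNA"]
    scored <- score_pirna_like(rownames(pool), pir_seqs, decoys,
                               threshold = score_threshold,
                               seed = config$seed)
    retained <- scored$sequence[scored$retained]
    mapped <- map_candidates(retained, res$ref$genome,
                             max_placements = max_placements)
    res$loci <<- build_loci(mapped$alignments,
                            pool[retained, , drop = FALSE],
                            merge_distance = merge_distance,
                            contig_class = res$ref$contig_class)
    res$mapped <<- mapped
    write_tsv(scored, file.path(out_dir, "discovery_scores.tsv"))
    writeLines(with(res$loci$loci,
                    sprintf("%s\t%d\t%d\t%s\t%d\t%s", contig, start, end,
                            locus_id, as.integer(total_coverage), strand)),
               file.path(out_dir, "pirlli_loci.bed"))
    matrix_tsv(res$loci$coverage, file.path(out_dir, "pirlli_coverage.tsv"),
               "locus_id")
    write_tsv(data.frame(sequence = mapped$unmapped),
              file.path(out_dir, "unmapped.tsv"))
    stage_log("discover", "%d candidates scored, %d retained, %d loci",
              nrow(scored), length(retained), nrow(res$loci$loci))
    note_stage("discover", nrow(res$loci$loci))
  })

  ## --- normalize ---------------------------------------------------------
  if ("normalize" %in% stages_to_run) run_stage("normalize", function() {
    combined <- rbind(res$pirna$matrix, res$loci$coverage)
    res$rpm <<- normalize_rpm(combined, res$collapsed$library_sizes)
    sheet <- res$sim$meta
    sheet$library_size <-
      unname(res$collapsed$library_sizes[sheet$sample])
    write_tsv(sheet, file.path(out_dir, "sample_sheet_libsize.tsv"))
    matrix_tsv(res$rpm, file.path(out_dir, "rpm.tsv"))
    stage_log("normalize", "%d features normalized to RPM", nrow(res$rpm))
    note_stage("normalize", nrow(res$rpm))
  })

  ## --- de ----------------------------------------------------------------
  if ("de" %in% stages_to_run) run_stage("de", function() {
    groups <- setNames(res$sim$meta$stage, res$sim$meta$sample)
    filt <- filter_low_expression(res$rpm, groups, rpm_filter_threshold)
    res$retained <<- filt$retained
    write_tsv(filt$removed, file.path(out_dir, "filtered_out.tsv"))
    cn <- res$sim$meta$sample[res$sim$meta$stage == "CN"]
    hcc <- res$sim$meta$sample[res$sim$meta$stage == "pHCC"]
    fam <- list(pirna = intersect(filt$retained,
                                  rownames(res$pirna$matrix)),
                pirlli = intersect(filt$retained,
                                   rownames(res$loci$coverage)))
    res$de <<- lapply(fam, function(ids) {
      if (length(ids) == 0L) return(NULL)
      wilcoxon_de(res$rpm[ids, , drop = FALSE], cn, hcc,
                  fc_threshold, fdr_threshold)
    })
    for (f in names(res$de)) {
      if (!is.null(res$de[[f]])) {
        write_tsv(res$de[[f]], file.path(out_dir,
                                         sprintf("de_%s.tsv", f)))
      }
    }
    high <- flag_high_expression(res$rpm[filt$retained, , drop = FALSE],
                                 groups, high_rpm_cutoff)
    res$high <<- high
    write_tsv(data.frame(feature_id = high$flagged,
                         stringsAsFactors = FALSE),
              file.path(out_dir, "high_expression.tsv"))
    n_sig <- sum(vapply(res$de, function(d) {
      if (is.null(d)) 0L else sum(d$in_signature)
    }, integer(1)))
    stage_log("de", "%d retained, %d in signatures", length(filt$retained),
              n_sig)
    note_stage("de", n_sig)
  })

  ## --- stages ------------------------------------------------------------
  if ("stages" %in% stages_to_run) run_stage("stages", function() {
    have <- intersect(c("CN", "LGDN", "HGDN", "eHCC", "pHCC"),
                      unique(res$sim$meta$stage))
    if (length(have) >= 3L) {
      pat <- stage_patterns(res$rpm[res$retained, , drop = FALSE],
                            res$sim$meta, stages = have)
      res$patterns <<- pat
      write_tsv(pat, file.path(out_dir, "stage_patterns.tsv"))
      stage_log("stages", "%d features classified into patterns",
                nrow(pat))
      note_stage("stages", nrow(pat))
    } else {
      stage_log("stages", "skipped: fewer than 3 stages present")
      note_stage("stages", 0L)
    }
  })

  ## --- features ----------------------------------------------------------
  if ("features" %in% stages_to_run) run_stage("features", function() {
    pir_ids <- rownames(res$pirna$matrix)
    pir_seq <- setNames(res$ref$sncrna$sequence,
                        res$ref$sncrna$id)[pir_ids]
    rep_seq <- res$loci$loci$representative_sequence
    seqs <- c(unname(pir_seq), rep_seq)
    ## unweighted: the repertoire logo; read copies of one molecule are
    ## not independent draws of its 5' base
    comp <- positional_composition(seqs)
    res$biogenesis <<- biogenesis_signature(seqs)
    write_tsv(as.data.frame(comp), file.path(out_dir, "composition.tsv"))
    write_tsv(res$biogenesis, file.path(out_dir, "biogenesis.tsv"))
    stage_log("features", "composition over %d sequences", length(seqs))
    note_stage("features", length(seqs))
  })

  ## --- context -----------------------------------------------------------
  if ("context" %in% stages_to_run) run_stage("context", function() {
    pir_ids <- rownames(res$pirna$matrix)
    pir_seq <- setNames(res$ref$sncrna$sequence,
                        res$ref$sncrna$id)[pir_ids]
    pmap <- map_candidates(unname(pir_seq), res$ref$genome,
                           max_placements = max_placements)
    aln <- pmap$alignments
    aln$feature_id <- pir_ids[match(aln$sequence, unname(pir_seq))]
    placements <- rbind(
      aln[, c("feature_id", "contig", "start", "end", "strand")],
      data.frame(feature_id = res$loci$loci$locus_id,
                 contig = res$loci$loci$contig,
                 start = res$loci$loci$start, end = res$loci$loci$end,
                 strand = res$loci$loci$strand, stringsAsFactors = FALSE))
    ann <- annotate_placement(placements, res$ref$gene_models,
                              res$ref$clusters, res$ref$contig_class,
                              nchar(res$ref$genome))
    res$context <<- context_summary(ann)
    write_tsv(ann, file.path(out_dir, "context_annotations.tsv"))
    write_tsv(res$context$by_category,
              file.path(out_dir, "context_by_category.tsv"))
    write_tsv(res$context$per_feature_category,
              file.path(out_dir, "context_per_feature.tsv"))
    stage_log("context", "%d placements annotated", nrow(ann))
    note_stage("context", nrow(ann))
  })

  ## --- targets -----------------------------------------------------------
  if ("targets" %in% stages_to_run) run_stage("targets", function() {
    sig_ids <- unlist(lapply(res$de, function(d) {
      if (is.null(d)) character(0) else d$feature_id[d$in_signature]
    }), use.names = FALSE)
    pir_seq <- setNames(res$ref$sncrna$sequence, res$ref$sncrna$id)
    loc_seq <- setNames(res$loci$loci$representative_sequence,
                        res$loci$loci$locus_id)
    all_seq <- c(pir_seq, loc_seq)
    g <- extract_guides(all_seq[intersect(sig_ids, names(all_seq))])
    res$sites <<- find_all_sites(g$guides, res$planted$transcripts)
    res$target_summary <<- target_summary(res$sites)
    write_tsv(res$sites, file.path(out_dir, "target_sites.tsv"))
    write_tsv(res$target_summary$by_region,
              file.path(out_dir, "targets_by_region.tsv"))
    stage_log("targets", "%d guides searched, %d sites in %d transcripts",
              length(g$guides), nrow(res$sites),
              res$target_summary$n_target_transcripts)
    note_stage("targets", nrow(res$sites))
  })

  ## --- cluster -----------------------------------------------------------
  if ("cluster" %in% stages_to_run) run_stage("cluster", function() {
    sig_ids <- unlist(lapply(res$de, function(d) {
      if (is.null(d)) character(0) else d$feature_id[d$in_signature]
    }), use.names = FALSE)
    feat <- if (length(sig_ids) >= 2L) sig_ids else res$retained
    samples <- res$sim$meta$sample[res$sim$meta$stage %in%
                                     c("CN", "pHCC")]
    m <- res$rpm[feat, samples, drop = FALSE]
    d <- kendall_distance(m)
    res$clust <<- ward_cluster(d)
    cluster_newick(res$clust, file.path(out_dir, "dendrogram.nwk"))
    heat <- export_heatmap_table(res$rpm, feat)
    matrix_tsv(heat, file.path(out_dir, "heatmap_table.tsv"))
    labels <- res$clust$labels_at(2)
    write_tsv(data.frame(sample = names(labels), cluster = labels,
                         row.names = NULL, stringsAsFactors = FALSE),
              file.path(out_dir, "clusters_k2.tsv"))
    stage_log("cluster", "%d samples clustered on %d features",
              length(samples), length(feat))
    note_stage("cluster", length(samples))
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  class(res) <- "pi_pipeline"
  invisible(res)
}

#' @export
print.pi_pipeline <- function(x, ...) {
  cat("pirliver pipeline result\n")
  if (!is.null(x$sim)) {
    cat(sprintf("  %d features x %d samples simulated\n",
                nrow(x$sim$counts), ncol(x$sim$counts)))
  }
  if (!is.null(x$loci)) cat(sprintf("  %d piR_LLi loci\n",
                                    nrow(x$loci$loci)))
  if (!is.null(x$de)) {
    for (f in names(x$de)) {
      if (!is.null(x$de[[f]])) {
        cat(sprintf("  %s signature: %d features\n", f,
                    sum(x$de[[f]]$in_signature)))
      }
    }
  }
  invisible(x)
}
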