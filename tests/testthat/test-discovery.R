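# k-mer discriminant scoring, exact-match genome placement, locus building.

test_that("scoring is deterministic and keeps held-in positives", {
  cfg <- small_config(seed = 21)
  ref <- generate_reference(cfg)
  pos <- ref$sncrna$sequence[ref$sncrna$class == "piRNA"]
  neg <- ref$sncrna$sequence[ref$sncrna$class != "piRNA"]
  s1 <- score_pirna_like(pos, pos, neg)
  s2 <- score_pirna_like(pos, pos, neg)
  expect_identical(s1, s2)
  expect_true(all(s1$score >= 0 & s1$score <= 1))
  expect_gt(mean(s1$retained), 0.9)
})

test_that("discriminant separates piRNA-like from shuffled sequence", {
  set.seed(301)
  pos <- vapply(1:500, function(i) {
    pirliver:::pirna_like_seq(sample(25:35, 1), 0.8)
  }, "")
  neg <- vapply(pos, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
  train <- 1:250
  sc <- score_pirna_like(c(pos[-train], neg[-train]),
                         pos[train], neg[train])
  lab <- rep(c(1, 0), each = 250)
  r <- rank(sc$score)
  auc <- (sum(r[lab == 1]) - 250 * 251 / 2) / (250 * 250)
  expect_gt(auc, 0.8)
})

test_that("training-set minimum is enforced", {
  expect_error(score_pirna_like("ACGT", c("ACGT", "GGTT"), c("TTAA"),
                                min_train = 10),
               "training")
})

test_that("exact placements are found on both strands and capped", {
  set.seed(77)
  cand <- random_seq(30)
  pal <- "ACGTACGTAATTACGTACGT"  # reverse-complement palindrome
  left <- random_seq(500)
  genome <- c(chr1 = paste0(left, cand, random_seq(200), pal,
                            random_seq(100)))
  res <- map_candidates(c(cand, pal, random_seq(30)), genome)
  aln <- res$alignments
  one <- aln[aln$sequence == cand, ]
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 500L)
  expect_equal(one$end, 530L)
  expect_equal(one$strand, "+")
  both <- aln[aln$sequence == pal, ]
  expect_setequal(both$strand, c("-", "+"))
  expect_equal(unique(both$start), 730L)
  expect_equal(length(res$unmapped), 1L)
  # cap: a sequence repeated beyond max_placements is dropped with report
  rep_seq <- random_seq(25)
  genome2 <- c(chr1 = paste(c(replicate(5, random_seq(50)),
                              rep(rep_seq, 4)), collapse = ""))
  res2 <- map_candidates(rep_seq, genome2, max_placements = 3L)
  expect_equal(res2$overmapped, rep_seq)
  expect_equal(nrow(res2$alignments), 0L)
})

test_that("locus merging follows interval arithmetic", {
  counts <- matrix(c(2L, 3L), 2, 1,
                   dimnames = list(c("AAA", "CCC"), "s1"))
  aln <- data.frame(sequence = c("AAA", "CCC"), contig = "chr1",
                    start = c(100L, 120L), end = c(130L, 150L),
                    strand = "+", stringsAsFactors = FALSE)
  loci <- build_loci(aln, counts)
  expect_equal(nrow(loci$loci), 1L)
  expect_equal(loci$loci$start, 100L)
  expect_equal(loci$loci$end, 150L)
  expect_equal(unname(loci$coverage[1, "s1"]), 5)

  # same intervals on opposite strands stay distinct
  aln$strand <- c("+", "-")
  aln$start <- c(100L, 100L)
  aln$end <- c(130L, 130L)
  expect_equal(nrow(build_loci(aln, counts)$loci), 2L)

  # adjacent-with-gap intervals merge only within merge_distance
  aln2 <- data.frame(sequence = c("AAA", "CCC"), contig = "chr1",
                     start = c(100L, 131L), end = c(130L, 160L),
                     strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(build_loci(aln2, counts)$loci), 2L)
  m5 <- build_loci(aln2, counts, merge_distance = 5L)
  expect_equal(nrow(m5$loci), 1L)
  expect_equal(c(m5$loci$start, m5$loci$end), c(100L, 160L))
  expect_error(build_loci(aln2, counts, merge_distance = -1L),
               "nonnegative")
})

test_that("locus building is idempotent and conserves coverage", {
  cfg <- small_config(seed = 23)
  ref <- generate_reference(cfg)
  sim <- simulate_counts(cfg, sim_feature_table(ref))
  dir <- withr::local_tempdir()
  col <- assign_classes(collapse_fastq(emit_reads(sim, ref, dir)),
                        annotation_index(ref$sncrna))
  pool <- unannotated_pool(col)
  mapped <- map_candidates(rownames(pool), ref$genome)
  loci <- build_loci(mapped$alignments, pool)
  # conservation: locus coverage sums the counts of every placement
  per_aln <- pool[mapped$alignments$sequence, , drop = FALSE]
  expect_equal(colSums(loci$coverage), colSums(per_aln))
  # idempotence: re-merging the loci intervals changes nothing
  aln2 <- data.frame(sequence = loci$loci$locus_id,
                     contig = loci$loci$contig, start = loci$loci$start,
                     end = loci$loci$end, strand = loci$loci$strand,
                     stringsAsFactors = FALSE)
  cov2 <- loci$coverage
  again <- build_loci(aln2, cov2)
  expect_equal(again$loci[, c("contig", "start", "end", "strand")],
               loci$loci[, c("contig", "start", "end", "strand")])
  # IDs numbered in (contig, start) order
  o <- order(loci$loci$contig, loci$loci$start, method = "radix")
  expect_equal(o, seq_len(nrow(loci$loci)))
})

test_that("planted loci are recovered with tight boundaries", {
  cfg <- small_config(seed = 24, n_planted_loci = 10L)
  ref <- generate_reference(cfg)
  sim <- simulate_counts(cfg, sim_feature_table(ref))
  dir <- withr::local_tempdir()
  col <- assign_classes(collapse_fastq(emit_reads(sim, ref, dir)),
                        annotation_index(ref$sncrna))
  pool <- unannotated_pool(col)
  sc <- score_pirna_like(rownames(pool),
                         ref$sncrna$sequence[ref$sncrna$class == "piRNA"],
                         ref$sncrna$sequence[ref$sncrna$class != "piRNA"])
  mapped <- map_candidates(sc$sequence[sc$retained], ref$genome)
  loci <- build_loci(mapped$alignments,
                     pool[sc$sequence[sc$retained], , drop = FALSE],
                     contig_class = ref$contig_class)
  emitted <- rowSums(sim$counts)[ref$loci$locus_id]
  truth <- ref$loci[emitted >= 5, ]
  hit <- mapply(function(ctg, st, en, strd) {
    any(loci$loci$contig == ctg & loci$loci$strand == strd &
          abs(loci$loci$start - st) <= 35 & abs(loci$loci$end - en) <= 35)
  }, truth$contig, truth$start, truth$end, truth$strand)
  expect_gte(mean(hit), 0.9)
  # mitochondrial-like contig is flagged
  if (any(loci$loci$contig == "contig_MT")) {
    expect_true(all(loci$loci$is_mito[loci$loci$contig == "contig_MT"]))
  }
})
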