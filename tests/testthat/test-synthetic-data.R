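# Synthetic-data generator: determinism, planted structure, ground truth.

test_that("reference generation is deterministic by seed", {
  r1 <- generate_reference(small_config(seed = 5))
  r2 <- generate_reference(small_config(seed = 5))
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$sncrna, r2$sncrna)
  expect_identical(r1$loci, r2$loci)
  r3 <- generate_reference(small_config(seed = 6))
  expect_false(identical(r1$genome, r3$genome))
})

test_that("reference with zero genes has empty annotation but a genome", {
  ref <- generate_reference(small_config(n_genes = 0L,
                                         n_known_pirnas = 10L))
  expect_equal(nrow(ref$gene_models), 0L)
  expect_true(all(nchar(ref$genome) > 0))
})

test_that("every context category offers a plantable interval", {
  ref <- generate_reference(small_config())
  for (cat in c("five_prime_utr", "CDS", "intron", "three_prime_utr")) {
    ints <- ref$gene_models[ref$gene_models$feature == cat, ]
    expect_gt(nrow(ints), 0)
    expect_true(all(ints$end - ints$start >= 40))  # fits a 35-nt read
  }
  # intergenic space: gene span is a small fraction of each contig
  gene_bp <- sum(ref$gene_models$end - ref$gene_models$start)
  expect_lt(gene_bp, sum(nchar(ref$genome)) / 2)
  # placements cover all five categories
  expect_setequal(unique(ref$pirna_placements$category),
                  c("five_prime_utr", "CDS", "intron", "three_prime_utr",
                    "intergenic"))
})

test_that("planted loci lie within contigs and members re-extract", {
  ref <- generate_reference(small_config(n_planted_loci = 10L))
  for (j in seq_len(nrow(ref$loci))) {
    lc <- ref$loci[j, ]
    expect_lte(lc$end, nchar(ref$genome[[lc$contig]]))
    fwd <- substr(ref$genome[[lc$contig]], lc$start + 1L, lc$end)
    mem <- ref$locus_members$sequence[ref$locus_members$locus_id ==
                                        lc$locus_id]
    locus_seq <- if (lc$strand == "+") fwd else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
    for (m in mem) expect_true(grepl(m, locus_seq, fixed = TRUE))
  }
})

test_that("planted piRNA placements match the genome sequence", {
  ref <- generate_reference(small_config())
  seqs <- setNames(ref$sncrna$sequence, ref$sncrna$id)
  for (i in seq_len(nrow(ref$pirna_placements))) {
    pl <- ref$pirna_placements[i, ]
    g <- substr(ref$genome[[pl$contig]], pl$start + 1L, pl$end)
    expected <- if (pl$strand == "+") seqs[[pl$pirna_id]] else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seqs[[pl$pirna_id]])))
    expect_identical(g, expected)
  }
})

test_that("no differential features are planted at fold change 1", {
  cfg <- small_config(planted_fc = 1)
  sim <- simulate_counts(cfg, data.frame(feature_id = sprintf("f%02d", 1:50)))
  expect_equal(nrow(sim$truth$differential), 0L)
})

test_that("the planted differential fraction is exact", {
  cfg <- small_config(frac_differential = 0.15, low_expression_frac = 0)
  sim <- simulate_counts(cfg, data.frame(feature_id = sprintf("f%03d", 1:200)))
  expect_equal(nrow(sim$truth$differential), 30L)
  # group mean ratio equals planted_fc on the mean matrix
  mu <- sim$truth$mu
  cn <- sim$meta$sample[sim$meta$stage == "CN"]
  tum <- sim$meta$sample[sim$meta$stage != "CN"]
  for (f in sim$truth$differential$feature_id[1:5]) {
    ratio <- mean(mu[f, tum]) / mean(mu[f, cn])
    tl <- sim$truth$differential$true_log2fc[
      sim$truth$differential$feature_id == f]
    expect_equal(log2(ratio), tl, tolerance = 1e-9)
  }
})

test_that("negative-binomial counts recover the configured mean", {
  cfg <- small_config(nb_mean = 50, nb_dispersion = 0.2,
                      low_expression_frac = 0, frac_differential = 0,
                      n_samples_per_stage = c(CN = 2L, pHCC = 2L))
  sim <- simulate_counts(cfg,
                         data.frame(feature_id = sprintf("f%04d", 1:10000)))
  cn <- sim$meta$sample[sim$meta$stage == "CN"]
  x <- as.vector(sim$counts[, cn])
  # per-feature means are jittered around nb_mean by a factor 2^U(-1,1)
  # whose expectation is (2 - 1/2) / (2 ln 2)
  expected <- 50 * 1.5 / (2 * log(2))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - expected), 3 * se)
})

test_that("emitted reads conserve counts and honour forced 5'-U", {
  cfg <- small_config(u1_prob = 1, n_planted_loci = 4L)
  ref <- generate_reference(cfg)
  sim <- simulate_counts(cfg, sim_feature_table(ref))
  dir <- withr::local_tempdir()
  paths <- emit_reads(sim, ref, dir)
  for (s in colnames(sim$counts)) {
    lines <- readLines(paths[[s]])
    expect_equal(length(lines) / 4L, sum(sim$counts[, s]))
    seqs <- lines[seq(2, length(lines), by = 4)]
    ids <- sub("^@([^:]+):.*", "\\1", lines[seq(1, length(lines), by = 4)])
    # count conservation per feature
    tab <- table(ids)
    nz <- sim$counts[, s][sim$counts[, s] > 0]
    expect_equal(as.integer(tab[names(nz)]), unname(nz))
    # all piRNA-like reads (piRNA + locus features) start with T
    pil <- ids %in% c(ref$sncrna$id[ref$sncrna$class == "piRNA"],
                      ref$loci$locus_id)
    if (any(pil)) {
      expect_true(all(substr(seqs[pil], 1, 1) == "T"))
    }
  }
})

test_that("planted target sites carry their declared mismatch count", {
  cfg <- small_config(planted_site_mismatches = c(0L, 3L, 4L))
  tx <- generate_transcripts(cfg)
  guides <- setNames(vapply(1:4, function(i) random_seq(20), ""),
                     sprintf("g%d", 1:4))
  set.seed(99)
  pl <- plant_target_sites(tx, guides, cfg)
  for (i in seq_len(nrow(pl$sites))) {
    st <- pl$sites[i, ]
    window <- substr(pl$transcripts$sequence[
      pl$transcripts$transcript_id == st$transcript_id],
      st$start + 1L, st$end)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(window)))
    g <- strsplit(guides[[st$pirna_id]], "")[[1]]
    expect_equal(sum(g != strsplit(rc, "")[[1]]), st$mismatches)
  }
  # m = 0 plants the exact reverse complement; m = 4 is undetectable at 3
  expect_true(all(pl$sites$detectable[pl$sites$mismatches == 0]))
  expect_false(any(pl$sites$detectable[pl$sites$mismatches == 4]))
})

test_that("site planting rejects out-of-range mismatch requests", {
  cfg <- small_config()
  cfg$planted_site_mismatches <- 5L
  tx <- generate_transcripts(small_config())
  expect_error(plant_target_sites(tx, c(g1 = random_seq(20)), cfg),
               "mismatch")
  expect_error(plant_target_sites(tx, c(g1 = random_seq(19)),
                                  small_config()),
               "20 nt")
})
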