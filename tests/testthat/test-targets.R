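# Guide extraction and seed-and-extend target search.

test_that("guides are positions 2..21 of the piRNA", {
  p30 <- paste0("T", strrep("ACGT", 5), strrep("A", 9))
  expect_equal(extract_guide(p30), substr(p30, 2, 21))
  expect_equal(extract_guide(p30), paste0(strrep("ACGT", 5)))
  p21 <- random_seq(21)
  expect_equal(extract_guide(p21), substr(p21, 2, 21))
  g20 <- extract_guide(random_seq(20))
  expect_true(is.na(g20))
  expect_equal(attr(g20, "reason"), "too short for guide")
  gs <- extract_guides(c(a = p30, b = random_seq(20)))
  expect_equal(names(gs$guides), "a")
  expect_equal(gs$skipped$pirna_id, "b")
})

test_that("an exact planted reverse complement is found with 0 mismatches", {
  set.seed(71)
  guide <- random_seq(20)
  rc <- pirliver:::revcomp(guide)
  tx <- data.frame(transcript_id = "t1",
                   sequence = paste0(random_seq(100), rc, random_seq(80)),
                   utr5_end = 50L, cds_end = 150L, length = 200L,
                   stringsAsFactors = FALSE)
  sites <- find_sites(guide, tx)
  planted <- sites[sites$start == 100L, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$mismatches, 0L)
  expect_equal(planted$end, 120L)
  expect_equal(planted$region, "CDS")  # midpoint 110 in [50,150)
})

test_that("windows beyond the mismatch budget are excluded", {
  set.seed(72)
  guide <- random_seq(20)
  rc <- strsplit(pirliver:::revcomp(guide), "")[[1]]
  mut <- rc
  for (p in c(2, 7, 12, 17)) {
    mut[p] <- setdiff(c("A", "C", "G", "T"), rc[p])[1]
  }
  tx <- data.frame(transcript_id = "t1",
                   sequence = paste0(random_seq(50),
                                     paste(mut, collapse = ""),
                                     random_seq(50)),
                   utr5_end = 20L, cds_end = 100L, length = 120L,
                   stringsAsFactors = FALSE)
  expect_equal(nrow(find_sites(guide, tx, max_mismatches = 3L)), 0L)
  s4 <- find_sites(guide, tx, max_mismatches = 4L)
  expect_equal(s4$mismatches, 4L)
})

test_that("seed-and-extend equals the brute-force scan on random data", {
  set.seed(73)
  tx <- data.frame(transcript_id = sprintf("t%02d", 1:10),
                   sequence = vapply(1:10, function(i) random_seq(500), ""),
                   utr5_end = 75L, cds_end = 400L, length = 500L,
                   stringsAsFactors = FALSE)
  for (i in 1:5) {
    guide <- random_seq(20)
    # plant a near-match to guarantee some hits
    mm <- sample(0:3, 1)
    win <- strsplit(pirliver:::revcomp(guide), "")[[1]]
    if (mm > 0) {
      for (p in sample(20, mm)) {
        win[p] <- setdiff(c("A", "C", "G", "T"), win[p])[1]
      }
    }
    j <- sample(10, 1)
    substr(tx$sequence[j], 201, 220) <- paste(win, collapse = "")
    got <- find_sites(guide, tx, pirna_id = "g")
    want <- brute_force_sites(guide, tx, pirna_id = "g")
    expect_identical(site_key(got), site_key(want))
    expect_true(any(got$start == 200L & got$transcript_id ==
                      tx$transcript_id[j]))
  }
})

test_that("site sets are monotone in the mismatch budget", {
  set.seed(74)
  tx <- data.frame(transcript_id = "t1", sequence = random_seq(2000),
                   utr5_end = 300L, cds_end = 1600L, length = 2000L,
                   stringsAsFactors = FALSE)
  guide <- random_seq(20)
  win <- pirliver:::revcomp(guide)
  substr(tx$sequence, 501, 520) <- win
  prev <- character(0)
  for (m in 0:4) {
    keys <- site_key(find_sites(guide, tx, max_mismatches = m))
    expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("short transcripts are skipped with a warning", {
  tx <- data.frame(transcript_id = "tiny", sequence = "ACGTACGT",
                   utr5_end = 2L, cds_end = 6L, length = 8L,
                   stringsAsFactors = FALSE)
  expect_warning(s <- find_sites(random_seq(20), tx), "skipped")
  expect_equal(nrow(s), 0L)
})

test_that("target summaries count pairs, regions and multiplicity", {
  sites <- data.frame(
    pirna_id = c("p1", "p1", "p2"),
    transcript_id = c("t1", "t1", "t1"),
    start = c(0L, 50L, 100L), end = c(20L, 70L, 120L),
    mismatches = c(0L, 2L, 1L),
    region = c("five_prime_utr", "CDS", "three_prime_utr"),
    stringsAsFactors = FALSE)
  sm <- target_summary(sites)
  expect_equal(sm$by_region$count,
               c(1L, 1L, 1L))
  expect_equal(sm$per_pirna$n_targets[sm$per_pirna$pirna_id == "p1"], 1L)
  expect_equal(sm$per_transcript$n_pirnas, 2L)
  pm <- sm$pair_multiplicity
  expect_equal(pm$n_sites[pm$pirna_id == "p1"], 2L)
  empty <- target_summary(sites[0, ])
  expect_equal(sum(empty$by_region$count), 0L)
  expect_equal(empty$n_target_transcripts, 0L)
})

test_that("planted truth sites are all recovered", {
  cfg <- small_config(seed = 75)
  tx <- generate_transcripts(cfg)
  guides <- setNames(vapply(1:5, function(i) random_seq(20), ""),
                     sprintf("g%d", 1:5))
  set.seed(76)
  pl <- plant_target_sites(tx, guides, cfg)
  found <- find_all_sites(guides, pl$transcripts)
  truth <- pl$sites[pl$sites$detectable, ]
  truth_keys <- sprintf("%s|%s|%d|%d", truth$pirna_id,
                        truth$transcript_id, truth$start, truth$mismatches)
  expect_true(all(truth_keys %in% site_key(found)))
  # region labels agree with the planting record
  m <- merge(found, truth, by = c("pirna_id", "transcript_id", "start"))
  expect_equal(m$region.x, m$region.y)
})
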