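# RPM normalisation, filtering, rank-sum DE, BH, stage patterns.

test_that("RPM normalisation is definitional", {
  m <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  rpm <- normalize_rpm(m, c(s1 = 1e5))
  expect_equal(unname(rpm["a", 1]), 100)
  expect_equal(unname(rpm["b", 1]), 0)
  expect_error(normalize_rpm(m, c(s1 = 0)), "s1")
  # column-total denominators give columns summing to 1e6
  m2 <- matrix(rpois(50, 20) + 1L, 10, 5,
               dimnames = list(sprintf("f%d", 1:10), sprintf("s%d", 1:5)))
  rpm2 <- normalize_rpm(m2, colSums(m2))
  expect_equal(unname(colSums(rpm2)), rep(1e6, 5))
})

test_that("low-expression filter keeps features passing in any group", {
  rpm <- rbind(low = c(0.4, 0.4, 0.7, 0.7),
               mix = c(0.4, 0.4, 2.0, 2.0))
  colnames(rpm) <- sprintf("s%d", 1:4)
  groups <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  f <- filter_low_expression(rpm, groups, threshold = 1)
  expect_equal(f$retained, "mix")
  expect_equal(f$removed$feature_id, "low")

  # synthetic: expressed features recovered exactly
  set.seed(41)
  expressed <- matrix(rnbinom(30 * 4, mu = 50, size = 5), 30, 4)
  tail <- matrix(0L, 70, 4)
  m <- rbind(expressed, tail) + 0
  rownames(m) <- sprintf("f%03d", 1:100)
  colnames(m) <- names(groups)
  rpm2 <- normalize_rpm(m, setNames(rep(1e4, 4), names(groups)))
  f2 <- filter_low_expression(rpm2, groups)
  expect_setequal(f2$retained, sprintf("f%03d", 1:30))
})

test_that("rank-sum p matches the exact small-sample distribution", {
  expect_equal(rank_sum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rank_sum_p(c(1, 2), c(1, 2)), 1)
  # invariance under strictly monotone transforms
  set.seed(42)
  x <- rnorm(6); y <- rnorm(7)
  expect_equal(rank_sum_p(x, y), rank_sum_p(exp(x), exp(y)))
  expect_equal(rank_sum_p(x, y), rank_sum_p(y, x))
  # approximation close to exact for groups of 8, tie-free
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    exact <- rank_sum_p(x, y)
    approx <- pirliver:::rank_sum_p_approx(x, y)
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("fold change is the median ratio with direction", {
  rpm <- rbind(up = c(10, 10, 10, 30, 30, 30),
               flat = c(5, 6, 7, 5, 6, 7))
  colnames(rpm) <- sprintf("s%d", 1:6)
  de <- wilcoxon_de(rpm, sprintf("s%d", 1:3), sprintf("s%d", 4:6),
                    fc_threshold = 1.5, fdr_threshold = 1)
  up <- de[de$feature_id == "up", ]
  expect_equal(up$fc, 3)
  expect_equal(up$direction, "up")
  flat <- de[de$feature_id == "flat", ]
  expect_equal(flat$fc, 1)
  expect_equal(flat$p_raw, 1)
  expect_false(flat$in_signature)
  # swapping the groups inverts the signed fold change
  de2 <- wilcoxon_de(rpm, sprintf("s%d", 4:6), sprintf("s%d", 1:3),
                     fc_threshold = 1.5, fdr_threshold = 1)
  expect_equal(de2$fc[de2$feature_id == "up"], -3)
  expect_equal(de2$p_raw, de$p_raw)
  expect_error(wilcoxon_de(rpm, "s1", sprintf("s%d", 4:6)), "2 samples")
})

test_that("zero medians are handled with the 0.5 pseudocount", {
  rpm <- rbind(z = c(0, 0, 0, 9.5, 9.5, 9.5))
  colnames(rpm) <- sprintf("s%d", 1:6)
  de <- wilcoxon_de(rpm, sprintf("s%d", 1:3), sprintf("s%d", 4:6))
  expect_equal(de$fc, (9.5 + 0.5) / 0.5)  # = 20
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      q[o[i]] <- min(1, min(p[o[i:m]] * m / (i:m)))
    }
    q
  }
  set.seed(43)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, step_up(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("stage patterns label planted profiles", {
  set.seed(44)
  stages <- c("CN", "LGDN", "HGDN", "eHCC", "pHCC")
  n_per <- c(CN = 8, LGDN = 6, HGDN = 6, eHCC = 6, pHCC = 8)
  meta <- data.frame(
    sample = unlist(lapply(stages, function(s) {
      sprintf("%s_%d", s, seq_len(n_per[[s]]))
    })),
    stage = rep(stages, n_per), stringsAsFactors = FALSE)
  mu <- rbind(flat = rep(50, nrow(meta)),
              lgdn_only = 50 * ifelse(meta$stage == "LGDN", 8, 1),
              from_hgdn = 50 * ifelse(meta$stage %in%
                                        c("HGDN", "eHCC", "pHCC"), 8, 1))
  m <- matrix(rnbinom(length(mu), mu = mu, size = 10), nrow = 3,
              dimnames = list(rownames(mu), meta$sample))
  pat <- stage_patterns(m + 0, meta)
  expect_equal(pat$pattern[pat$feature_id == "flat"], "flat")
  expect_equal(pat$pattern[pat$feature_id == "lgdn_only"],
               "LGDN-restricted")
  expect_equal(pat$pattern[pat$feature_id == "from_hgdn"], "up-from-HGDN")
  expect_error(stage_patterns(m + 0, meta[meta$stage != "eHCC", ]),
               "eHCC")
})

test_that("high-expression flags use within-group means and RPM share", {
  rpm <- rbind(hi = c(6000, 6000, 10, 10),
               lo = c(10, 10, 10, 10))
  colnames(rpm) <- sprintf("s%d", 1:4)
  groups <- c(s1 = "CN", s2 = "CN", s3 = "pHCC", s4 = "pHCC")
  fl <- flag_high_expression(rpm, groups)
  expect_equal(fl$flagged, "hi")
  expect_equal(fl$share, sum(rpm["hi", ]) / sum(rpm))
  fl2 <- flag_high_expression(rpm, groups, rpm_cutoff = 1e7)
  expect_equal(length(fl2$flagged), 0L)
  expect_equal(fl2$share, 0)
})
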