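## RPM normalisation, low-expression filtering, rank-sum differential
## expression with FC/FDR signature calling, stage-wise patterns and
## high-expression flagging.

#' Normalise raw counts to reads per million
#'
#' @param counts feature x sample matrix of raw counts.
#' @param library_sizes named vector of per-sample library sizes (total
#'   reads passing ingest filters).
#' @return matrix of RPM values, same shape as \code{counts}.
#' @export
normalize_rpm <- function(counts, library_sizes) {
  libs <- library_sizes[colnames(counts)]
  if (any(is.na(libs))) {
    stop("missing library size for sample(s): ",
         paste(colnames(counts)[is.na(libs)], collapse = ", "))
  }
  if (any(libs <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[libs <= 0], collapse = ", "))
  }
  sweep(counts, 2, libs, "/") * 1e6
}

#' Filter out low-expression features
#'
#' A feature is retained when its mean RPM exceeds the threshold in at
#' least one sample group.
#'
#' @param rpm feature x sample RPM matrix.
#' @param groups named character vector sample -> group.
#' @param threshold mean-RPM threshold (default 1).
#' @return list with \code{retained} (feature ids) and \code{removed}
#'   (data.frame feature_id, reason).
#' @export
filter_low_expression <- function(rpm, groups, threshold = 1) {
  gs <- unique(unname(groups[colnames(rpm)]))
  if (length(gs) < 1L) stop("need at least one sample group")
  means <- vapply(gs, function(g) {
    cols <- colnames(rpm)[groups[colnames(rpm)] == g]
    rowMeans(rpm[, cols, drop = FALSE])
  }, numeric(nrow(rpm)))
  if (is.null(dim(means))) means <- matrix(means, nrow = nrow(rpm))
  keep <- apply(means, 1, max) > threshold
  list(retained = rownames(rpm)[keep],
       removed = data.frame(
         feature_id = rownames(rpm)[!keep],
         reason = rep(sprintf("mean RPM <= %g in every group", threshold),
                      sum(!keep)),
         stringsAsFactors = FALSE))
}

#' Two-sided rank-sum (Wilcoxon Mann-Whitney) p-value
#'
#' Exact by the null distribution of the Mann-Whitney U statistic when both
#' groups have at most 8 observations and the pooled values are tie-free;
#' tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param x,y numeric vectors (the two groups).
#' @return two-sided p-value.
#' @export
rank_sum_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 <= 8L && n2 <= 8L) {
    p <- 2 * min(pwilcox(u, n1, n2), 1 - pwilcox(u - 1, n1, n2))
    return(min(1, p))
  }
  rank_sum_p_approx(x, y)
}

## tie-corrected normal approximation with continuity correction
rank_sum_p_approx <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  n <- n1 + n2
  sigma2 <- (n1 * n2 / 12) *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @return adjusted values (monotone, >= raw p, in \[0, 1\]).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

signed_fc <- function(med_a, med_b, pseudocount = 0.5) {
  if (med_a == 0 || med_b == 0) {
    med_a <- med_a + pseudocount
    med_b <- med_b + pseudocount
  }
  ratio <- med_b / med_a
  list(ratio = ratio,
       fc = if (ratio >= 1) ratio else -1 / ratio,
       log2fc = log2(ratio))
}

#' Rank-sum differential expression with signature calling
#'
#' Tests every feature between two sample groups with the two-sided
#' Wilcoxon Mann-Whitney test, computes the fold change as the ratio of
#' group medians (group_b over group_a; a 0.5-RPM pseudocount is added to
#' both medians when either is zero), adjusts p-values by
#' Benjamini-Hochberg across all tested features, and flags the signature:
#' |FC| >= fc_threshold and FDR <= fdr_threshold. FC > 1 means
#' overexpressed in group_b (the second-named, tumor, group); fold changes
#' below one are reported as negative reciprocals.
#'
#' @param rpm feature x sample RPM matrix.
#' @param samples_a,samples_b sample ids of the two groups (>= 2 each).
#' @param fc_threshold absolute fold-change threshold (default 1.5).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param paired use the Wilcoxon signed-rank test on matched samples
#'   (samples_a and samples_b must be ordered by patient).
#' @return object of class \code{pi_de}: data.frame (feature_id, fc,
#'   log2fc, p_raw, fdr, in_signature, direction).
#' @export
wilcoxon_de <- function(rpm, samples_a, samples_b, fc_threshold = 1.5,
                        fdr_threshold = 0.05, paired = FALSE) {
  if (length(samples_a) < 2L || length(samples_b) < 2L) {
    stop("need at least 2 samples per group")
  }
  a <- rpm[, samples_a, drop = FALSE]
  b <- rpm[, samples_b, drop = FALSE]
  res <- lapply(seq_len(nrow(rpm)), function(i) {
    p <- if (paired) {
      suppressWarnings(stats::wilcox.test(b[i, ], a[i, ],
                                          paired = TRUE)$p.value)
    } else {
      rank_sum_p(a[i, ], b[i, ])
    }
    if (is.na(p)) p <- 1
    fc <- signed_fc(median(a[i, ]), median(b[i, ]))
    data.frame(feature_id = rownames(rpm)[i], fc = fc$fc,
               log2fc = fc$log2fc, p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p_raw)
  out$in_signature <- abs(out$fc) >= fc_threshold &
    out$fdr <= fdr_threshold
  out$direction <- ifelse(out$fc >= 1, "up", "down")
  out$direction[out$fc == 1] <- "none"
  class(out) <- c("pi_de", "data.frame")
  out
}

#' @export
print.pi_de <- function(x, ...) {
  cat(sprintf("Differential expression: %d features tested, %d in signature (%d up, %d down)\n",
              nrow(x), sum(x$in_signature),
              sum(x$in_signature & x$direction == "up"),
              sum(x$in_signature & x$direction == "down")))
  NextMethod()
}

#' Summarise a DE result
#' @param object a \code{pi_de}.
#' @param ... unused.
#' @export
summary.pi_de <- function(object, ...) {
  sig <- object[object$in_signature, ]
  list(n_tested = nrow(object), n_signature = nrow(sig),
       n_up = sum(sig$direction == "up"),
       n_down = sum(sig$direction == "down"),
       min_fdr = if (nrow(object)) min(object$fdr) else NA_real_)
}

#' Stage-wise expression patterns
#'
#' For each feature and each intermediate stage (LGDN, HGDN, eHCC), runs
#' two rank-sum tests -- against CN and against pHCC -- at raw
#' p <= alpha, and labels the feature with a pattern string:
#' \code{flat} (no significant comparison), \code{<stage>-restricted}
#' (differs from both ends at exactly one intermediate stage),
#' \code{up-from-<stage>} / \code{down-from-<stage>} (consistent departure
#' from CN starting at that stage and maintained through pHCC), or
#' \code{complex}.
#'
#' @param rpm feature x sample RPM matrix.
#' @param meta data.frame with \code{sample} and \code{stage} columns.
#' @param alpha raw p-value threshold (default 0.05).
#' @param stages stage order, first = baseline, last = endpoint.
#' @return data.frame: feature_id, per-comparison p-values, pattern.
#' @export
stage_patterns <- function(rpm, meta, alpha = 0.05,
                           stages = c("CN", "LGDN", "HGDN", "eHCC",
                                      "pHCC")) {
  missing_stage <- setdiff(stages, unique(meta$stage))
  if (length(missing_stage) > 0L) {
    stop("stage(s) absent from metadata: ",
         paste(missing_stage, collapse = ", "))
  }
  base_s <- stages[1]
  end_s <- stages[length(stages)]
  mids <- stages[-c(1, length(stages))]
  cols_of <- function(s) meta$sample[meta$stage == s]
  base_cols <- cols_of(base_s)
  end_cols <- cols_of(end_s)

  rows <- lapply(seq_len(nrow(rpm)), function(i) {
    v <- rpm[i, ]
    p_vs_base <- vapply(mids, function(s) {
      rank_sum_p(v[base_cols], v[cols_of(s)])
    }, numeric(1))
    p_vs_end <- vapply(mids, function(s) {
      rank_sum_p(v[end_cols], v[cols_of(s)])
    }, numeric(1))
    p_end_base <- rank_sum_p(v[base_cols], v[end_cols])
    dir_vs_base <- vapply(mids, function(s) {
      sign(median(v[cols_of(s)]) - median(v[base_cols]))
    }, numeric(1))
    dir_end <- sign(median(v[end_cols]) - median(v[base_cols]))

    sig_base <- p_vs_base <= alpha
    sig_end <- p_vs_end <= alpha
    pattern <- if (!any(sig_base) && !any(sig_end) && p_end_base > alpha) {
      "flat"
    } else if (sum(sig_base & sig_end) == 1L && sum(sig_base) == 1L &&
               p_end_base > alpha) {
      sprintf("%s-restricted", mids[sig_base & sig_end])
    } else {
      k <- which(sig_base)
      if (length(k) > 0L && all(seq(min(k), length(mids)) %in% k) &&
          length(unique(dir_vs_base[k])) == 1L &&
          p_end_base <= alpha && dir_end == dir_vs_base[k[1]]) {
        sprintf("%s-from-%s", if (dir_end > 0) "up" else "down",
                mids[min(k)])
      } else {
        "complex"
      }
    }
    cbind(data.frame(feature_id = rownames(rpm)[i],
                     stringsAsFactors = FALSE),
          setNames(as.list(p_vs_base), paste0("p_", mids, "_vs_", base_s)),
          setNames(as.list(p_vs_end), paste0("p_", mids, "_vs_", end_s)),
          data.frame(p_end_vs_base = p_end_base, pattern = pattern,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Flag very highly expressed features
#'
#' A feature is flagged when its mean RPM within any one stage group meets
#' the cutoff; the flagged set's share of total RPM is reported.
#'
#' @param rpm feature x sample RPM matrix.
#' @param groups named character vector sample -> group.
#' @param rpm_cutoff mean-RPM cutoff (default 5000).
#' @return list with \code{flagged} (feature ids), \code{share} (flagged
#'   features' fraction of total RPM) and \code{group_means}.
#' @export
flag_high_expression <- function(rpm, groups, rpm_cutoff = 5000) {
  if (nrow(rpm) == 0L) stop("empty expression matrix")
  gs <- unique(unname(groups[colnames(rpm)]))
  means <- vapply(gs, function(g) {
    cols <- colnames(rpm)[groups[colnames(rpm)] == g]
    rowMeans(rpm[, cols, drop = FALSE])
  }, numeric(nrow(rpm)))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = nrow(rpm),
                    dimnames = list(rownames(rpm), gs))
  }
  flagged <- rownames(rpm)[apply(means, 1, max) >= rpm_cutoff]
  share <- if (sum(rpm) > 0) {
    sum(rpm[flagged, , drop = FALSE]) / sum(rpm)
  } else 0
  list(flagged = flagged, share = share, group_means = means)
}
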