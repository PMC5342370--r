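## Sample clustering on signature expression: Ward agglomeration on the
## 1 - Kendall-tau dissimilarity, plus the log2 median-centered matrix
## export used for heatmaps.

#' Kendall dissimilarity between samples
#'
#' Pairwise Kendall tau-b (tie-corrected) between sample expression
#' vectors; dissimilarity = 1 - tau, in \[0, 2\].
#'
#' @param rpm feature x sample matrix (>= 2 features, >= 2 samples),
#'   typically restricted to a signature feature set.
#' @return symmetric sample x sample dissimilarity matrix, zero diagonal.
#' @export
kendall_distance <- function(rpm) {
  if (ncol(rpm) < 2L || nrow(rpm) < 2L) {
    stop("need at least 2 samples and 2 features")
  }
  const <- apply(rpm, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    stop("constant expression vector (tau undefined) for sample(s): ",
         paste(colnames(rpm)[const], collapse = ", "))
  }
  tau <- cor(rpm, method = "kendall")
  d <- 1 - tau
  diag(d) <- 0
  d
}

#' Ward clustering of samples
#'
#' Agglomerative clustering by Ward's criterion applied to the
#' dissimilarity directly (classical Ward; for 1 - tau this is the usual
#' approximation on a non-Euclidean dissimilarity). Deterministic for a
#' given input.
#'
#' @param d sample x sample dissimilarity matrix (as from
#'   [kendall_distance()]).
#' @return object of class \code{pi_clust}: list with \code{dist},
#'   \code{tree} (an \code{hclust}), \code{order} and \code{labels_at},
#'   a function of k returning flat cluster labels.
#' @export
ward_cluster <- function(d) {
  if (nrow(d) < 2L) stop("need at least 2 samples to cluster")
  tree <- hclust(as.dist(d), method = "ward.D")
  structure(list(dist = d, tree = tree, order = tree$order,
                 labels_at = function(k) cutree(tree, k = k)),
            class = "pi_clust")
}

#' @export
print.pi_clust <- function(x, ...) {
  cat(sprintf("Ward clustering of %d samples (1 - Kendall tau)\n",
              nrow(x$dist)))
  k2 <- x$labels_at(2)
  cat(sprintf("  k=2 split: %d | %d samples; merge height range %.3f-%.3f\n",
              sum(k2 == 1), sum(k2 == 2), min(x$tree$height),
              max(x$tree$height)))
  invisible(x)
}

#' Export the dendrogram as a Newick string
#'
#' @param clust a \code{pi_clust}.
#' @param path optional file to write.
#' @return the Newick string, invisibly when written to file.
#' @export
cluster_newick <- function(clust, path = NULL) {
  phy <- ape::as.phylo(clust$tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Heatmap table: log2, median-centered expression
#'
#' value = log2(RPM + pseudocount) - row median; every output row has
#' median zero.
#'
#' @param rpm feature x sample RPM matrix.
#' @param features optional feature subset.
#' @param pseudocount added before log2 (default 1).
#' @return transformed matrix.
#' @export
export_heatmap_table <- function(rpm, features = NULL, pseudocount = 1) {
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(rpm))
    if (length(missing) > 0L) {
      stop("feature(s) absent from matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    rpm <- rpm[features, , drop = FALSE]
  }
  lg <- log2(rpm + pseudocount)
  lg - apply(lg, 1, median)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b cluster label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
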