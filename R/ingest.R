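## Read collapsing and classification against the known sncRNA annotation.
## Matching is exact by full sequence; the first matching class in the
## priority order wins.

DEFAULT_PRIORITY <- c("miRNA", "rRNA", "tRNA", "snoRNA", "piRNA")

#' Load an annotation index from a sncRNA FASTA
#'
#' Headers follow the \code{>ID|CLASS} convention. Duplicate sequences
#' within a class are rejected; the same sequence may occur in different
#' classes (resolved later by the priority order).
#'
#' @param fasta path to the annotation FASTA, or a data.frame with columns
#'   \code{id}, \code{class}, \code{sequence}.
#' @param priority class priority order (first match wins).
#' @return an object of class \code{annotation_index}.
#' @export
annotation_index <- function(fasta, priority = DEFAULT_PRIORITY) {
  if (is.character(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    hdr <- strsplit(names(ss), "|", fixed = TRUE)
    ann <- data.frame(id = vapply(hdr, `[`, "", 1L),
                      class = vapply(hdr, `[`, "", 2L),
                      sequence = as.character(ss), stringsAsFactors = FALSE)
  } else {
    ann <- fasta[, c("id", "class", "sequence")]
  }
  if (any(is.na(ann$class) | !nzchar(ann$class))) {
    stop("annotation headers must follow the >ID|CLASS convention")
  }
  by_class <- split(ann, ann$class)
  maps <- lapply(by_class, function(d) {
    dup <- duplicated(d$sequence)
    if (any(dup)) {
      stop("duplicate sequence within class ", d$class[1], ": ",
           d$sequence[dup][1])
    }
    setNames(d$id, d$sequence)
  })
  structure(list(maps = maps, priority = priority), class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("Annotation index:",
      paste(sprintf("%s=%d", names(x$maps), lengths(x$maps)),
            collapse = " "), "\n")
  cat("  priority:", paste(x$priority, collapse = " > "), "\n")
  invisible(x)
}

#' Collapse FASTQ reads to unique sequences with per-sample counts
#'
#' @param fastq_files named character vector of FASTQ paths (names =
#'   sample ids; basenames used when unnamed).
#' @param length_window integer \code{c(min, max)}; reads outside the
#'   window, or containing N, are tallied to the discard report.
#' @return an object of class \code{collapsed_reads}: list with
#'   \code{counts} (unique sequence x sample integer matrix, rownames =
#'   sequences), \code{discards} (per-sample report) and
#'   \code{library_sizes} (reads passing filters per sample).
#' @export
collapse_fastq <- function(fastq_files, length_window = c(18L, 40L)) {
  if (is.null(names(fastq_files))) {
    names(fastq_files) <- sub("\\.(fastq|fq)(\\.gz)?$", "",
                              basename(fastq_files))
  }
  per_sample <- lapply(names(fastq_files), function(s) {
    ln <- readLines(fastq_files[[s]], warn = FALSE)
    if (length(ln) %% 4L != 0L) {
      stop("malformed FASTQ in sample ", s, ": truncated record ",
           length(ln) %/% 4L + 1L)
    }
    if (length(ln) > 0L) {
      bad_hdr <- which(!startsWith(ln[seq(1L, length(ln), 4L)], "@"))
      bad_sep <- which(!startsWith(ln[seq(3L, length(ln), 4L)], "+"))
      if (length(c(bad_hdr, bad_sep)) > 0L) {
        stop("malformed FASTQ in sample ", s, ": record ",
             min(c(bad_hdr, bad_sep)))
      }
    }
    reads <- tryCatch(
      as.character(Biostrings::readDNAStringSet(fastq_files[[s]],
                                                format = "fastq")),
      error = function(e) stop("malformed FASTQ in sample ", s, ": ",
                               conditionMessage(e)))
    reads <- toupper(reads)
    len <- nchar(reads)
    has_n <- grepl("N", reads, fixed = TRUE)
    in_window <- len >= length_window[1] & len <= length_window[2]
    keep <- in_window & !has_n
    list(tab = table(reads[keep]),
         discards = data.frame(sample = s, input_reads = length(reads),
                               too_short = sum(len < length_window[1]),
                               too_long = sum(len > length_window[2]),
                               with_n = sum(has_n & in_window),
                               kept = sum(keep), stringsAsFactors = FALSE))
  })
  all_seqs <- unique(unlist(lapply(per_sample,
                                   function(x) names(x$tab))))
  all_seqs <- sort(as.character(all_seqs), method = "radix")
  counts <- matrix(0L, length(all_seqs), length(fastq_files),
                   dimnames = list(all_seqs, names(fastq_files)))
  for (i in seq_along(per_sample)) {
    tab <- per_sample[[i]]$tab
    counts[names(tab), i] <- as.integer(tab)
  }
  discards <- do.call(rbind, lapply(per_sample, `[[`, "discards"))
  structure(list(counts = counts, discards = discards,
                 library_sizes = colSums(counts)),
            class = "collapsed_reads")
}

#' @export
print.collapsed_reads <- function(x, ...) {
  cat(sprintf("Collapsed reads: %d unique sequences x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  library sizes: %s\n",
              paste(range(x$library_sizes), collapse = " - ")))
  invisible(x)
}

#' Assign collapsed reads to sncRNA classes
#'
#' Exact full-sequence match against the annotation index; the first class
#' in the priority order that contains the sequence wins. Unmatched
#' sequences are labeled \code{unannotated}.
#'
#' @param collapsed a \code{collapsed_reads} object.
#' @param index an [annotation_index()].
#' @return the \code{collapsed_reads} object with an \code{assignment}
#'   data.frame added (sequence, assigned_class, assigned_id).
#' @export
assign_classes <- function(collapsed, index) {
  seqs <- rownames(collapsed$counts)
  cls <- rep("unannotated", length(seqs))
  id <- rep("", length(seqs))
  todo <- rep(TRUE, length(seqs))
  for (cl in index$priority) {
    map <- index$maps[[cl]]
    if (is.null(map)) next
    hit <- todo & seqs %in% names(map)
    cls[hit] <- cl
    id[hit] <- unname(map[seqs[hit]])
    todo <- todo & !hit
  }
  collapsed$assignment <- data.frame(sequence = seqs, assigned_class = cls,
                                     assigned_id = id,
                                     stringsAsFactors = FALSE)
  collapsed
}

#' Known-piRNA raw count matrix
#'
#' Sums counts of all sequence variants sharing one piRNA identifier, keeps
#' identifiers with nonzero total count, and reports the number of distinct
#' piRNAs detected per sample group.
#'
#' @param assigned a \code{collapsed_reads} after [assign_classes()].
#' @param groups optional named character vector sample -> group for the
#'   detection report.
#' @return list with \code{matrix} (piRNA id x sample) and
#'   \code{detected_per_group}.
#' @export
pirna_count_matrix <- function(assigned, groups = NULL) {
  if (is.null(assigned$assignment)) stop("run assign_classes() first")
  sel <- assigned$assignment$assigned_class == "piRNA"
  if (!any(sel)) {
    warning("no piRNA-assigned sequences in input")
    m <- matrix(0L, 0L, ncol(assigned$counts),
                dimnames = list(character(), colnames(assigned$counts)))
    return(list(matrix = m, detected_per_group = integer(0)))
  }
  sub <- assigned$counts[sel, , drop = FALSE]
  ids <- assigned$assignment$assigned_id[sel]
  m <- rowsum(sub, group = ids)
  m <- m[rowSums(m) > 0L, , drop = FALSE]
  m <- m[ord(rownames(m)), , drop = FALSE]
  detected <- integer(0)
  if (!is.null(groups)) {
    gs <- unique(unname(groups[colnames(m)]))
    detected <- vapply(gs, function(g) {
      cols <- colnames(m)[groups[colnames(m)] == g]
      sum(rowSums(m[, cols, drop = FALSE]) > 0L)
    }, integer(1))
    names(detected) <- gs
  }
  list(matrix = m, detected_per_group = detected)
}

#' Per-class count summary
#'
#' Per-sample read totals by assigned class; together with the discard
#' report this accounts for every input read.
#'
#' @param assigned a \code{collapsed_reads} after [assign_classes()].
#' @return data.frame: class x sample totals.
#' @export
class_count_summary <- function(assigned) {
  if (is.null(assigned$assignment)) stop("run assign_classes() first")
  m <- rowsum(assigned$counts, group = assigned$assignment$assigned_class)
  data.frame(class = rownames(m), m, check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract the unannotated read pool
#'
#' @param assigned a \code{collapsed_reads} after [assign_classes()].
#' @param length_window keep sequences within this window (the discovery
#'   window; 25--35 nt by default).
#' @return count matrix (sequence x sample) of unannotated reads.
#' @export
unannotated_pool <- function(assigned, length_window = c(25L, 35L)) {
  if (is.null(assigned$assignment)) stop("run assign_classes() first")
  sel <- assigned$assignment$assigned_class == "unannotated" &
    nchar(rownames(assigned$counts)) >= length_window[1] &
    nchar(rownames(assigned$counts)) <= length_window[2]
  assigned$counts[sel, , drop = FALSE]
}
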