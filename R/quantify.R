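# Aggregation of mapped-read intervals into feature counts and per-base
# coverage, plus the read-count summaries used to calibrate the calling metric.

#' Count reads over features
#'
#' A read increments a feature iff their overlap is at least
#' `min_overlap_frac` times the read's length (default 0.5). Counting is
#' unstranded; a read meeting the rule for several features increments each.
#' With disjoint features and a fraction above 0.5 a read can be counted at
#' most once.
#'
#' @param reads Data frame of read intervals (`start`, `end`, 0-based half-open).
#' @param features Data frame with `id`, `start`, `end`.
#' @param min_overlap_frac Minimum overlap as a fraction of read length.
#' @return Named integer vector of counts, one per feature.
#' @export
count_reads <- function(reads, features, min_overlap_frac = 0.5) {
  stopifnot(min_overlap_frac >= 0, min_overlap_frac <= 1)
  out <- stats::setNames(integer(nrow(features)), features$id)
  if (nrow(reads) == 0L || nrow(features) == 0L) return(out)
  rir <- .as_iranges(reads$start, reads$end)
  fir <- .as_iranges(features$start, features$end)
  ov <- IRanges::findOverlaps(rir, fir)
  if (length(ov) == 0L) return(out)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(rir[q], fir[s]))
  keep <- w >= min_overlap_frac * IRanges::width(rir)[q]
  out[] <- tabulate(s[keep], nbins = nrow(features))
  out
}

#' Per-base coverage of an IOR
#'
#' Pileup of read intervals clipped to the IOR interval.
#'
#' @param reads Data frame of read intervals (`start`, `end`).
#' @param ior_start,ior_end IOR interval (0-based half-open).
#' @return Integer vector of length `ior_end - ior_start`.
#' @export
coverage_profile <- function(reads, ior_start, ior_end) {
  len <- ior_end - ior_start
  stopifnot(len > 0)
  keep <- reads$start < ior_end & reads$end > ior_start
  if (!any(keep)) return(integer(len))
  s <- pmax(reads$start[keep], ior_start) - ior_start
  e <- pmin(reads$end[keep], ior_end) - ior_start
  as.integer(IRanges::coverage(IRanges::IRanges(s + 1L, e), width = len))
}

#' Build the feature x library count matrix
#'
#' Rows are ORFs (`orf`), known sRNAs (`known_srna`), structural RNAs
#' (`structural`) and IORs (`ior`); columns are libraries. Reads falling
#' outside the contig are dropped with a message.
#'
#' @param readsets Named list of read data frames.
#' @param annotation A [genome_annotation()].
#' @param iors IOR table from [derive_iors()].
#' @param min_overlap_frac Overlap rule passed to [count_reads()].
#' @return Object of class `count_matrix`: `counts` (integer matrix), `class`
#'   (row class labels), `libraries`, plus the `features` table.
#' @export
build_count_matrix <- function(readsets, annotation, iors,
                               min_overlap_frac = 0.5) {
  feats <- rbind(
    data.frame(id = annotation$orfs$id, start = annotation$orfs$start,
               end = annotation$orfs$end, class = "orf", stringsAsFactors = FALSE),
    if (nrow(annotation$known_srnas) > 0L)
      data.frame(id = annotation$known_srnas$id, start = annotation$known_srnas$start,
                 end = annotation$known_srnas$end, class = "known_srna",
                 stringsAsFactors = FALSE),
    if (nrow(annotation$structural_rnas) > 0L)
      data.frame(id = annotation$structural_rnas$id,
                 start = annotation$structural_rnas$start,
                 end = annotation$structural_rnas$end, class = "structural",
                 stringsAsFactors = FALSE),
    data.frame(id = iors$id, start = iors$start, end = iors$end, class = "ior",
               stringsAsFactors = FALSE))
  counts <- matrix(0L, nrow(feats), length(readsets),
                   dimnames = list(feats$id, names(readsets)))
  dropped <- 0L
  for (l in seq_along(readsets)) {
    r <- readsets[[l]]
    ok <- r$start >= 0 & r$end <= annotation$contig_length & r$end > r$start
    dropped <- dropped + sum(!ok)
    counts[, l] <- count_reads(r[ok, , drop = FALSE], feats, min_overlap_frac)
  }
  if (dropped > 0L)
    .msgf("build_count_matrix: dropped %d read(s) outside the contig", dropped)
  structure(list(counts = counts, class = feats$class,
                 libraries = names(readsets), features = feats),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$class))
  invisible(x)
}

#' Read-count frequency distribution of a feature class
#'
#' The calibration view behind the calling metric: how feature read counts of
#' one class distribute, and what fraction reaches the candidate threshold.
#'
#' @param cm A `count_matrix`.
#' @param class Feature class (`"orf"`, `"known_srna"`, `"structural"`, `"ior"`).
#' @param bin_edges Histogram bin edges (right-open; last bin open-ended).
#' @param stat Per-feature statistic across libraries: `max` (default,
#'   matching the any-library threshold semantics), `sum` or `mean`.
#' @param threshold Count threshold whose exceedance fraction is reported.
#' @return List with `table` (bin, frequency) and `frac_ge` (fraction of
#'   features with statistic >= threshold).
#' @export
readcount_histogram <- function(cm, class, bin_edges = c(0, 10, 50, 100, 500, 1000),
                                stat = c("max", "sum", "mean"), threshold = 50) {
  stat <- match.arg(stat)
  rows <- cm$class == class
  if (!any(rows))
    return(list(table = data.frame(bin = character(), count = integer()),
                frac_ge = NA_real_))
  x <- switch(stat,
              max = apply(cm$counts[rows, , drop = FALSE], 1, max),
              sum = rowSums(cm$counts[rows, , drop = FALSE]),
              mean = rowMeans(cm$counts[rows, , drop = FALSE]))
  edges <- unique(c(bin_edges, Inf))
  tab <- table(cut(x, edges, right = FALSE, include.lowest = TRUE))
  list(table = data.frame(bin = names(tab), count = as.integer(tab),
                          stringsAsFactors = FALSE),
       frac_ge = mean(x >= threshold))
}

#' Per-class share of counted reads
#'
#' The read-category partition (what fraction of counted reads fall on ORFs,
#' known sRNAs, structural RNAs and IORs). Shares sum to 1 over counted reads.
#'
#' @param cm A `count_matrix`.
#' @return Named numeric vector of fractions.
#' @export
category_fractions <- function(cm) {
  tot <- tapply(rowSums(cm$counts), cm$class, sum)
  tot <- tot / sum(tot)
  tot[order(names(tot))]
}
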