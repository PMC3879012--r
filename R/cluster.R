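# Expression-pattern analysis: log ratio matrices versus the matched control
# time point, hierarchical clustering, and percentile abundance ranking.

#' Stress/control log2 ratio matrix
#'
#' For every (stressor, dose, time) contrast, the log2 ratio of the mean
#' normalized stress count to the mean normalized control count at the same
#' time point, with a pseudocount on both to handle zeros. Doubling a
#' library's raw counts together with its size factor leaves the matrix
#' unchanged.
#'
#' @param cm A `count_matrix` or plain count matrix.
#' @param design A [study_design()] table.
#' @param features Feature ids (default all rows).
#' @param sf Size factors (default: estimated).
#' @param pseudocount Pseudocount c (default 1) in
#'   `log2((stress + c)/(control + c))`.
#' @return List of class `ratio_matrix`: `ratios` (features x contrasts),
#'   `contrasts` (data frame describing the columns).
#' @export
ratio_matrix <- function(cm, design, features = NULL, sf = NULL, pseudocount = 1) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(features)) features <- rownames(counts)
  fidx <- match(features, rownames(counts))
  z <- sweep(counts[fidx, , drop = FALSE], 2, sf, "/")
  lvl <- unique(design[design$stressor != "none", c("stressor", "dose")])
  times <- sort(unique(design$time_min))
  cols <- list(); meta <- list()
  for (i in seq_len(nrow(lvl))) for (tm in times) {
    ctrl <- which(design$stressor == "none" & design$time_min == tm)
    strs <- which(design$stressor == lvl$stressor[i] &
                    design$dose == lvl$dose[i] & design$time_min == tm)
    if (length(ctrl) == 0L || length(strs) == 0L) next
    mc <- rowMeans(z[, ctrl, drop = FALSE])
    ms <- rowMeans(z[, strs, drop = FALSE])
    nm <- sprintf("%s_%s_t%02d", lvl$stressor[i], lvl$dose[i], tm)
    cols[[nm]] <- log2((ms + pseudocount) / (mc + pseudocount))
    meta[[nm]] <- data.frame(contrast = nm, stressor = lvl$stressor[i],
                             dose = lvl$dose[i], time_min = tm,
                             stringsAsFactors = FALSE)
  }
  ratios <- do.call(cbind, cols)
  rownames(ratios) <- features
  structure(list(ratios = ratios, contrasts = do.call(rbind, c(meta, list(make.row.names = FALSE)))),
            class = "ratio_matrix")
}

#' Hierarchical clustering of expression ratios
#'
#' Agglomerative clustering of the rows of a ratio matrix. The default
#' distance is Pearson correlation distance (1 - r); rows with zero variance
#' get distance 1 to every other row (with a message). Average linkage by
#' default; the tree is cut at `k` clusters.
#'
#' @param x A `ratio_matrix` or plain numeric matrix (features x contrasts).
#' @param distance `"pearson"` or `"euclidean"`.
#' @param linkage Linkage method for [stats::hclust()].
#' @param k Number of clusters at the cut.
#' @return List of class `cluster_result`: `tree` (hclust), `labels` (named
#'   cluster ids), `leaf_order` (feature ids in dendrogram order), `k`.
#' @export
hcluster <- function(x, distance = c("pearson", "euclidean"),
                     linkage = "average", k = 4) {
  distance <- match.arg(distance)
  m <- if (inherits(x, "ratio_matrix")) x$ratios else x
  stopifnot(is.matrix(m), nrow(m) >= 2)
  if (distance == "pearson") {
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0))
      .msgf("hcluster: %d constant row(s); correlation distance set to 1",
            sum(sds == 0))
    r <- suppressWarnings(stats::cor(t(m)))
    r[!is.finite(r)] <- 0
    diag(r) <- 1
    d <- stats::as.dist(1 - r)
  } else {
    d <- stats::dist(m)
  }
  tree <- stats::hclust(d, method = linkage)
  k <- min(k, nrow(m))
  labels <- stats::cutree(tree, k = k)
  structure(list(tree = tree, labels = labels,
                 leaf_order = rownames(m)[tree$order], k = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d features in %d clusters\n",
              length(x$labels), x$k))
  print(table(x$labels))
  invisible(x)
}

#' Percentile abundance ranks
#'
#' Within each library, normalized counts are ranked ascending and mapped to
#' percentiles `100 (r - 1)/(n - 1)`; ties receive the mean of their
#' positions' percentiles. A single-feature matrix ranks 100 by convention.
#'
#' @param cm A `count_matrix` or plain count matrix.
#' @param sf Size factors (default: estimated).
#' @return Matrix of percentile ranks in \[0, 100\], same shape as the counts.
#' @export
percentile_rank <- function(cm, sf = NULL) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (is.null(sf)) sf <- size_factors(counts)
  z <- sweep(counts, 2, sf, "/")
  n <- nrow(z)
  if (n == 1L) {
    .msgf("percentile_rank: single feature; rank 100 by convention")
    out <- z; out[] <- 100
    return(out)
  }
  apply(z, 2, function(x) 100 * (rank(x, ties.method = "average") - 1) / (n - 1))
}
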