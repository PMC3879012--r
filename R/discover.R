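# Novel-sRNA calling: threshold expressed IORs, intersect with the
# computational prediction track, eliminate UTR-bleed false positives, and
# name the survivors.

#' Call expressed IORs by read-count threshold
#'
#' An IOR passes iff its raw count reaches `min_count` in at least
#' `ceiling(min_library_fraction * n_libraries)` libraries. The default quorum
#' is a single library: the permissive reading that retains
#' condition-specific sRNAs. Counts are raw (un-normalized) sums per library,
#' as the threshold is calibrated on the raw read-count distribution.
#'
#' @param cm A `count_matrix` with IOR rows.
#' @param min_count Count threshold (default 50).
#' @param min_library_fraction Quorum as a fraction of libraries; `NULL`
#'   (default) means any single library.
#' @return Character vector of passing IOR ids.
#' @export
call_expressed_iors <- function(cm, min_count = 50, min_library_fraction = NULL) {
  if (!is.numeric(min_count) || min_count < 0)
    .stopf("min_count must be a nonnegative number")
  rows <- which(cm$class == "ior")
  if (length(rows) == 0L) .stopf("count matrix has no IOR rows")
  quorum <- if (is.null(min_library_fraction)) 1L
            else max(1L, ceiling(min_library_fraction * ncol(cm$counts)))
  x <- cm$counts[rows, , drop = FALSE]
  pass <- rowSums(x >= min_count) >= quorum
  rownames(x)[pass]
}

#' Intersect expressed IORs with the prediction track
#'
#' An expressed IOR becomes a candidate when it contains at least one
#' computationally predicted sRNA interval (any overlap of >= 1 nt).
#' Predictions corresponding to already-known sRNAs are excluded via
#' `exclude_ids`.
#'
#' @param expressed_iors IOR table rows (from [derive_iors()]) restricted to
#'   expressed IORs, or the full table plus an `expressed` id vector.
#' @param predictions Prediction track (`id`, `start`, `end`).
#' @param exclude_ids Prediction ids to ignore (the known-sRNA analogue).
#' @return Named list mapping each expressed IOR id to the character vector of
#'   overlapping (non-excluded) prediction ids.
#' @export
intersect_predictions <- function(expressed_iors, predictions,
                                  exclude_ids = character()) {
  preds <- predictions[!(predictions$id %in% exclude_ids), , drop = FALSE]
  out <- stats::setNames(vector("list", nrow(expressed_iors)), expressed_iors$id)
  if (nrow(preds) == 0L) {
    out[] <- list(character())
    return(out)
  }
  iir <- .as_iranges(expressed_iors$start, expressed_iors$end)
  pir <- .as_iranges(preds$start, preds$end)
  ov <- IRanges::findOverlaps(iir, pir)
  for (i in seq_len(nrow(expressed_iors)))
    out[[i]] <- preds$id[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]
  out
}

#' UTR false-positive filter
#'
#' Eliminates candidates whose reads come predominantly from the untranslated
#' ends of a neighboring gene's transcript: a candidate is `fp_utr` iff the
#' share of its coverage lying in the two `w`-nt flank windows reaches
#' `dominance` AND the neighbor ORF adjacent to the dominant flank is itself
#' expressed (count >= `neighbor_min` in at least one library). IORs no longer
#' than `w` cannot be assessed (the window is the whole IOR); they are
#' retained and flagged for manual review.
#'
#' @param coverage Integer coverage vector over the IOR (pooled over
#'   libraries), from [coverage_profile()].
#' @param ior_start,ior_end IOR interval.
#' @param neighbor_counts Named numeric: `left`, `right` maximum per-library
#'   counts of the two neighbor ORFs (`NA` when absent).
#' @param w Flank window width (default 50 nt).
#' @param dominance Minimum flank coverage share (default 0.8).
#' @param neighbor_min Neighbor expression threshold (default 50).
#' @return List: `fp` (logical), `flank_share`, `dominant_side`,
#'   `utr_left_fraction`, `utr_right_fraction`, `manual_review` (logical).
#' @export
utr_fp_filter <- function(coverage, ior_start, ior_end, neighbor_counts,
                          w = 50, dominance = 0.8, neighbor_min = 50) {
  len <- ior_end - ior_start
  stopifnot(length(coverage) == len, w >= 1)
  tot <- sum(coverage)
  fw <- flank_windows(ior_start, ior_end, w)
  li <- (fw$left[1] - ior_start + 1):(fw$left[2] - ior_start)
  ri <- (fw$right[1] - ior_start + 1):(fw$right[2] - ior_start)
  lfrac <- if (tot > 0) sum(coverage[li]) / tot else 0
  rfrac <- if (tot > 0) sum(coverage[ri]) / tot else 0
  share <- if (tot > 0) sum(coverage[union(li, ri)]) / tot else 0
  side <- if (lfrac >= rfrac) "left" else "right"
  if (len <= w)
    return(list(fp = FALSE, flank_share = share, dominant_side = side,
                utr_left_fraction = lfrac, utr_right_fraction = rfrac,
                manual_review = TRUE))
  nb <- neighbor_counts[[side]]
  fp <- share >= dominance && !is.na(nb) && nb >= neighbor_min
  list(fp = isTRUE(fp), flank_share = share, dominant_side = side,
       utr_left_fraction = lfrac, utr_right_fraction = rfrac,
       manual_review = FALSE)
}

#' Name surviving candidates
#'
#' Deterministic names in the `sCAC<n>` style, where `n` is the locus number
#' of the nearest downstream ORF (the right neighbor; falls back to the left
#' neighbor for terminal IORs). Multiple survivors sharing a reference ORF are
#' suffixed `a`, `b`, ... in genomic order.
#'
#' @param survivors IOR table rows of surviving candidates (sorted or not).
#' @param orfs ORF table (`id`, `start`, `end`).
#' @return Character vector of names, parallel to `survivors` rows.
#' @export
name_candidates <- function(survivors, orfs) {
  if (nrow(survivors) == 0L) return(character())
  ord <- order(survivors$start)
  ref <- character(nrow(survivors))
  o <- orfs[order(orfs$start), , drop = FALSE]
  for (i in seq_len(nrow(survivors))) {
    ri <- which(o$start >= survivors$end[i])
    li <- which(o$end <= survivors$start[i])
    ref[i] <- if (length(ri)) o$id[min(ri)]
              else if (length(li)) o$id[max(li)] else NA_character_
  }
  num <- as.integer(sub("\\D+", "", ref))
  base <- ifelse(is.na(num), "sCAC0", sprintf("sCAC%d", num))
  names_out <- base
  for (b in unique(base[duplicated(base)])) {
    idx <- which(base == b)
    idx <- idx[order(survivors$start[idx])]
    names_out[idx] <- paste0(b, letters[seq_along(idx)])
  }
  names_out
}

#' Run the full candidate-calling procedure
#'
#' Composes the threshold call, the prediction intersection, and the UTR
#' false-positive filter into a per-IOR candidate ledger, assigning each IOR a
#' status: `not_expressed`, `expressed_no_prediction`, `fp_utr`, or
#' `novel_srna` (named).
#'
#' @param cm A `count_matrix` (with IOR and ORF rows).
#' @param iors IOR table from [derive_iors()].
#' @param orfs ORF table (`id`, `start`, `end`) used for naming survivors;
#'   defaults to the ORF rows recorded in `cm`.
#' @param readsets Named list of read data frames (for coverage pooling).
#' @param predictions Prediction track (`id`, `start`, `end`).
#' @param exclude_ids Prediction ids on the known-sRNA exclusion list.
#' @param min_count,min_library_fraction Threshold parameters
#'   ([call_expressed_iors()]).
#' @param w,dominance,neighbor_min UTR filter parameters ([utr_fp_filter()]).
#' @return Data frame ledger, one row per IOR, with all intermediate fields
#'   (`qualifying_count`, `passed_threshold`, `predictions_in_ior`,
#'   `utr_left_fraction`, `utr_right_fraction`, `flank_share`,
#'   `neighbor_left_count`, `neighbor_right_count`, `manual_review`, `status`,
#'   `assigned_name`).
#' @export
discover_candidates <- function(cm, iors, readsets, predictions,
                                exclude_ids = character(),
                                min_count = 50, min_library_fraction = NULL,
                                w = 50, dominance = 0.8, neighbor_min = 50,
                                orfs = NULL) {
  if (is.null(orfs)) {
    if (is.null(cm$features)) .stopf("supply `orfs` when cm carries no feature table")
    orfs <- cm$features[cm$class == "orf", c("id", "start", "end")]
  }
  expressed <- call_expressed_iors(cm, min_count, min_library_fraction)
  led <- iors
  ior_counts <- cm$counts[match(iors$id, rownames(cm$counts)), , drop = FALSE]
  led$qualifying_count <- apply(ior_counts, 1, max)
  led$passed_threshold <- led$id %in% expressed

  hits <- intersect_predictions(iors[led$passed_threshold, , drop = FALSE],
                                predictions, exclude_ids)
  led$predictions_in_ior <- ""
  led$predictions_in_ior[led$passed_threshold] <-
    vapply(hits, paste, character(1), collapse = ",")

  # pooled coverage per candidate IOR
  nb_count <- function(orf_id) {
    if (is.na(orf_id)) return(NA_real_)
    max(cm$counts[match(orf_id, rownames(cm$counts)), ])
  }
  led$utr_left_fraction <- NA_real_; led$utr_right_fraction <- NA_real_
  led$flank_share <- NA_real_; led$manual_review <- FALSE
  led$neighbor_left_count <- vapply(led$left_neighbor, nb_count, 0)
  led$neighbor_right_count <- vapply(led$right_neighbor, nb_count, 0)
  led$status <- "not_expressed"
  led$status[led$passed_threshold] <- "expressed_no_prediction"

  cand <- which(led$passed_threshold & nzchar(led$predictions_in_ior))
  for (i in cand) {
    cov <- integer(led$end[i] - led$start[i])
    for (r in readsets) {
      cv <- coverage_profile(r, led$start[i], led$end[i])
      cov <- cov + cv
    }
    res <- utr_fp_filter(cov, led$start[i], led$end[i],
                         list(left = led$neighbor_left_count[i],
                              right = led$neighbor_right_count[i]),
                         w = w, dominance = dominance,
                         neighbor_min = neighbor_min)
    led$utr_left_fraction[i] <- res$utr_left_fraction
    led$utr_right_fraction[i] <- res$utr_right_fraction
    led$flank_share[i] <- res$flank_share
    led$manual_review[i] <- res$manual_review
    led$status[i] <- if (res$fp) "fp_utr" else "novel_srna"
  }
  led$assigned_name <- NA_character_
  surv <- which(led$status == "novel_srna")
  if (length(surv))
    led$assigned_name[surv] <- name_candidates(led[surv, , drop = FALSE], orfs)
  led
}
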