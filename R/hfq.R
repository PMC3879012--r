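# Rule-based Hfq-binding motif classification of sRNA sequences.
#
# The Hfq chaperone binds many trans-acting sRNAs at U-rich elements around
# their Rho-independent terminator: a poly-U tail at the 3' end (downstream of
# the terminator stem) and a U-rich or AU-rich region upstream of the stem.
# The classifier operationalizes that description with explicit, configurable
# thresholds (these defaults are this package's, stated so the rule is
# reproducible).

#' Classify an sRNA as a putative Hfq target
#'
#' Positive iff (a) a terminator hairpin is found with its 5' stem arm in the
#' 3' half of the sequence, (b) at least `tail_min_u` U's occur within
#' `tail_window` nt downstream of that stem, and (c) the `up_window` nt
#' upstream of the stem are U-rich (U fraction >= `u_rich_min`) or AU-rich
#' (A+U fraction >= `au_rich_min`). Criteria (b) and (c) are evaluated on the
#' top-scoring 3'-half hit — the hairpin a terminator caller would report —
#' so that ablating the poly-U tail of the terminator reliably flips the
#' call. Windows truncated by the sequence ends are evaluated as-is and
#' flagged low-confidence.
#'
#' @param seq sRNA sequence, 5' to 3' (ACGT/ACGU).
#' @param tail_min_u Minimum U count in the tail window (default 5).
#' @param tail_window Tail window downstream of the stem (default 10 nt).
#' @param up_window Upstream window before the stem (default 25 nt).
#' @param u_rich_min U-fraction threshold for the upstream window.
#' @param au_rich_min A+U-fraction threshold for the upstream window.
#' @param ... Passed to [find_terminators()].
#' @return List of class `hfq_call`: `is_hfq_target`, rationale booleans
#'   (`has_terminator_3p`, `tail_ok`, `upstream_ok`), `tail_u_count_in_window`,
#'   `upstream_u_fraction`, `upstream_au_fraction`, `low_confidence`, and the
#'   selected `terminator` hit (one-row data frame or NULL).
#' @export
classify_hfq <- function(seq, tail_min_u = 5, tail_window = 10, up_window = 25,
                         u_rich_min = 0.40, au_rich_min = 0.70, ...) {
  chars <- .norm_seq_chars(seq)
  L <- length(chars)
  hits <- tryCatch(find_terminators(seq, ...),
                   error = function(e) NULL)
  empty_call <- function(term_present) list(
    is_hfq_target = FALSE, has_terminator_3p = term_present, tail_ok = FALSE,
    upstream_ok = FALSE, tail_u_count_in_window = 0L,
    upstream_u_fraction = NA_real_, upstream_au_fraction = NA_real_,
    low_confidence = FALSE, terminator = NULL)
  if (is.null(hits) || nrow(hits) == 0L) {
    out <- empty_call(FALSE)
    class(out) <- "hfq_call"
    return(out)
  }
  h3 <- hits[hits$stem5_start > L / 2, , drop = FALSE]
  if (nrow(h3) == 0L) {
    out <- empty_call(FALSE)
    class(out) <- "hfq_call"
    return(out)
  }
  eval_hit <- function(hit) {
    tail_idx <- (hit$stem3_end + 1L):min(L, hit$stem3_end + tail_window)
    tail_idx <- tail_idx[tail_idx >= 1 & tail_idx <= L & tail_idx > hit$stem3_end]
    tail_u <- sum(chars[tail_idx] == "T")
    up_idx <- max(1L, hit$stem5_start - up_window):(hit$stem5_start - 1L)
    up_idx <- up_idx[up_idx >= 1]
    uf <- if (length(up_idx)) mean(chars[up_idx] == "T") else NA_real_
    auf <- if (length(up_idx)) mean(chars[up_idx] %in% c("A", "T")) else NA_real_
    low <- (hit$stem3_end + tail_window > L) ||
      (hit$stem5_start - up_window < 1L)
    list(tail_u = tail_u, tail_ok = tail_u >= tail_min_u,
         uf = uf, auf = auf,
         up_ok = isTRUE(uf >= u_rich_min) || isTRUE(auf >= au_rich_min),
         low = low)
  }
  chosen <- h3[1, , drop = FALSE]       # hits arrive sorted by score desc
  ev <- eval_hit(chosen)
  out <- list(
    is_hfq_target = ev$tail_ok && ev$up_ok,
    has_terminator_3p = TRUE, tail_ok = ev$tail_ok, upstream_ok = ev$up_ok,
    tail_u_count_in_window = ev$tail_u,
    upstream_u_fraction = ev$uf, upstream_au_fraction = ev$auf,
    low_confidence = ev$low, terminator = chosen)
  class(out) <- "hfq_call"
  out
}

#' @export
print.hfq_call <- function(x, ...) {
  cat(sprintf("<hfq_call> %s (terminator3'=%s tail=%s upstream=%s)%s\n",
              if (x$is_hfq_target) "Hfq target" else "not an Hfq target",
              x$has_terminator_3p, x$tail_ok, x$upstream_ok,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Classify a set of sRNA sequences
#'
#' @param seqs Named character vector of sRNA sequences.
#' @param ... Passed to [classify_hfq()].
#' @return Data frame with one row per sequence (id, call fields, and the
#'   terminator stem position when present).
#' @export
classify_hfq_set <- function(seqs, ...) {
  rows <- lapply(seq_along(seqs), function(i) {
    cl <- classify_hfq(seqs[[i]], ...)
    data.frame(srna_id = names(seqs)[i],
               is_hfq_target = cl$is_hfq_target,
               has_terminator_3p = cl$has_terminator_3p,
               tail_ok = cl$tail_ok, upstream_ok = cl$upstream_ok,
               tail_u_count_in_window = cl$tail_u_count_in_window,
               upstream_u_fraction = cl$upstream_u_fraction,
               upstream_au_fraction = cl$upstream_au_fraction,
               low_confidence = cl$low_confidence,
               stem5_start = if (!is.null(cl$terminator)) cl$terminator$stem5_start else NA_integer_,
               stem3_end = if (!is.null(cl$terminator)) cl$terminator$stem3_end else NA_integer_,
               u_tail_len = if (!is.null(cl$terminator)) cl$terminator$u_tail_len else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
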