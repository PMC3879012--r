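# Rho-independent terminator detection: enumeration of inverted repeats
# (stem-loop) followed by a poly-U tract, scored by pairing content. This is a
# combinatorial detector, not a thermodynamic folder: the score counts paired
# bases (GC pairs weighted up), penalizes mismatches, and rewards the poly-U
# tail, which is sufficient for the rule-based downstream Hfq classification
# and is exactly testable against brute-force enumeration.

.norm_seq_chars <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  chars[chars == "U"] <- "T"
  bad <- which(!(chars %in% c("A", "C", "G", "T")))
  if (length(bad))
    .stopf("invalid character '%s' at position %d", chars[bad[1]], bad[1])
  chars
}

# Length of the T run starting at each position.
.t_runlen <- function(chars) {
  n <- length(chars)
  run <- integer(n)
  i <- n
  while (i >= 1) {
    run[i] <- if (chars[i] == "T") (if (i < n) run[i + 1L] else 0L) + 1L else 0L
    i <- i - 1L
  }
  run
}

#' Find Rho-independent terminator hairpins
#'
#' Enumerates all inverted-repeat placements with stem length in
#' `[stem_min, stem_max]` and loop length in `[loop_min, loop_max]`, allowing
#' up to `max_mismatch` unpaired stem positions and (optionally) G-U wobble
#' pairs. Each hit records the longest poly-U run starting within `tail_gap`
#' nt downstream of the 3' stem arm and is scored
#' `paired_bases + 0.5 * GC_pairs - mismatches + min(u_tail_len, 8)`.
#'
#' @param seq Nucleotide string (ACGT/ACGU, case-insensitive).
#' @param stem_min,stem_max Stem arm length bounds (nt).
#' @param loop_min,loop_max Loop length bounds (nt).
#' @param max_mismatch Maximum unpaired stem positions.
#' @param allow_wobble Count G-U as a pair.
#' @param tail_gap Maximum gap (nt) between the stem 3' end and the poly-U run.
#' @param score_min Minimum reported score (default 8).
#' @return Data frame of hits, sorted by score (desc) then leftmost position:
#'   1-based inclusive positions `stem5_start`, `stem5_end`, `loop_start`,
#'   `loop_end`, `stem3_start`, `stem3_end`, plus `paired_bases`,
#'   `wobble_pairs`, `mismatches`, `u_tail_len`, `score`.
#' @export
find_terminators <- function(seq, stem_min = 6, stem_max = 12, loop_min = 3,
                             loop_max = 10, max_mismatch = 1,
                             allow_wobble = TRUE, tail_gap = 3, score_min = 8) {
  chars <- .norm_seq_chars(seq)
  L <- length(chars)
  if (L < 2 * stem_min + loop_min)
    .stopf("sequence shorter than the minimal hairpin (%d nt)",
           2 * stem_min + loop_min)
  run <- .t_runlen(chars)
  hits <- list()
  for (s in stem_min:stem_max) {
    for (l in loop_min:loop_max) {
      span <- 2L * s + l
      if (span > L) next
      i <- seq_len(L - span + 1L)
      m1 <- outer(i, 0:(s - 1L), "+")                 # 5' arm, 5'->3'
      m2 <- outer(i + span - 1L, 0:(s - 1L), "-")     # 3' arm, pairing order
      a1 <- matrix(chars[m1], ncol = s)
      a2 <- matrix(chars[m2], ncol = s)
      comp <- unname(.complement[a1]) == a2
      wob <- (a1 == "G" & a2 == "T") | (a1 == "T" & a2 == "G")
      dim(comp) <- dim(wob) <- dim(a1)
      paired <- comp | (allow_wobble & wob & !comp)
      mm <- s - rowSums(paired)
      ok <- which(mm <= max_mismatch)
      if (!length(ok)) next
      gc <- rowSums((a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G"))
      wobn <- rowSums(wob & !comp & allow_wobble)
      end3 <- i + span - 1L
      tail_pos <- pmin(L + 1L, end3 + 1L)
      u_tail <- vapply(ok, function(r) {
        p <- (end3[r] + 1L):(end3[r] + 1L + tail_gap)
        p <- p[p <= L]
        if (!length(p)) 0L else max(run[p])
      }, 0L)
      score <- (s - mm[ok]) + 0.5 * gc[ok] - mm[ok] + pmin(u_tail, 8L)
      keep <- score >= score_min
      if (!any(keep)) next
      ii <- ok[keep]
      hits[[length(hits) + 1L]] <- data.frame(
        stem5_start = i[ii], stem5_end = i[ii] + s - 1L,
        loop_start = i[ii] + s, loop_end = i[ii] + s + l - 1L,
        stem3_start = i[ii] + s + l, stem3_end = end3[ii],
        paired_bases = s - mm[ii], wobble_pairs = wobn[ii],
        mismatches = mm[ii], u_tail_len = u_tail[keep], score = score[keep])
    }
  }
  if (!length(hits))
    return(data.frame(stem5_start = integer(), stem5_end = integer(),
                      loop_start = integer(), loop_end = integer(),
                      stem3_start = integer(), stem3_end = integer(),
                      paired_bases = integer(), wobble_pairs = integer(),
                      mismatches = integer(), u_tail_len = integer(),
                      score = numeric()))
  out <- do.call(rbind, hits)
  out <- out[order(-out$score, out$stem5_start, out$stem3_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
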