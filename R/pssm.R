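# Position-specific scoring matrices and the two-box (sigma-factor style)
# promoter scan.

#' Build a PSSM from aligned binding sites
#'
#' Per-position, per-base log-odds
#' `log2(((count + pseudocount) / (n + 4 pseudocount)) / background)`.
#' The consensus attains the per-position maximum (ties broken in ACGT order).
#'
#' @param sites Character vector of equal-length aligned sites (ACGT).
#' @param pseudocount Added to each base count (default 0.5).
#' @param background Named base frequencies (default uniform).
#' @return Object of class `pssm`: `mat` (4 x width log-odds), `counts`,
#'   `consensus`, `background`, `pseudocount`, `n`.
#' @export
build_pssm <- function(sites, pseudocount = 0.5,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(length(sites) >= 1)
  sites <- toupper(sites)
  w <- unique(nchar(sites))
  if (length(w) != 1L) .stopf("aligned sites must have equal lengths")
  background <- background[c("A", "C", "G", "T")]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-6)
    .stopf("background must be named frequencies over A,C,G,T summing to 1")
  m <- do.call(rbind, strsplit(sites, ""))
  if (any(!(m %in% c("A", "C", "G", "T"))))
    .stopf("sites must be over the ACGT alphabet")
  n <- length(sites)
  counts <- vapply(seq_len(w), function(j)
    c(A = sum(m[, j] == "A"), C = sum(m[, j] == "C"),
      G = sum(m[, j] == "G"), T = sum(m[, j] == "T")), numeric(4))
  counts <- matrix(counts, nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  freq <- (counts + pseudocount) / (n + 4 * pseudocount)
  mat <- log2(freq / background)
  consensus <- paste(rownames(mat)[apply(mat, 2, which.max)], collapse = "")
  structure(list(mat = mat, counts = counts, consensus = consensus,
                 background = background, pseudocount = pseudocount, n = n),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> width %d, consensus %s (n=%d sites, pseudocount=%g)\n",
              ncol(x$mat), x$consensus, x$n, x$pseudocount))
  invisible(x)
}

#' Score a PSSM at every placement of a sequence
#'
#' @param seq Nucleotide string.
#' @param pssm A [build_pssm()] object.
#' @return Numeric vector of scores, one per start position (1-based);
#'   length `nchar(seq) - width + 1`.
#' @export
scan_pssm <- function(seq, pssm) {
  chars <- .norm_seq_chars(seq)
  w <- ncol(pssm$mat)
  L <- length(chars)
  if (L < w) return(numeric())
  base_idx <- match(chars, c("A", "C", "G", "T"))
  scores <- numeric(L - w + 1L)
  for (j in seq_len(w))
    scores <- scores + pssm$mat[cbind(base_idx[j:(L - w + j)], j)]
  scores
}

#' Scan for two-box promoters
#'
#' Scores all placements of a -35 box and a -10 box separated by a spacer in
#' `[spacer_min, spacer_max]` nt; the combined score is the sum of the two box
#' scores. Hits are sorted by combined score (desc), then position.
#'
#' @param seq Nucleotide string to scan.
#' @param pssm35,pssm10 PSSMs for the -35 and -10 boxes.
#' @param spacer_min,spacer_max Spacer length bounds (defaults 15-19, a
#'   sigma-A-like range).
#' @param score_min Minimum reported combined score.
#' @return Data frame of hits: `minus35_pos`, `minus10_pos` (1-based),
#'   `spacer_len`, `score35`, `score10`, `combined_score`.
#' @export
scan_promoter <- function(seq, pssm35, pssm10, spacer_min = 15, spacer_max = 19,
                          score_min = -Inf) {
  w35 <- ncol(pssm35$mat); w10 <- ncol(pssm10$mat)
  L <- nchar(seq)
  if (L < w35 + spacer_min + w10)
    .stopf("sequence shorter than the minimal promoter span (%d nt)",
           w35 + spacer_min + w10)
  s35 <- scan_pssm(seq, pssm35)
  s10 <- scan_pssm(seq, pssm10)
  rows <- list()
  for (sp in spacer_min:spacer_max) {
    i35 <- seq_len(max(0L, L - (w35 + sp + w10) + 1L))
    if (!length(i35)) next
    i10 <- i35 + w35 + sp
    comb <- s35[i35] + s10[i10]
    keep <- which(comb >= score_min)
    if (!length(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      minus35_pos = i35[keep], minus10_pos = i10[keep], spacer_len = sp,
      score35 = s35[i35[keep]], score10 = s10[i10[keep]],
      combined_score = comb[keep])
  }
  if (!length(rows))
    return(data.frame(minus35_pos = integer(), minus10_pos = integer(),
                      spacer_len = integer(), score35 = numeric(),
                      score10 = numeric(), combined_score = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$combined_score, out$minus35_pos, out$spacer_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus sigma-A promoter PSSMs
#'
#' The canonical housekeeping sigma factor recognizes TTGACA (-35) and TATAAT
#' (-10); these single-site PSSMs provide the standard worked example for
#' [scan_promoter()].
#'
#' @param pseudocount,background Passed to [build_pssm()].
#' @return List with elements `p35` and `p10`.
#' @export
sigma_a_pssms <- function(pseudocount = 0.5,
                          background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  list(p35 = build_pssm("TTGACA", pseudocount, background),
       p10 = build_pssm("TATAAT", pseudocount, background))
}

#' Write/read a PSSM in a JASPAR-like count format
#'
#' Count matrix with one row per base, preceded by a header line and a comment
#' line declaring the background and pseudocount.
#'
#' @param pssm A `pssm` object.
#' @param path File path.
#' @param name Motif name for the header.
#' @return `read_pssm` returns a `pssm` rebuilt from counts.
#' @export
write_pssm <- function(pssm, path, name = "motif") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(">%s", name), con)
  writeLines(sprintf("; background A=%g C=%g G=%g T=%g pseudocount=%g n=%d",
                     pssm$background["A"], pssm$background["C"],
                     pssm$background["G"], pssm$background["T"],
                     pssm$pseudocount, pssm$n), con)
  for (b in c("A", "C", "G", "T"))
    writeLines(sprintf("%s [ %s ]", b,
                       paste(pssm$counts[b, ], collapse = " ")), con)
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, ";")][1]
  get <- function(key) as.numeric(sub(sprintf(".*%s=([0-9.eE+-]+).*", key), "\\1", meta))
  bg <- c(A = get("A"), C = get("C"), G = get("G"), T = get("T"))
  pc <- get("pseudocount"); n <- as.integer(get("n"))
  rows <- lines[grepl("^[ACGT] \\[", lines)]
  counts <- do.call(rbind, lapply(rows, function(r) {
    as.numeric(strsplit(trimws(sub(".*\\[(.*)\\].*", "\\1", r)), "\\s+")[[1]])
  }))
  rownames(counts) <- substr(rows, 1, 1)
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  freq <- (counts + pc) / (n + 4 * pc)
  mat <- log2(freq / bg)
  consensus <- paste(rownames(mat)[apply(mat, 2, which.max)], collapse = "")
  structure(list(mat = mat, counts = counts, consensus = consensus,
                 background = bg, pseudocount = pc, n = n), class = "pssm")
}
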