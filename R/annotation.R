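#' Assemble a genome annotation
#'
#' Bundles the coordinate backbone of a bacterial contig: ORFs, operons
#' (ordered groups of ORFs with a covering span), known sRNAs, computationally
#' predicted sRNAs, and optionally high-abundance structural RNAs (rRNA/tRNA
#' analogues). All coordinates are 0-based half-open internally; GFF3 export
#' converts to the 1-based inclusive convention.
#'
#' @param contig_id Contig name.
#' @param contig_length Contig length in nucleotides.
#' @param orfs Data frame with columns `id`, `start`, `end`, `strand`.
#' @param operons Data frame with columns `id`, `start`, `end`, `strand` and a
#'   list-column `members` of ORF ids in genomic order. The span of each operon
#'   must cover exactly the union of its members' intervals.
#' @param known_srnas,predicted_srnas,structural_rnas Optional feature data
#'   frames (`id`, `start`, `end`, `strand`).
#' @param sequence Optional nucleotide string of length `contig_length`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(contig_id, contig_length, orfs,
                              operons = NULL,
                              known_srnas = .empty_features(),
                              predicted_srnas = .empty_features(),
                              structural_rnas = .empty_features(),
                              sequence = NULL) {
  stopifnot(.is_count(contig_length), contig_length > 0)
  if (is.null(operons)) {
    operons <- data.frame(id = character(), start = integer(), end = integer(),
                          strand = character(), stringsAsFactors = FALSE)
    operons$members <- list()
  }
  .check_intervals(orfs, "orfs", contig_length)
  .check_intervals(operons, "operons", contig_length)
  .check_intervals(known_srnas, "known_srnas", contig_length)
  .check_intervals(predicted_srnas, "predicted_srnas", contig_length)
  .check_intervals(structural_rnas, "structural_rnas", contig_length)
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != contig_length)
      .stopf("sequence length (%d) != contig_length (%d)",
             nchar(sequence), contig_length)
  }
  # operon span must equal the union of its members' intervals
  if (nrow(operons) > 0L) {
    if (is.null(operons$members))
      .stopf("operons must carry a 'members' list-column of ORF ids")
    for (i in seq_len(nrow(operons))) {
      m <- match(operons$members[[i]], orfs$id)
      if (anyNA(m))
        .stopf("operon %s refers to unknown ORF ids", operons$id[i])
      if (min(orfs$start[m]) != operons$start[i] ||
          max(orfs$end[m]) != operons$end[i])
        .stopf("operon %s span does not cover the union of its members",
               operons$id[i])
    }
  }
  structure(list(contig_id = contig_id,
                 contig_length = as.integer(contig_length),
                 sequence = sequence,
                 orfs = orfs, operons = operons,
                 known_srnas = known_srnas,
                 predicted_srnas = predicted_srnas,
                 structural_rnas = structural_rnas),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s (%d nt)%s\n", x$contig_id,
              x$contig_length, if (is.null(x$sequence)) "" else " +sequence"))
  cat(sprintf("  %d ORFs in %d operons; %d known sRNAs; %d predicted sRNAs; %d structural RNAs\n",
              nrow(x$orfs), nrow(x$operons), nrow(x$known_srnas),
              nrow(x$predicted_srnas), nrow(x$structural_rnas)))
  invisible(x)
}

#' Derive interoperonic regions (IORs)
#'
#' IORs are the maximal intervals of the contig not covered by any operon span.
#' ORFs not assigned to any operon are treated as singleton operons before the
#' complement is computed, so all gene-covered DNA is excluded. Overlapping
#' operon spans are merged with a warning. IORs are strandless. IORs sorted by
#' start receive consecutive ids (`INTEROP0001`, ...), and the nearest ORF on
#' each side is attached as `left_neighbor` / `right_neighbor`.
#'
#' @param annotation A [genome_annotation()].
#' @param include_terminal Include the contig segments before the first and
#'   after the last operon span (default `TRUE`).
#' @return Data frame: `id`, `start`, `end`, `left_neighbor`, `left_strand`,
#'   `right_neighbor`, `right_strand` (0-based half-open coordinates).
#' @export
derive_iors <- function(annotation, include_terminal = TRUE) {
  stopifnot(inherits(annotation, "genome_annotation"))
  len <- annotation$contig_length
  ops <- annotation$operons
  orfs <- annotation$orfs
  in_operon <- unlist(ops$members)
  loose <- orfs[!(orfs$id %in% in_operon), , drop = FALSE]
  spans_start <- c(ops$start, loose$start)
  spans_end <- c(ops$end, loose$end)

  if (length(spans_start) == 0L) {
    out <- if (include_terminal)
      data.frame(start = 0L, end = len) else data.frame(start = integer(), end = integer())
  } else {
    ir <- .as_iranges(spans_start, spans_end)
    n_ov <- length(IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE))
    if (n_ov > 0L)
      warning(sprintf("%d overlapping operon span pair(s) merged", n_ov),
              call. = FALSE)
    merged <- IRanges::reduce(ir)
    gaps <- IRanges::gaps(merged, start = 1L, end = len)
    out <- data.frame(start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps))
    if (!include_terminal) {
      first_span <- min(IRanges::start(merged)) - 1L
      last_span <- max(IRanges::end(merged))
      out <- out[out$start >= first_span & out$end <= last_span, , drop = FALSE]
    }
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  n <- nrow(out)
  out$id <- sprintf("INTEROP%04d", seq_len(n))
  # nearest ORF neighbors (left: max end <= start; right: min start >= end)
  left_id <- character(n); left_str <- character(n)
  right_id <- character(n); right_str <- character(n)
  if (nrow(orfs) > 0L && n > 0L) {
    o <- orfs[order(orfs$start), , drop = FALSE]
    for (i in seq_len(n)) {
      li <- which(o$end <= out$start[i])
      ri <- which(o$start >= out$end[i])
      left_id[i] <- if (length(li)) o$id[max(li)] else NA_character_
      left_str[i] <- if (length(li)) o$strand[max(li)] else NA_character_
      right_id[i] <- if (length(ri)) o$id[min(ri)] else NA_character_
      right_str[i] <- if (length(ri)) o$strand[min(ri)] else NA_character_
    }
  } else {
    left_id[] <- NA_character_; left_str[] <- NA_character_
    right_id[] <- NA_character_; right_str[] <- NA_character_
  }
  data.frame(id = out$id, start = out$start, end = out$end,
             left_neighbor = left_id, left_strand = left_str,
             right_neighbor = right_id, right_strand = right_str,
             stringsAsFactors = FALSE)
}

#' Flank windows of an IOR
#'
#' The leftmost and rightmost `w`-nt sub-intervals of an IOR, adjacent to its
#' neighboring ORFs. For an IOR shorter than `2w` the two windows overlap; for
#' an IOR of length `<= w` both windows equal the IOR.
#'
#' @param start,end IOR interval (0-based half-open).
#' @param w Window width in nt (`>= 1`).
#' @return List with `left` and `right`, each `c(start, end)`.
#' @export
flank_windows <- function(start, end, w) {
  stopifnot(.is_count(w), w >= 1, end > start)
  len <- end - start
  ww <- min(w, len)
  list(left = c(start, start + ww), right = c(end - ww, end))
}
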