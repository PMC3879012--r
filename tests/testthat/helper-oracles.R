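# Independent brute-force oracles. These deliberately use naive per-base /
# all-pairs algorithms and plain string operations, so they share no code path
# with the implementations they check.

# Interval complement by per-base membership scan (0-based half-open).
oracle_complement <- function(spans, contig_length) {
  covered <- logical(contig_length)
  for (i in seq_len(nrow(spans)))
    covered[(spans$start[i] + 1):spans$end[i]] <- TRUE
  free <- which(!covered)
  if (!length(free)) return(data.frame(start = integer(), end = integer()))
  brk <- c(0, which(diff(free) > 1), length(free))
  data.frame(start = free[brk[-length(brk)] + 1] - 1L,
             end = free[brk[-1]])
}

# All-pairs read-feature overlap counting.
oracle_count <- function(reads, features, frac) {
  out <- integer(nrow(features))
  for (i in seq_len(nrow(reads))) {
    rl <- reads$end[i] - reads$start[i]
    for (j in seq_len(nrow(features))) {
      ov <- min(reads$end[i], features$end[j]) - max(reads$start[i], features$start[j])
      if (ov >= frac * rl) out[j] <- out[j] + 1L
    }
  }
  stats::setNames(out, features$id)
}

# Per-base pileup by membership counting.
oracle_coverage <- function(reads, s, e) {
  v <- integer(e - s)
  for (p in seq_len(e - s)) {
    pos <- s + p - 1L
    v[p] <- sum(reads$start <= pos & reads$end > pos)
  }
  v
}

# Exhaustive stem-loop enumeration with plain substring operations.
oracle_terminators <- function(seq, stem_min = 6, stem_max = 12, loop_min = 3,
                               loop_max = 10, max_mismatch = 1,
                               allow_wobble = TRUE, tail_gap = 3, score_min = 8) {
  seq <- gsub("U", "T", toupper(seq))
  L <- nchar(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  for (i in 1:L) for (s in stem_min:stem_max) for (l in loop_min:loop_max) {
    end3 <- i + 2 * s + l - 1
    if (end3 > L) next
    mm <- 0; wob <- 0; gc <- 0
    for (k in 0:(s - 1)) {
      x <- substr(seq, i + k, i + k)
      y <- substr(seq, end3 - k, end3 - k)
      if (comp[[x]] == y) {
        if ((x == "G" && y == "C") || (x == "C" && y == "G")) gc <- gc + 1
      } else if (allow_wobble && ((x == "G" && y == "T") || (x == "T" && y == "G"))) {
        wob <- wob + 1
      } else mm <- mm + 1
    }
    if (mm > max_mismatch) next
    ut <- 0
    for (d in 0:tail_gap) {
      p <- end3 + 1 + d
      run <- 0
      while (p + run <= L && substr(seq, p + run, p + run) == "T") run <- run + 1
      ut <- max(ut, run)
    }
    score <- (s - mm) + 0.5 * gc - mm + min(ut, 8)
    if (score < score_min) next
    rows[[length(rows) + 1]] <- data.frame(
      stem5_start = i, stem5_end = i + s - 1, loop_start = i + s,
      loop_end = i + s + l - 1, stem3_start = i + s + l, stem3_end = end3,
      paired_bases = s - mm, wobble_pairs = wob, mismatches = mm,
      u_tail_len = ut, score = score)
  }
  if (!length(rows))
    return(data.frame(stem5_start = integer(), stem5_end = integer(),
                      loop_start = integer(), loop_end = integer(),
                      stem3_start = integer(), stem3_end = integer(),
                      paired_bases = integer(), wobble_pairs = integer(),
                      mismatches = integer(), u_tail_len = integer(),
                      score = numeric()))
  out <- do.call(rbind, rows)
  out[order(-out$score, out$stem5_start, out$stem3_end), , drop = FALSE]
}

# Exhaustive two-box placement scoring with substring lookups.
oracle_scan_promoter <- function(seq, p35, p10, spacer_min = 15, spacer_max = 19) {
  seq <- toupper(seq)
  L <- nchar(seq)
  w35 <- ncol(p35$mat); w10 <- ncol(p10$mat)
  score_at <- function(p, pssm, w) {
    s <- 0
    for (j in 1:w) s <- s + pssm$mat[substr(seq, p + j - 1, p + j - 1), j]
    s
  }
  rows <- list()
  for (i in 1:L) for (sp in spacer_min:spacer_max) {
    i10 <- i + w35 + sp
    if (i10 + w10 - 1 > L) next
    rows[[length(rows) + 1]] <- data.frame(
      minus35_pos = i, minus10_pos = i10, spacer_len = sp,
      combined_score = score_at(i, p35, w35) + score_at(i10, p10, w10))
  }
  out <- do.call(rbind, rows)
  out[order(-out$combined_score, out$minus35_pos, out$spacer_len), , drop = FALSE]
}

# Sort-based percentile ranks within one vector.
oracle_percentile <- function(x) {
  n <- length(x)
  pct <- numeric(n)
  o <- order(x)
  r <- 1
  while (r <= n) {
    ties <- which(x[o] == x[o[r]])
    pct[o[ties]] <- mean(100 * (ties - 1) / (n - 1))
    r <- max(ties) + 1
  }
  pct
}

.read_tsv_test <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Small random fixtures ------------------------------------------------------

random_features <- function(n, contig_length, min_len = 20, max_len = 400) {
  start <- sort(sample(0:(contig_length - max_len - 1), n))
  len <- sample(min_len:max_len, n, replace = TRUE)
  data.frame(id = sprintf("F%03d", seq_len(n)), start = start,
             end = pmin(start + len, contig_length))
}

random_reads <- function(n, contig_length, read_length = 50) {
  start <- sample(0:(contig_length - read_length), n, replace = TRUE)
  data.frame(start = start, end = start + read_length)
}

random_nonoverlapping_operons <- function(n, contig_length) {
  # sequential placement with random gaps
  ops <- list(); pos <- sample(0:200, 1)
  for (k in seq_len(n)) {
    len <- sample(100:600, 1)
    if (pos + len >= contig_length) break
    ops[[k]] <- data.frame(id = sprintf("OP%02d", k), start = pos,
                           end = pos + len, strand = "+")
    pos <- pos + len + sample(50:400, 1)
  }
  do.call(rbind, ops)
}

# Tiny annotation with explicit operon membership for derive_iors tests.
make_annotation <- function(operon_spans, contig_length, orf_per_operon = 1) {
  orfs <- list(); ops <- operon_spans
  ops$members <- vector("list", nrow(ops))
  cnt <- 0
  for (i in seq_len(nrow(ops))) {
    cnt <- cnt + 1
    id <- sprintf("CAC%04d", cnt)
    orfs[[i]] <- data.frame(id = id, start = ops$start[i], end = ops$end[i],
                            strand = "+")
    ops$members[[i]] <- id
  }
  genome_annotation("contig1", contig_length, do.call(rbind, orfs), ops)
}

# Planted-cassette sRNA sequence (mirrors the generator's construction but
# assembled by hand here).
planted_hfq_seq <- function(len = 120) {
  head_len <- len - 53
  head <- paste(sample(c("A", "C", "G", "T"), head_len, replace = TRUE,
                       prob = c(0.355, 0.145, 0.145, 0.355)), collapse = "")
  up <- c(sample(c(rep("T", 10), rep("A", 5), rep("C", 3), rep("G", 3))),
          sample(c("T", "T", "T", "C")))   # no A/G abutting the stem
  up <- paste(up, collapse = "")
  stem <- paste(sample(c("G", "C"), 8, replace = TRUE), collapse = "")
  rc <- chartr("ACGT", "TGCA", stem)
  rc <- paste(rev(strsplit(rc, "")[[1]]), collapse = "")
  paste0(head, up, stem, "GAAA", rc, "TTTTTTTT")
}
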