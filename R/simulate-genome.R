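# Synthetic-data generator: study design and genome with planted features.
#
# The generator is first-class, tested code. It emulates the structure the
# analysis assumes: a low-GC bacterial contig tiled by operons, true sRNAs
# planted inside interoperonic regions (some carrying a Rho-independent
# terminator cassette with a poly-U tail), UTR-bleed decoys abutting operon
# boundaries, high-abundance structural RNAs, and a graded two-stressor,
# four-time-point study design.

.REF_DEPTH <- 50000L

#' Build the default metabolite-stress study design
#'
#' Seven culture conditions (an unstressed control plus low/medium/high doses
#' of butanol at 30/60/90 mM and of butyrate at 30/40/50 mM), sampled at 15,
#' 30, 60 and 75 minutes post stress, with a fixed number of biological
#' replicates per (condition, time) cell.
#'
#' @param replicates Replicates per (condition, time) cell (default 2, a
#'   desk-scale replica of the original 3-replicate design).
#' @param times Sampling times in minutes.
#' @param read_length Read length in nt (default 50).
#' @param depth Target mapped reads per library (default 50000).
#' @return Data frame of libraries with columns `library_id`, `condition_id`,
#'   `stressor`, `dose`, `dose_mM`, `time_min`, `replicate`; `read_length` and
#'   `depth` are carried as attributes.
#' @export
study_design <- function(replicates = 2, times = c(15, 30, 60, 75),
                         read_length = 50, depth = .REF_DEPTH) {
  stopifnot(.is_count(replicates), replicates >= 1)
  cond <- data.frame(
    stressor = c("none", rep("butanol", 3), rep("butyrate", 3)),
    dose = c("none", rep(c("low", "medium", "high"), 2)),
    dose_mM = c(0, 30, 60, 90, 30, 40, 50),
    stringsAsFactors = FALSE)
  cond$condition_id <- ifelse(cond$stressor == "none", "none",
                              paste(cond$stressor, cond$dose, sep = "_"))
  grid <- expand.grid(replicate = seq_len(replicates), time_min = times,
                      ci = seq_len(nrow(cond)))
  d <- data.frame(condition_id = cond$condition_id[grid$ci],
                  stressor = cond$stressor[grid$ci],
                  dose = cond$dose[grid$ci],
                  dose_mM = cond$dose_mM[grid$ci],
                  time_min = grid$time_min,
                  replicate = grid$replicate,
                  stringsAsFactors = FALSE)
  d$library_id <- sprintf("%s_t%02d_r%d", d$condition_id, d$time_min, d$replicate)
  d <- d[, c("library_id", "condition_id", "stressor", "dose", "dose_mM",
             "time_min", "replicate")]
  attr(d, "read_length") <- as.integer(read_length)
  attr(d, "depth") <- as.integer(depth)
  d
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp_chars <- function(chars) rev(unname(.complement[chars]))

# U-run suppression: single left-to-right pass replacing any T that would be
# the 5th T within a trailing 10-nt window, so no 10-nt window retains >= 5 U.
# Used for Hfq-negative planted sRNAs so that the poly-U tail criterion of the
# Hfq classifier cannot fire by chance.
.suppress_u_runs <- function(chars, window = 10L, max_t = 4L) {
  n <- length(chars)
  for (i in seq_len(n)) {
    if (chars[i] != "T") next
    lo <- max(1L, i - window + 1L)
    if (i > lo && sum(chars[lo:(i - 1L)] == "T") >= max_t) chars[i] <- "C"
  }
  chars
}

# Terminator + poly-U cassette with a U-rich upstream region (28 + `up` nt).
# The upstream window has fixed base composition (52% U, 72% A+U), shuffled,
# so the classifier's U-rich criterion is satisfied by construction, not by
# a random draw that could fall below threshold.
.hfq_cassette <- function(up = 25L) {
  comp <- c(rep("T", ceiling(0.52 * up)), rep("A", ceiling(0.20 * up)))
  comp <- c(comp, rep(c("C", "G"), length.out = up - length(comp)))
  upstream <- sample(comp)
  # the 4 nt abutting the stem must not be A/G: an A or G there can pair
  # (Watson-Crick or wobble) against the poly-U tail and extend the stem into
  # a register that swallows the tail
  upstream[(up - 3L):up] <- sample(c("T", "T", "T", "C"))
  stem <- sample(c("G", "C"), 8L, replace = TRUE)
  loop <- sample(c("A", "G"), 4L, replace = TRUE)
  c(upstream, stem, loop, .revcomp_chars(stem), rep("T", 8L))
}

#' Simulate a low-GC genome with planted features
#'
#' Lays out `n_operons` operons (1-5 ORFs each) along one contig, separated by
#' interoperonic gaps. Internal gaps host, in random order: true sRNAs
#' (48-300 nt, centered with >= 100 nt margins), known sRNAs (the analogue of a
#' previously predicted set, used as an exclusion list downstream), UTR-bleed
#' decoys (a 50-nt expression block at one IOR edge), structural RNAs
#' (rRNA/tRNA-like, very high abundance), or nothing. A fraction
#' `hfq_fraction` of the true and known sRNAs receive a spliced terminator +
#' poly-U cassette (Hfq-positive); the remaining sRNA sequences have U-runs
#' suppressed so that classification is separable by construction. The
#' computational-prediction track (a comparative-genomics stand-in) contains
#' one prediction per planted sRNA and per decoy.
#'
#' @param n_operons Number of operons (>= 2).
#' @param n_srnas,n_known,n_decoys,n_structural Planted feature counts; their
#'   sum must be at most `n_operons - 1` (one feature per internal gap).
#' @param gc Genome GC fraction (default 0.29, a low-GC clostridial genome).
#' @param contig_length Contig length in nt.
#' @param hfq_fraction Fraction of sRNAs built Hfq-positive.
#' @param orf_de_fraction Fraction of ORFs given a stress response.
#' @param seed Mandatory RNG seed.
#' @return List with `annotation` (a [genome_annotation()]) and `truth` (the
#'   truth table: one row per planted feature with class, interval, baseline
#'   mean, per-stressor response direction, and Hfq/terminator flags; dose fold
#'   changes `c(1.5, 2, 4)` and the time ramp are carried as attributes).
#' @export
simulate_genome <- function(n_operons = 48, n_srnas = 20, n_decoys = 10,
                            n_known = 5, n_structural = 4, gc = 0.29,
                            contig_length = 120000, hfq_fraction = 0.5,
                            orf_de_fraction = 0.1, seed) {
  stopifnot(!missing(seed), .is_count(seed))
  stopifnot(gc > 0, gc < 1, n_operons >= 2)
  n_special <- n_srnas + n_known + n_decoys + n_structural
  if (n_special > n_operons - 1)
    .stopf("cannot place %d features in %d internal gaps", n_special, n_operons - 1)
  set.seed(seed)

  roles <- sample(c(rep("srna", n_srnas), rep("known", n_known),
                    rep("decoy", n_decoys), rep("structural", n_structural),
                    rep("empty", n_operons - 1 - n_special)))

  # Hfq flags decided up front (exact counts, per the stated fraction)
  hfq_true <- rep(FALSE, n_srnas); hfq_true[seq_len(round(hfq_fraction * n_srnas))] <- TRUE
  hfq_true <- sample(hfq_true)
  hfq_known <- rep(FALSE, n_known)
  if (n_known > 0) {
    hfq_known[seq_len(round(hfq_fraction * n_known))] <- TRUE
    hfq_known <- sample(hfq_known)
  }

  pos <- sample(150:400, 1)               # terminal segment before first operon
  orf_rows <- list(); op_rows <- list(); planted <- list()
  orf_counter <- 0L; srna_i <- 0L; known_i <- 0L
  margin <- 100L

  for (k in seq_len(n_operons)) {
    n_orf <- sample(1:5, 1)
    lens <- sample(200:800, n_orf, replace = TRUE)
    gaps <- if (n_orf > 1) sample(25:60, n_orf - 1, replace = TRUE) else integer()
    strand <- sample(c("+", "-"), 1)
    op_start <- pos
    ids <- character(n_orf)
    for (j in seq_len(n_orf)) {
      orf_counter <- orf_counter + 1L
      ids[j] <- sprintf("CAC%04d", orf_counter)
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        id = ids[j], start = pos, end = pos + lens[j], strand = strand,
        stringsAsFactors = FALSE)
      pos <- pos + lens[j] + if (j < n_orf) gaps[j] else 0L
    }
    op_rows[[length(op_rows) + 1L]] <- data.frame(
      id = sprintf("OP%03d", k), start = op_start, end = pos, strand = strand,
      stringsAsFactors = FALSE)
    op_rows[[length(op_rows)]]$members <- list(ids)
    if (pos > contig_length)
      .stopf("infeasible packing: operon OP%03d does not fit in the contig", k)
    if (k == n_operons) break

    role <- roles[k]
    gap_start <- pos
    if (role %in% c("srna", "known")) {
      if (role == "srna") { srna_i <- srna_i + 1L; hfq <- hfq_true[srna_i] }
      else { known_i <- known_i + 1L; hfq <- hfq_known[known_i] }
      len <- if (hfq) sample(70:300, 1) else sample(48:300, 1)
      gap <- len + 2L * margin
      planted[[length(planted) + 1L]] <- data.frame(
        feature_id = if (role == "srna") sprintf("srna%03d", srna_i)
                     else sprintf("ksrna%02d", known_i),
        class = if (role == "srna") "srna_true" else "srna_known",
        start = gap_start + margin, end = gap_start + margin + len,
        strand = "+", side = NA_character_, hfq_positive = hfq,
        has_terminator = hfq, stringsAsFactors = FALSE)
    } else if (role == "decoy") {
      gap <- 300L
      side <- sample(c("left", "right"), 1)
      dstart <- if (side == "left") gap_start else gap_start + gap - 50L
      planted[[length(planted) + 1L]] <- data.frame(
        feature_id = sprintf("decoy%02d", sum(roles[seq_len(k)] == "decoy")),
        class = "utr_decoy", start = dstart, end = dstart + 50L,
        strand = "+", side = side, hfq_positive = FALSE,
        has_terminator = FALSE, stringsAsFactors = FALSE)
    } else if (role == "structural") {
      len <- sample(c(120L, 300L, 900L, 1500L), 1)
      gap <- len + 2L * margin
      planted[[length(planted) + 1L]] <- data.frame(
        feature_id = sprintf("struct%02d", sum(roles[seq_len(k)] == "structural")),
        class = "structural", start = gap_start + margin,
        end = gap_start + margin + len, strand = "+", side = NA_character_,
        hfq_positive = FALSE, has_terminator = FALSE, stringsAsFactors = FALSE)
    } else {
      gap <- sample(150:600, 1)
    }
    pos <- pos + gap
    if (pos > contig_length)
      .stopf("infeasible packing: gap after operon OP%03d (role %s) does not fit",
             k, role)
  }
  if (pos + 150L > contig_length)
    .stopf("infeasible packing: no terminal segment left after the last operon")

  orfs <- do.call(rbind, orf_rows)
  operons <- do.call(rbind, op_rows)
  planted <- if (length(planted)) do.call(rbind, planted) else NULL

  # i.i.d. sequence at the requested GC, then splice planted sRNA sequences
  chars <- sample(c("A", "C", "G", "T"), contig_length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  if (!is.null(planted)) {
    for (i in which(planted$class %in% c("srna_true", "srna_known"))) {
      s <- planted$start[i]; e <- planted$end[i]; len <- e - s
      idx <- (s + 1L):e
      if (planted$hfq_positive[i]) {
        cass <- .hfq_cassette()
        chars[idx[(len - length(cass) + 1L):len]] <- cass
      } else {
        chars[idx] <- .suppress_u_runs(chars[idx])
      }
    }
  }
  sequence <- paste(chars, collapse = "")

  # truth table: planted features + ORFs (baselines and stress directions)
  orf_truth <- data.frame(feature_id = orfs$id, class = "orf",
                          start = orfs$start, end = orfs$end,
                          strand = orfs$strand, side = NA_character_,
                          hfq_positive = FALSE, has_terminator = FALSE,
                          stringsAsFactors = FALSE)
  truth <- rbind(orf_truth, planted)
  n <- nrow(truth)
  truth$baseline_mean <- pmax(80, round(stats::rlnorm(n, log(400), 0.4)))
  is_srna <- truth$class %in% c("srna_true", "srna_known", "utr_decoy")
  truth$baseline_mean[is_srna] <- pmax(200, round(stats::rlnorm(sum(is_srna), log(400), 0.5)))
  truth$baseline_mean[truth$class == "structural"] <- 20000

  truth$dir_butanol <- 0L; truth$dir_butyrate <- 0L
  srna_idx <- which(truth$class %in% c("srna_true", "srna_known"))
  truth$dir_butanol[srna_idx] <- sample(c(-1L, 0L, 1L), length(srna_idx),
                                        replace = TRUE, prob = c(0.35, 0.3, 0.35))
  truth$dir_butyrate[srna_idx] <- sample(c(-1L, 0L, 1L), length(srna_idx),
                                         replace = TRUE, prob = c(0.35, 0.3, 0.35))
  orf_idx <- which(truth$class == "orf")
  de_orfs <- sample(orf_idx, round(orf_de_fraction * length(orf_idx)))
  truth$dir_butanol[de_orfs] <- sample(c(-1L, 1L), length(de_orfs), replace = TRUE)
  truth$dir_butyrate[de_orfs] <- sample(c(-1L, 1L), length(de_orfs), replace = TRUE)
  attr(truth, "dose_fold") <- c(low = 1.5, medium = 2, high = 4)
  attr(truth, "time_ramp") <- c(`15` = 0.5, `30` = 1, `60` = 1, `75` = 1)

  known_tr <- truth[truth$class == "srna_known",
                    c("feature_id", "start", "end", "strand")]
  names(known_tr)[1] <- "id"
  struct_tr <- truth[truth$class == "structural",
                     c("feature_id", "start", "end", "strand")]
  names(struct_tr)[1] <- "id"
  pred_src <- truth[truth$class %in% c("srna_true", "srna_known", "utr_decoy"), ]
  preds <- data.frame(id = sprintf("PRED%04d", seq_len(nrow(pred_src))),
                      start = pred_src$start, end = pred_src$end,
                      strand = ".", stringsAsFactors = FALSE)

  ann <- genome_annotation("contig1", contig_length, orfs, operons,
                           known_srnas = known_tr,
                           predicted_srnas = preds,
                           structural_rnas = struct_tr,
                           sequence = sequence)
  list(annotation = ann, truth = truth)
}

#' Multiplicative stress effect of each truth-table feature
#'
#' Effects are multiplicative and monotone in dose: a responding feature with
#' direction d gets `fold(dose)^(d * ramp(time))`, with dose fold changes 1.5 /
#' 2 / 4 for low / medium / high and a time ramp that applies half the (log)
#' effect at 15 min and the full effect from 30 min on. The unstressed control
#' has effect 1 for every feature.
#'
#' @param truth Truth table from [simulate_genome()].
#' @param stressor `"none"`, `"butanol"` or `"butyrate"`.
#' @param dose `"none"`, `"low"`, `"medium"` or `"high"`.
#' @param time_min Sampling time in minutes.
#' @return Numeric vector of multipliers, one per truth row.
#' @export
stress_effect <- function(truth, stressor, dose, time_min) {
  if (stressor == "none" || dose == "none") return(rep(1, nrow(truth)))
  fold <- attr(truth, "dose_fold")[[dose]]
  ramp <- attr(truth, "time_ramp")[[as.character(time_min)]]
  if (is.null(fold) || is.null(ramp)) .stopf("unknown dose or time")
  dir <- truth[[paste0("dir_", stressor)]]
  fold^(dir * ramp)
}
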