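# Synthetic RNA-seq counts realized as mapped-read intervals.

#' Simulate per-library read sets under a negative-binomial model
#'
#' For feature f and library l a count is drawn from a negative binomial with
#' mean `s_l * mu_f * effect_f(condition_l, time_l) * depth/50000` and
#' dispersion `alpha` (variance `mu + alpha * mu^2`); `dispersion = 0`
#' degenerates to Poisson. Library size factors `s_l` are drawn log-normally
#' around 1. Counts are realized as uniformly placed read-start intervals of
#' `read_length` nt within the feature. UTR-bleed decoys are the exception:
#' their reads straddle the operon/IOR boundary (read overlap with the IOR is
#' uniform on `[L/2, 3L/2 - 1]` for read length `L`), emulating a transcript
#' that runs across the boundary, so IOR coverage piles up in the flank
#' window; such reads never extend more than `read_length - 1` nt beyond the
#' 50-nt decoy window. Uniform background noise reads are added genome-wide at
#' `noise_rate` of the library depth.
#'
#' @param design A [study_design()] table.
#' @param annotation The [genome_annotation()] the truth table refers to.
#' @param truth Truth table from [simulate_genome()].
#' @param dispersion NB dispersion alpha (>= 0; default 0.05).
#' @param depth Reads per library (default: the design's `depth` attribute);
#'   feature means are stated at a 50000-read reference depth and scale
#'   linearly, so `depth = 0` yields empty read sets.
#' @param noise_rate Background read rate as a fraction of depth.
#' @param seed Mandatory RNG seed.
#' @return List of class `sim_counts`: `readsets` (named list of data frames
#'   with `start`, `end`), `counts` (the realized feature x library count
#'   matrix), `size_factors`, `design`, `truth`.
#' @export
simulate_counts <- function(design, annotation, truth, dispersion = 0.05,
                            depth = NULL, noise_rate = 0.005, seed) {
  stopifnot(!missing(seed), .is_count(seed), dispersion >= 0)
  if (is.null(depth)) depth <- attr(design, "depth")
  stopifnot(depth >= 0)
  set.seed(seed)
  rl <- attr(design, "read_length")
  if (is.null(rl)) rl <- 50L
  clen <- annotation$contig_length
  nlib <- nrow(design)
  scale <- depth / .REF_DEPTH
  sf <- exp(stats::rnorm(nlib, 0, 0.1))

  nfeat <- nrow(truth)
  counts <- matrix(0L, nfeat, nlib,
                   dimnames = list(truth$feature_id, design$library_id))
  readsets <- vector("list", nlib)
  names(readsets) <- design$library_id
  half <- rl %/% 2L

  for (l in seq_len(nlib)) {
    eff <- stress_effect(truth, design$stressor[l], design$dose[l],
                         design$time_min[l])
    mu <- sf[l] * truth$baseline_mean * eff * scale
    k <- if (dispersion == 0) stats::rpois(nfeat, mu)
         else stats::rnbinom(nfeat, mu = mu, size = 1 / dispersion)
    counts[, l] <- k
    # realize read starts
    idx <- rep.int(seq_len(nfeat), k)
    if (length(idx)) {
      fs <- truth$start[idx]; fe <- truth$end[idx]
      lo <- fs; hi <- pmax(fs, fe - rl)
      is_decoy <- truth$class[idx] == "utr_decoy"
      if (any(is_decoy)) {
        edge <- ifelse(truth$side[idx] == "left", truth$start[idx], truth$end[idx])
        lo[is_decoy] <- ifelse(truth$side[idx[is_decoy]] == "left",
                               edge[is_decoy] - half,
                               edge[is_decoy] - rl - half + 1L)
        hi[is_decoy] <- ifelse(truth$side[idx[is_decoy]] == "left",
                               edge[is_decoy] + half - 1L,
                               edge[is_decoy] - half)
      }
      starts <- lo + floor(stats::runif(length(idx)) * (hi - lo + 1L))
    } else starts <- integer()
    n_noise <- stats::rpois(1, noise_rate * depth)
    if (n_noise > 0)
      starts <- c(starts, floor(stats::runif(n_noise) * (clen - rl + 1L)))
    starts <- pmax(0L, pmin(as.integer(starts), clen - rl))
    readsets[[l]] <- data.frame(start = starts, end = starts + rl)
  }
  structure(list(readsets = readsets, counts = counts, size_factors = sf,
                 design = design, truth = truth),
            class = "sim_counts")
}

#' @export
print.sim_counts <- function(x, ...) {
  cat(sprintf("<sim_counts> %d libraries, %d features, %s reads total\n",
              length(x$readsets), nrow(x$counts),
              format(sum(vapply(x$readsets, nrow, 0L)), big.mark = ",")))
  invisible(x)
}
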