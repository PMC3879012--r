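# Differential expression of sRNAs under graded stress versus the unstressed
# control: median-of-ratios library normalization, a two-group negative
# binomial exact test (normal approximation for large totals), a
# method-of-moments dispersion estimator, and the pairwise per-time-point
# contrast driver.

#' Median-of-ratios library size factors
#'
#' For each library, the median over features of the ratio of its count to the
#' feature's geometric mean across libraries, computed over features with a
#' positive geometric mean (i.e. nonzero in every library). When no such
#' feature exists, falls back per library to the median over its nonzero
#' features, with a message.
#'
#' @param counts Count matrix (features x libraries) or a `count_matrix`.
#' @return Positive numeric vector of per-library factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  lg <- rowMeans(log(counts))
  ok <- is.finite(lg)
  if (any(ok)) {
    sf <- apply(counts[ok, , drop = FALSE], 2, function(k)
      stats::median(exp(log(k) - lg[ok])))
  } else {
    .msgf("size_factors: no feature is nonzero in all libraries; per-library fallback")
    lg2 <- rowMeans(ifelse(counts > 0, log(counts), NA), na.rm = TRUE)
    sf <- apply(counts, 2, function(k) {
      nz <- k > 0 & is.finite(lg2)
      if (!any(nz)) return(1)
      stats::median(exp(log(k[nz]) - lg2[nz]))
    })
  }
  if (any(!is.finite(sf) | sf <= 0))
    .stopf("size factor estimation failed (non-positive factor)")
  sf
}

# Moment-matched NB for a group's count sum: mean and size parameter.
.group_nb <- function(q, sf, dispersion) {
  mu <- q * sum(sf)
  v <- sum(q * sf + dispersion * (q * sf)^2)
  size <- if (v > mu) mu^2 / (v - mu) else Inf
  list(mu = mu, size = size)
}

.dnb <- function(x, mu, size) {
  if (is.infinite(size)) stats::dpois(x, mu) else stats::dnbinom(x, mu = mu, size = size)
}

#' Two-group negative binomial exact test
#'
#' Tests equality of normalized means between two groups of count libraries
#' under a negative binomial model with known dispersion (variance
#' `mu + alpha mu^2`). The group sums are modelled as moment-matched negative
#' binomials at the pooled per-unit mean; the two-sided p-value sums the
#' conditional probabilities of all outcomes with `a + b` equal to the
#' observed total that are no more likely than the observed split (exact
#' conditional enumeration when the total is at most `exact_max_total`, a
#' normal approximation on the normalized difference otherwise). Symmetric in
#' group order; an all-zero feature gives p = 1.
#'
#' @param k_a,k_b Integer count vectors (one per replicate library).
#' @param sf_a,sf_b Size factors of the corresponding libraries.
#' @param dispersion NB dispersion alpha (>= 0).
#' @param exact_max_total Largest total count enumerated exactly.
#' @return Two-sided p-value in \[0, 1\].
#' @export
nb_test <- function(k_a, k_b, sf_a, sf_b, dispersion, exact_max_total = 1e4) {
  stopifnot(length(k_a) == length(sf_a), length(k_b) == length(sf_b),
            length(k_a) >= 1, length(k_b) >= 1, dispersion >= 0)
  ka <- sum(k_a); kb <- sum(k_b); total <- ka + kb
  if (total == 0L) return(1)
  q <- total / (sum(sf_a) + sum(sf_b))
  A <- .group_nb(q, sf_a, dispersion)
  B <- .group_nb(q, sf_b, dispersion)
  if (total <= exact_max_total) {
    a <- 0:total
    pa <- .dnb(a, A$mu, A$size) * .dnb(total - a, B$mu, B$size)
    denom <- sum(pa)
    if (denom == 0) return(1)
    obs <- pa[ka + 1L]
    min(1, sum(pa[pa <= obs * (1 + 1e-8)]) / denom)
  } else {
    ta <- ka / sum(sf_a); tb <- kb / sum(sf_b)
    va <- sum(q * sf_a + dispersion * (q * sf_a)^2) / sum(sf_a)^2
    vb <- sum(q * sf_b + dispersion * (q * sf_b)^2) / sum(sf_b)^2
    z <- (ta - tb) / sqrt(va + vb)
    2 * stats::pnorm(-abs(z))
  }
}

#' Method-of-moments dispersion estimation
#'
#' Pools, across replicate groups (condition x time cells with >= 2
#' libraries), the within-group sample mean and variance of normalized counts
#' for each feature, and solves `variance = mean + alpha mean^2` for alpha.
#' Estimates are floored at `min_disp`. Designs with no replicated group fall
#' back to a global default with a message.
#'
#' @param counts Count matrix (features x libraries) or `count_matrix`.
#' @param design A [study_design()] table matching the columns.
#' @param sf Size factors (default: estimated from the matrix).
#' @param min_disp Dispersion floor (default 0.01).
#' @param fallback Dispersion used when no group has replicates.
#' @return Named numeric vector of per-feature dispersions.
#' @export
estimate_dispersion <- function(counts, design, sf = NULL, min_disp = 0.01,
                                fallback = 0.05) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (is.null(sf)) sf <- size_factors(counts)
  z <- sweep(counts, 2, sf, "/")
  grp <- interaction(design$condition_id, design$time_min, drop = TRUE)
  keep <- names(table(grp))[table(grp) >= 2]
  if (length(keep) == 0L) {
    .msgf("estimate_dispersion: no replicated group; using fallback %.3g", fallback)
    return(stats::setNames(rep(fallback, nrow(counts)), rownames(counts)))
  }
  num <- 0; mu_acc <- 0; df_acc <- 0; n_acc <- 0
  var_w <- rep(0, nrow(counts)); mu_w <- rep(0, nrow(counts))
  for (g in keep) {
    cols <- which(grp == g)
    m <- rowMeans(z[, cols, drop = FALSE])
    v <- apply(z[, cols, drop = FALSE], 1, stats::var)
    df <- length(cols) - 1
    var_w <- var_w + v * df
    mu_w <- mu_w + m * length(cols)
    df_acc <- df_acc + df
    n_acc <- n_acc + length(cols)
  }
  s2 <- var_w / df_acc
  mu <- mu_w / n_acc
  alpha <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  stats::setNames(pmax(min_disp, alpha), rownames(counts))
}

#' Pairwise differential expression against the unstressed control
#'
#' For every stress level (stressor x dose) and time point, tests each feature
#' between the stress libraries and the control libraries at the same time
#' point with [nb_test()]. Raw p-values are thresholded at `alpha` (no
#' multiple-testing correction by default, matching the p <= 0.05 convention;
#' set `fdr = TRUE` for Benjamini-Hochberg adjusted calls).
#'
#' @param cm A `count_matrix` or plain count matrix.
#' @param design A [study_design()] table.
#' @param features Feature ids to test (default: all rows).
#' @param alpha Significance threshold on the p-value.
#' @param dispersion Per-feature dispersions (default: estimated with
#'   [estimate_dispersion()]).
#' @param sf Size factors (default: estimated from the full matrix).
#' @param pseudocount Pseudocount for the reported log2 ratio.
#' @param fdr Apply Benjamini-Hochberg and call significance on the adjusted
#'   p-value.
#' @return Data frame of class `de_results`: one row per (feature, stressor,
#'   dose, time) with normalized group means, `log2_ratio`, `p_value` and
#'   `significant`. Contrasts lacking a control time point are skipped with a
#'   message.
#' @export
call_de <- function(cm, design, features = NULL, alpha = 0.05,
                    dispersion = NULL, sf = NULL, pseudocount = 1,
                    fdr = FALSE) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts, design, sf)
  if (is.null(features)) features <- rownames(counts)
  fidx <- match(features, rownames(counts))
  if (anyNA(fidx)) .stopf("unknown feature ids in `features`")
  disp <- if (length(dispersion) == 1L)
    stats::setNames(rep(dispersion, length(fidx)), features)
  else dispersion[features]

  lvl <- unique(design[design$stressor != "none", c("stressor", "dose")])
  times <- sort(unique(design$time_min))
  rows <- list()
  for (i in seq_len(nrow(lvl))) for (tm in times) {
    ctrl <- which(design$stressor == "none" & design$time_min == tm)
    strs <- which(design$stressor == lvl$stressor[i] &
                    design$dose == lvl$dose[i] & design$time_min == tm)
    if (length(ctrl) == 0L) {
      .msgf("call_de: no control libraries at t=%d; contrast skipped", tm)
      next
    }
    if (length(strs) == 0L) next
    mc <- rowMeans(sweep(counts[fidx, ctrl, drop = FALSE], 2, sf[ctrl], "/"))
    ms <- rowMeans(sweep(counts[fidx, strs, drop = FALSE], 2, sf[strs], "/"))
    p <- vapply(seq_along(fidx), function(j)
      nb_test(counts[fidx[j], strs], counts[fidx[j], ctrl],
              sf[strs], sf[ctrl], disp[j]), 0)
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = features, stressor = lvl$stressor[i], dose = lvl$dose[i],
      time_min = tm, mean_control = mc, mean_stress = ms,
      log2_ratio = log2((ms + pseudocount) / (mc + pseudocount)),
      p_value = p, stringsAsFactors = FALSE, row.names = NULL)
  }
  de <- do.call(rbind, rows)
  if (fdr) {
    de$p_adj <- stats::p.adjust(de$p_value, "BH")
    de$significant <- de$p_adj <= alpha
  } else {
    de$significant <- de$p_value <= alpha
  }
  class(de) <- c("de_results", class(de))
  attr(de, "alpha") <- alpha
  de
}

#' Up/down summary per stress level
#'
#' The per-stress-level tally of differentially expressed features: a feature
#' counts as up (down) for a stress level if it is significant with positive
#' (negative) log2 ratio at one or more time points.
#'
#' @param de Output of [call_de()].
#' @return Data frame with `stressor`, `dose`, `up`, `down`.
#' @export
de_summary <- function(de) {
  lv <- unique(de[, c("stressor", "dose")])
  out <- lv
  out$up <- 0L; out$down <- 0L
  for (i in seq_len(nrow(lv))) {
    d <- de[de$stressor == lv$stressor[i] & de$dose == lv$dose[i] & de$significant, ]
    out$up[i] <- length(unique(d$feature_id[d$log2_ratio > 0]))
    out$down[i] <- length(unique(d$feature_id[d$log2_ratio < 0]))
  }
  rownames(out) <- NULL
  out
}
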