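make_cm <- function(ior_counts, orf_counts = NULL) {
  # ior_counts: named list of per-library count vectors
  rows <- c(lapply(ior_counts, as.integer), lapply(orf_counts, as.integer))
  counts <- do.call(rbind, rows)
  rownames(counts) <- c(names(ior_counts), names(orf_counts))
  colnames(counts) <- sprintf("L%d", seq_len(ncol(counts)))
  structure(list(counts = counts,
                 class = c(rep("ior", length(ior_counts)),
                           rep("orf", length(orf_counts))),
                 libraries = colnames(counts)),
            class = "count_matrix")
}

test_that("the minimal read count of 50 is an inclusive boundary", {
  cm <- make_cm(list(I1 = c(50, 0, 0), I2 = c(49, 49, 49), I3 = c(0, 51, 3)))
  pass <- call_expressed_iors(cm, min_count = 50)
  expect_true("I1" %in% pass)    # exactly 50 in one library passes
  expect_false("I2" %in% pass)   # 49 everywhere fails
  expect_true("I3" %in% pass)
  expect_error(call_expressed_iors(cm, min_count = -1), "nonnegative")
})

test_that("the library quorum is configurable", {
  cm <- make_cm(list(I1 = c(60, 10, 10), I2 = c(60, 60, 10), I3 = c(60, 60, 60)))
  expect_setequal(call_expressed_iors(cm, 50), c("I1", "I2", "I3"))
  expect_setequal(call_expressed_iors(cm, 50, min_library_fraction = 0.5),
                  c("I2", "I3"))
  expect_setequal(call_expressed_iors(cm, 50, min_library_fraction = 1),
                  "I3")
})

test_that("the expressed set matches a direct matrix scan", {
  set.seed(301)
  counts <- matrix(rnbinom(600, mu = 40, size = 2), 60, 10,
                   dimnames = list(sprintf("I%02d", 1:60), sprintf("L%d", 1:10)))
  cm <- structure(list(counts = counts, class = rep("ior", 60),
                       libraries = colnames(counts)), class = "count_matrix")
  pass <- call_expressed_iors(cm, 50)
  brute <- rownames(counts)[apply(counts, 1, function(x) any(x >= 50))]
  expect_setequal(pass, brute)
  # monotone in the threshold
  expect_true(all(call_expressed_iors(cm, 80) %in% pass))
})

test_that("prediction intersection keeps any >= 1 nt overlap, minus exclusions", {
  iors <- data.frame(id = c("INTEROP0001", "INTEROP0002"),
                     start = c(300, 1000), end = c(600, 1300))
  preds <- data.frame(id = c("P1", "P2", "P3"),
                      start = c(400, 599, 700), end = c(480, 650, 800))
  hits <- intersect_predictions(iors, preds)
  expect_setequal(hits$INTEROP0001, c("P1", "P2"))  # P2 overlaps by 1 nt
  expect_equal(hits$INTEROP0002, character())
  hits2 <- intersect_predictions(iors, preds, exclude_ids = "P1")
  expect_equal(hits2$INTEROP0001, "P2")
})

test_that("the UTR filter needs both flank dominance and an expressed neighbor", {
  # 90% of coverage in the left 50-nt window of a 500-nt IOR
  cov <- c(rep(90L, 50), rep(1L, 450))
  res <- utr_fp_filter(cov, 0, 500, list(left = 500, right = 5))
  expect_true(res$fp)
  expect_equal(res$dominant_side, "left")
  # same shape, neighbor not expressed -> retained
  res2 <- utr_fp_filter(cov, 0, 500, list(left = 10, right = 5))
  expect_false(res2$fp)
  # uniform coverage -> flank share 0.2 < 0.8 -> retained
  res3 <- utr_fp_filter(rep(3L, 500), 0, 500, list(left = 500, right = 500))
  expect_false(res3$fp)
  expect_equal(res3$flank_share, 0.2)
  # IOR no longer than the window cannot be assessed
  res4 <- utr_fp_filter(rep(5L, 40), 100, 140, list(left = 500, right = 500),
                        w = 50)
  expect_false(res4$fp)
  expect_true(res4$manual_review)
})

test_that("raising dominance never enlarges the fp set", {
  set.seed(302)
  for (rep in 1:20) {
    cov <- as.integer(rpois(300, lambda = sample(1:20, 1)) +
                        c(rep(sample(0:80, 1), 50), rep(0, 250)))
    low <- utr_fp_filter(cov, 0, 300, list(left = 500, right = 500),
                         dominance = 0.5)
    high <- utr_fp_filter(cov, 0, 300, list(left = 500, right = 500),
                          dominance = 0.9)
    expect_true(low$fp || !high$fp)
  }
})

test_that("survivor naming follows the downstream locus number", {
  orfs <- data.frame(id = c("CAC0380", "CAC0381", "CAC0382"),
                     start = c(1000, 2000, 3000), end = c(1500, 2500, 3500))
  surv <- data.frame(id = "INTEROP0218", start = 1600, end = 1900)
  expect_equal(name_candidates(surv, orfs), "sCAC381")
  # two survivors before the same ORF get deterministic suffixes
  surv2 <- data.frame(id = c("INTEROPA", "INTEROPB"),
                      start = c(1750, 1600), end = c(1900, 1700))
  expect_equal(name_candidates(surv2, orfs), c("sCAC381b", "sCAC381a"))
  # terminal IOR falls back to the left neighbor
  surv3 <- data.frame(id = "INTEROPC", start = 3600, end = 3900)
  expect_equal(name_candidates(surv3, orfs), "sCAC382")
  expect_equal(name_candidates(surv[0, ], orfs), character())
})

test_that("planted decoys with expressed neighbors are eliminated, sRNAs kept", {
  gen <- simulate_genome(n_operons = 24, n_srnas = 6, n_decoys = 4, n_known = 2,
                         n_structural = 1, contig_length = 70000, seed = 31)
  d <- study_design(replicates = 1, times = c(30, 60), depth = 50000)
  sim <- simulate_counts(d, gen$annotation, gen$truth, seed = 32)
  iors <- derive_iors(gen$annotation)
  cm <- build_count_matrix(sim$readsets, gen$annotation, iors)
  preds <- gen$annotation$predicted_srnas
  kn <- gen$annotation$known_srnas
  excl <- preds$id[vapply(seq_len(nrow(preds)), function(i)
    any(kn$start < preds$end[i] & kn$end > preds$start[i]), TRUE)]
  led <- discover_candidates(cm, iors, sim$readsets, preds, exclude_ids = excl,
                             orfs = gen$annotation$orfs)
  tt <- gen$truth
  dec <- tt[tt$class == "utr_decoy", ]
  dec_ior <- vapply(seq_len(nrow(dec)), function(i)
    led$id[led$start <= dec$start[i] & led$end >= dec$end[i]][1], "")
  nb_expr <- vapply(dec_ior, function(id) {
    r <- led[led$id == id, ]
    side <- if (r$utr_left_fraction >= r$utr_right_fraction) "left" else "right"
    cnt <- if (side == "left") r$neighbor_left_count else r$neighbor_right_count
    isTRUE(cnt >= 50)
  }, TRUE)
  expect_true(all(led$status[match(dec_ior[nb_expr], led$id)] == "fp_utr"))

  srna <- tt[tt$class == "srna_true", ]
  srna_ior <- vapply(seq_len(nrow(srna)), function(i)
    led$id[led$start <= srna$start[i] & led$end >= srna$end[i]][1], "")
  expect_true(all(led$status[match(srna_ior, led$id)] == "novel_srna"))
})
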