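# Study-design and generator behavior. The design table and generator
# defaults define the study conditions the acceptance properties are
# evaluated under.

test_that("the default study design has 7 conditions x 4 times x r replicates", {
  d <- study_design(replicates = 3)
  expect_equal(nrow(d), 7 * 4 * 3)
  expect_equal(sum(d$stressor == "none"), 4 * 3)
  expect_setequal(unique(d$dose_mM[d$stressor == "butanol"]), c(30, 60, 90))
  expect_setequal(unique(d$dose_mM[d$stressor == "butyrate"]), c(30, 40, 50))
  cells <- table(d$condition_id, d$time_min)
  expect_true(all(cells == 3))
  expect_false(anyDuplicated(d$library_id) > 0)
})

test_that("simulated genomes hit the requested GC content", {
  gen <- simulate_genome(n_operons = 40, n_srnas = 15, n_decoys = 8,
                         n_known = 4, n_structural = 3,
                         contig_length = 100000, seed = 3)
  chars <- strsplit(gen$annotation$sequence, "")[[1]]
  gc <- mean(chars %in% c("G", "C"))
  expect_lt(abs(gc - 0.29), 0.02)
})

test_that("planted feature classes and Hfq cassette counts follow the request", {
  gen <- simulate_genome(seed = 5)
  tt <- gen$truth
  expect_equal(sum(tt$class == "srna_true"), 20)
  expect_equal(sum(tt$class == "utr_decoy"), 10)
  expect_equal(sum(tt$hfq_positive[tt$class == "srna_true"]), 10)
  expect_equal(tt$hfq_positive, tt$has_terminator)
  # cassette really spliced in: positives end in a poly-U run
  pos <- tt[tt$class == "srna_true" & tt$hfq_positive, ]
  tails <- substring(gen$annotation$sequence, pos$end - 7, pos$end)
  expect_true(all(tails == "TTTTTTTT"))

  none <- simulate_genome(n_srnas = 0, n_operons = 30, n_decoys = 5,
                          n_known = 3, n_structural = 2, seed = 5)
  expect_equal(sum(none$truth$class == "srna_true"), 0)
})

test_that("planted features land inside IORs and decoys abut an ORF boundary", {
  gen <- simulate_genome(seed = 8)
  iors <- derive_iors(gen$annotation)
  tt <- gen$truth[gen$truth$class %in% c("srna_true", "utr_decoy"), ]
  inside <- vapply(seq_len(nrow(tt)), function(i)
    any(iors$start <= tt$start[i] & iors$end >= tt$end[i]), TRUE)
  expect_true(all(inside))
  dec <- gen$truth[gen$truth$class == "utr_decoy", ]
  at_edge <- vapply(seq_len(nrow(dec)), function(i)
    any(iors$start == dec$start[i] | iors$end == dec$end[i]), TRUE)
  expect_true(all(at_edge))
})

test_that("generation is bit-reproducible under a fixed seed", {
  g1 <- simulate_genome(n_operons = 20, n_srnas = 6, n_decoys = 3, n_known = 2,
                        n_structural = 1, contig_length = 60000, seed = 42)
  g2 <- simulate_genome(n_operons = 20, n_srnas = 6, n_decoys = 3, n_known = 2,
                        n_structural = 1, contig_length = 60000, seed = 42)
  expect_identical(g1$annotation$sequence, g2$annotation$sequence)
  expect_identical(g1$truth, g2$truth)
  d <- study_design(replicates = 1, times = 30, depth = 5000)
  s1 <- simulate_counts(d, g1$annotation, g1$truth, seed = 7)
  s2 <- simulate_counts(d, g2$annotation, g2$truth, seed = 7)
  expect_identical(s1$readsets, s2$readsets)
  expect_identical(s1$counts, s2$counts)
})

test_that("infeasible packing fails with the offending feature named", {
  expect_error(simulate_genome(n_operons = 48, contig_length = 30000, seed = 1),
               "infeasible packing")
})

test_that("dispersion 0 degenerates to Poisson counts", {
  gen <- simulate_genome(n_operons = 10, n_srnas = 2, n_decoys = 1, n_known = 1,
                         n_structural = 1, contig_length = 30000, seed = 2)
  tt <- gen$truth
  tt$baseline_mean[] <- 0
  tt$baseline_mean[tt$class == "orf"][1] <- 500
  d <- data.frame(library_id = sprintf("ctl_r%03d", 1:200),
                  condition_id = "none", stressor = "none", dose = "none",
                  dose_mM = 0, time_min = 30, replicate = 1:200)
  attr(d, "read_length") <- 50L
  sim <- simulate_counts(d, gen$annotation, tt, dispersion = 0, depth = 50000,
                         noise_rate = 0, seed = 9)
  z <- sim$counts[tt$class == "orf", ][1, ] / sim$size_factors
  expect_gt(var(z) / mean(z), 0.8)
  expect_lt(var(z) / mean(z), 1.2)
})

test_that("empirical means converge to size factor x baseline x effect", {
  gen <- simulate_genome(n_operons = 10, n_srnas = 2, n_decoys = 1, n_known = 1,
                         n_structural = 1, contig_length = 30000, seed = 2)
  tt <- gen$truth
  d <- data.frame(library_id = sprintf("bx_r%03d", 1:300),
                  condition_id = "butanol_high", stressor = "butanol",
                  dose = "high", dose_mM = 90, time_min = 60, replicate = 1:300)
  attr(d, "read_length") <- 50L
  sim <- simulate_counts(d, gen$annotation, tt, dispersion = 0.05,
                         depth = 50000, noise_rate = 0, seed = 10)
  z <- sweep(sim$counts, 2, sim$size_factors, "/")
  expected <- tt$baseline_mean * stress_effect(tt, "butanol", "high", 60)
  strong <- expected >= 200
  rel <- abs(rowMeans(z)[strong] - expected[strong]) / expected[strong]
  expect_true(all(rel < 0.05))
})

test_that("decoy reads stay within a read length of their flank window", {
  gen <- simulate_genome(n_operons = 16, n_srnas = 2, n_decoys = 6, n_known = 1,
                         n_structural = 1, contig_length = 50000, seed = 4)
  tt <- gen$truth
  tt$baseline_mean[tt$class != "utr_decoy"] <- 0
  d <- study_design(replicates = 1, times = 30, depth = 50000)
  sim <- simulate_counts(d, gen$annotation, tt, depth = 50000,
                         noise_rate = 0, seed = 11)
  dec <- tt[tt$class == "utr_decoy", ]
  rl <- 50L
  for (r in sim$readsets) {
    ok <- vapply(seq_len(nrow(r)), function(i)
      any(r$start[i] >= dec$start - (rl - 1) & r$end[i] <= dec$end + (rl - 1)),
      TRUE)
    expect_true(all(ok))
  }
})

test_that("depth 0 yields empty read sets", {
  gen <- simulate_genome(n_operons = 10, n_srnas = 2, n_decoys = 1, n_known = 1,
                         n_structural = 1, contig_length = 30000, seed = 2)
  d <- study_design(replicates = 1, times = 30)
  sim <- simulate_counts(d, gen$annotation, gen$truth, depth = 0, seed = 3)
  expect_true(all(vapply(sim$readsets, nrow, 0L) == 0))
})

test_that("stress effects are monotone in dose and 1 under no stress", {
  gen <- simulate_genome(n_operons = 10, n_srnas = 2, n_decoys = 1, n_known = 1,
                         n_structural = 1, contig_length = 30000, seed = 2)
  tt <- gen$truth
  expect_true(all(stress_effect(tt, "none", "none", 30) == 1))
  lo <- stress_effect(tt, "butanol", "low", 60)
  hi <- stress_effect(tt, "butanol", "high", 60)
  up <- tt$dir_butanol > 0; dn <- tt$dir_butanol < 0
  expect_true(all(hi[up] > lo[up]))
  expect_true(all(hi[dn] < lo[dn]))
  expect_equal(lo[up], rep(1.5, sum(up)))
  expect_equal(hi[up], rep(4, sum(up)))
})
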