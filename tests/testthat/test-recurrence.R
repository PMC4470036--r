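test_that("probe frequencies count direction-matched calls", {
  m <- cbind(a = c(0L, 2L, 0L), b = c(0L, 1L, -1L),
             c = c(0L, 0L, -1L), d = c(0L, 0L, 0L))
  expect_equal(probe_frequency(m, "gain"), c(0, 0.5, 0))
  expect_equal(probe_frequency(m, "loss"), c(0, 0, 0.5))
})

test_that("recurrent amplification regions honor the sample threshold", {
  ann <- small_annotation(1000)
  m <- matrix(0L, nrow(ann), 10,
              dimnames = list(ann$probe_id, paste0("s", 1:10)))
  expect_equal(nrow(recurrent_amplifications(m, ann)), 0)
  amp_idx <- which(ann$chromosome == "1")[100:140]
  m[amp_idx, 1:3] <- 2L
  reg <- recurrent_amplifications(m, ann, min_samples = 3)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$n_probes, 41L)
  expect_equal(reg$samples, "s1,s2,s3")
  m2 <- m; m2[amp_idx, 3] <- 0L
  expect_equal(nrow(recurrent_amplifications(m2, ann, min_samples = 3)), 0)
})

test_that("arm alteration counts keep whole-chromosome events exclusive", {
  ann <- small_annotation(2000)
  n1 <- sum(ann$chromosome == "1")
  n2p <- sum(ann$chromosome == "2" & ann$arm == "p")
  segs <- do.call(rbind, c(
    lapply(1:5, function(i)
      make_segment("1", 1L, n1 + 1L, ann, -0.6, -1L, sample = paste0("s", i),
                   scope = "whole_chromosome")),
    list(make_segment("2", 1L, n2p + 1L, ann, 0.5, 1L, sample = "s1",
                      scope = "whole_arm"))))
  tab <- arm_alteration_table(segs, ann)
  expect_equal(tab$whole_loss[tab$chromosome == "1"], 5L)
  expect_equal(tab$p_loss[tab$chromosome == "1"], 0L)
  expect_equal(tab$q_loss[tab$chromosome == "1"], 0L)
  expect_equal(tab$p_gain[tab$chromosome == "2"], 1L)
  expect_equal(tab$whole_gain[tab$chromosome == "2"], 0L)
})

test_that("simulated arm-level cohort reproduces the planted design", {
  ann <- small_annotation(2000)
  cfg <- run_config(seed = 3, seg_n_perm = 200L)
  segs <- list()
  for (i in 1:3) {
    # whole chr1 gain in every sample; 2p loss in sample 1 only
    events <- if (i == 1)
      event_plan(paste0("s", i), c("1", "2"), c(0, 0),
                 c(150e6, 60e6), c(3L, 1L), c(1L, 0L))
    else
      event_plan(paste0("s", i), "1", 0, 150e6, 3L, 1L)
    sig <- simulate_sample(events, ann, noise_model(), seed = 40 + i)$signals
    segs[[i]] <- segment_sample(sig, ann, cfg, paste0("s", i))
  }
  tab <- arm_alteration_table(do.call(rbind, segs), ann)
  expect_equal(tab$whole_gain[tab$chromosome == "1"], 3L)
  expect_equal(tab$p_loss[tab$chromosome == "2"], 1L)
})

test_that("MCR output is consistent and order-invariant", {
  ann <- small_annotation(1000)
  cfg <- run_config(seed = 5, seg_n_perm = 200L)
  shared <- data.frame(chromosome = "1", start = 40e6, end = 60e6,
                       total = 3L, minor = 1L)
  co <- simulate_cohort(6, ann, shared, penetrance = 1,
                        background_rate = 1, seed = 5)
  segs <- do.call(rbind, lapply(names(co$signals), function(s)
    segment_sample(co$signals[[s]], ann, cfg, s)))
  mcr <- mcr_permutation_test(segs, ann, "gain", n_perm = 300, seed = 7)
  expect_gt(nrow(mcr), 0)
  # consistency: region frequency >= minimum member-probe frequency
  calls <- cohort_call_matrix(segs, ann)
  freq <- probe_frequency(calls, "gain")
  for (i in seq_len(nrow(mcr))) {
    probes <- ann$chromosome == mcr$chromosome[i] &
      ann$position - 1 >= mcr$start_bp[i] & ann$position - 1 < mcr$end_bp[i]
    expect_gte(mcr$frequency[i], min(freq[probes]))
    expect_lt(mcr$p_adjusted[i], 0.05)
  }
  # invariance to sample order
  segs_rev <- segs[order(segs$sample, decreasing = TRUE), ]
  mcr_rev <- mcr_permutation_test(segs_rev, ann, "gain", n_perm = 300,
                                  seed = 7)
  expect_equal(mcr_rev[order(mcr_rev$start_bp), c("start_bp", "end_bp")],
               mcr[order(mcr$start_bp), c("start_bp", "end_bp")])
})

test_that("MCR p-values stabilize across seeds at high permutation counts", {
  ann <- small_annotation(500)
  cfg <- run_config(seed = 11, seg_n_perm = 200L)
  shared <- data.frame(chromosome = "1", start = 40e6, end = 70e6,
                       total = 3L, minor = 1L)
  co <- simulate_cohort(4, ann, shared, penetrance = 0.5,
                        background_rate = 1, seed = 11)
  segs <- do.call(rbind, lapply(names(co$signals), function(s)
    segment_sample(co$signals[[s]], ann, cfg, s)))
  m1 <- mcr_permutation_test(segs, ann, "gain", n_perm = 4000, seed = 1)
  m2 <- mcr_permutation_test(segs, ann, "gain", n_perm = 4000, seed = 2)
  if (nrow(m1) && nrow(m2))
    expect_lt(abs(min(m1$p_adjusted) - min(m2$p_adjusted)), 0.01)
  expect_equal(nrow(m1), nrow(m2))
})

test_that("degenerate MCR inputs are handled", {
  ann <- small_annotation(500)
  cfg <- run_config(seed = 2, seg_n_perm = 200L)
  sig <- diploid_sample(ann, seed = 2)
  segs <- segment_sample(sig, ann, cfg, "only")
  # no altered segments -> empty result
  expect_equal(nrow(mcr_permutation_test(segs, ann, "gain", n_perm = 200,
                                         seed = 3)), 0)
  # single-sample cohort with one alteration: must not crash
  plan <- event_plan("only", "1", 30e6, 60e6, 3L, 1L)
  sig2 <- simulate_sample(plan, ann, noise_model(), seed = 3)$signals
  segs2 <- segment_sample(sig2, ann, cfg, "only")
  expect_warning(
    m <- mcr_permutation_test(segs2, ann, "gain", n_perm = 50, seed = 3),
    "resolution")
  expect_true(is.data.frame(m))
})
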