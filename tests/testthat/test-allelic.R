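test_that("probe allelic states follow the LOH and HD rules", {
  sig <- data.frame(genotype = c("AA", "NC", "AB", "BB", "NC", "AA"),
                    baf = c(0.01, 0.37, 0.50, 0.99, 0.37, 0.01),
                    logR = c(-0.4, -2.5, 0.0, -0.4, -0.3, -0.4))
  seg_mean <- c(-0.4, -2.5, 0.0, -0.4, -0.3, -0.05)
  st <- call_allelic_state(sig, seg_mean)
  # HD needs the deep decline; LOH needs at least the shallow one
  expect_equal(st, c("LOH", "HD", "normal", "LOH", "normal", "normal"))
})

test_that("planted copy-neutral LOH is detected with tight boundaries", {
  ann <- small_annotation()
  plan <- event_plan("s", "1", 40e6, 50e6, 2L, 0L)
  hits <- 0
  for (seed in 1:10) {
    sig <- simulate_sample(plan, ann, noise_model(), seed = seed)$signals
    ev <- detect_upd(sig, sample = "s")
    m <- match_events(ev, data.frame(sample = "s", chromosome = "1",
                                     start = 40e6, end = 50e6),
                      min_ro = 0.9)
    hits <- hits + (m$n_matched_truth == 1 && nrow(ev) == 1)
  }
  expect_gte(hits, 9)
})

test_that("diploid and hemizygous-deleted chromosomes yield no UPD", {
  ann <- small_annotation()
  sig <- diploid_sample(ann, seed = 21)
  expect_equal(nrow(detect_upd(sig, sample = "s")), 0)
  # hemizygous deletion: LOH-like genotypes but logR below the band
  del <- event_plan("s", "1", 30e6, 80e6, 1L, 0L)
  sig_d <- simulate_sample(del, ann, noise_model(), seed = 22)$signals
  expect_equal(nrow(detect_upd(sig_d, sample = "s")), 0)
})

test_that("no emitted event sits outside the logR tolerance band", {
  ann <- small_annotation()
  plan <- event_plan("s", c("1", "2"), c(20e6, 10e6), c(120e6, 60e6),
                     c(2L, 4L), c(0L, 0L))
  for (seed in 1:5) {
    sig <- simulate_sample(plan, ann, noise_model(), seed = seed)$signals
    ev <- detect_upd(sig, sample = "s")
    expect_true(all(ev$mean_logR >= -0.15))
  }
})

test_that("UPD categories follow the six-way taxonomy", {
  ann <- small_annotation()
  pos1 <- ann$position[ann$chromosome == "1"]
  n1 <- length(pos1)
  neutral <- make_segment("1", 1L, n1 + 1L, ann, 0, 0L,
                          scope = "whole_chromosome")
  ev <- function(start, end) data.frame(
    sample = "s", chromosome = "1", start_bp = start, end_bp = end,
    n_probes = 100L, mean_logR = 0)

  # 1: whole chromosome, all neutral
  whole <- ev(0, max(pos1))
  expect_equal(classify_upd(whole, ann, neutral)$category, 1L)
  # 2: one arm only (p arm is 40% of the chromosome)
  arm <- ev(0, 60e6)
  expect_equal(classify_upd(arm, ann, neutral)$category, 2L)
  # 3: focal, copy-neutral context
  focal <- ev(50e6, 60e6)
  expect_equal(classify_upd(focal, ann, neutral)$category, 3L)
  # 5: focal overlapping an amplification segment
  amp_seg <- rbind(neutral,
                   make_segment("1", 700L, 800L, ann, log2(6 / 2), 2L))
  focal_amp <- ev(ann$position[700] - 1, ann$position[790])
  expect_equal(classify_upd(focal_amp, ann, amp_seg)$category, 5L)
  # 4: focal overlapping a gain segment
  gain_seg <- rbind(neutral,
                    make_segment("1", 700L, 800L, ann, log2(3 / 2), 1L))
  expect_equal(classify_upd(focal_amp, ann, gain_seg)$category, 4L)
  # 6: nearly whole chromosome plus a focal deletion on the chromosome
  del_seg <- rbind(neutral,
                   make_segment("1", 10L, 80L, ann, -1, -1L))
  near <- ev(15e6, max(pos1))
  expect_equal(classify_upd(near, ann, del_seg)$category, 6L)
})

test_that("gene status aggregates probe support then segment majority", {
  ann <- small_annotation(1000)
  genes <- list(gA = ann$probe_id[1:10], gB = ann$probe_id[21:30])
  states <- rep("normal", nrow(ann))
  states[1:10] <- "LOH"
  states[21] <- "HD"   # single HD probe: below min support
  calls <- rep(0L, nrow(ann))
  calls[21:30] <- 1L
  gs <- gene_status(genes, ann, states, calls)
  expect_equal(gs$status[gs$gene == "gA"], "LOH")
  expect_equal(gs$status[gs$gene == "gB"], "gain")
  expect_warning(
    gene_status(list(gX = "nope"), ann, states, calls), "no annotated")
})

test_that("a planted homozygous deletion over a 22-probe gene is called HD", {
  ann <- small_annotation()
  pos1 <- ann$position[ann$chromosome == "1"]
  # delete a window covering probes 100..121 of chromosome 1
  start <- pos1[100] - 1; end <- pos1[121]
  plan <- event_plan("s", "1", start, end, 0L, 0L)
  sig <- simulate_sample(plan, ann, noise_model(), seed = 31)$signals
  seg <- segment_sample(sig, ann, run_config(seed = 31, seg_n_perm = 200L),
                        "s")
  states <- call_allelic_state(sig, probe_segment_means(seg, ann))
  gene <- list(G = ann$probe_id[ann$chromosome == "1"][100:121])
  gs <- gene_status(gene, ann, states, probe_calls(seg, ann))
  expect_equal(gs$status, "HD")
  expect_gte(gs$n_probes_support, 2)
})

test_that("cohort UPD summaries count and bin correctly", {
  s <- upd_summary(data.frame(sample = character(0),
                              start_bp = numeric(0), end_bp = numeric(0)),
                   samples = c("a", "b"))
  expect_equal(s$per_sample$n_events, c(0L, 0L))
  expect_equal(s$median_events, 0)
  ev <- data.frame(sample = c(rep("a", 3), rep("b", 5)),
                   start_bp = 0, end_bp = 1e6)
  s2 <- upd_summary(ev, c("a", "b"))
  expect_equal(sort(s2$per_sample$n_events), c(3L, 5L))
  expect_equal(s2$median_events, 4)
  expect_equal(s2$per_sample$total_bp[s2$per_sample$sample == "b"], 5e6)
})
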