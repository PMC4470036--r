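test_that("instability metrics are zero on a neutral genome", {
  ann <- small_annotation(1000)
  n1 <- sum(ann$chromosome == "1"); n2 <- sum(ann$chromosome == "2")
  segs <- rbind(make_segment("1", 1L, n1 + 1L, ann, 0, 0L),
                make_segment("2", 1L, n2 + 1L, ann, 0, 0L))
  m <- instability_metrics(segs, ann)
  expect_equal(m$mb_altered, 0)
  expect_equal(m$frac_probes_altered, 0)
  expect_equal(m$n_altered_segments, 0L)
})

test_that("metrics equal analytic sums of planted extents at zero noise", {
  ann <- small_annotation(2000)
  plan <- event_plan("s", c("1", "2"), c(30e6, 50e6), c(60e6, 110e6),
                     c(3L, 1L), c(1L, 0L))
  sim <- simulate_sample(plan, ann,
                         noise_model(logR_sd = 1e-6, baf_sd = 0,
                                     dropout = 0), seed = 13)
  seg <- segment_sample(sim$signals, ann,
                        run_config(seed = 13, seg_n_perm = 200L), "s")
  m <- instability_metrics(seg, ann)
  # analytic truth at probe resolution, computed from the annotation
  extent <- function(chr, s, e) {
    pos <- ann$position[ann$chromosome == chr]
    inside <- pos[pos - 1 >= s & pos - 1 < e]
    c(mb = (max(inside) - (min(inside) - 1)) / 1e6, n = length(inside))
  }
  g <- extent("1", 30e6, 60e6); l <- extent("2", 50e6, 110e6)
  expect_equal(m$mb_gained, unname(g["mb"]))
  expect_equal(m$mb_lost, unname(l["mb"]))
  expect_equal(m$mb_altered, m$mb_gained + m$mb_lost)
  expect_equal(m$frac_probes_altered, unname(g["n"] + l["n"]) / nrow(ann))
  expect_equal(m$n_altered_segments, 2L)
})

test_that("metrics are additive over chromosomes", {
  ann <- small_annotation(1000)
  sig <- simulate_sample(event_plan("s", c("1", "2"), c(10e6, 20e6),
                                    c(50e6, 70e6), c(3L, 1L), c(1L, 0L)),
                         ann, noise_model(), seed = 17)$signals
  seg <- segment_sample(sig, ann, run_config(seed = 17, seg_n_perm = 200L),
                        "s")
  whole <- instability_metrics(seg, ann)
  parts <- lapply(unique(seg$chromosome), function(chr)
    instability_metrics(seg[seg$chromosome == chr, ], ann))
  expect_equal(whole$mb_altered, sum(vapply(parts, `[[`, 1, "mb_altered")))
  expect_equal(whole$n_altered_segments,
               sum(vapply(parts, `[[`, 1L, "n_altered_segments")))
})

test_that("tertiles cut at empirical thirds with ties going low", {
  t1 <- tertile_classify(1:9)
  expect_equal(as.character(t1),
               rep(c("low", "intermediate", "high"), each = 3))
  expect_warning(t2 <- tertile_classify(rep(5, 6)), "equal")
  expect_true(all(t2 == "low"))
  # order invariance
  set.seed(3)
  v <- rnorm(30)
  p <- sample(30)
  expect_equal(as.character(tertile_classify(v)[p]),
               as.character(tertile_classify(v[p])))
  # balanced thirds within 1
  tab <- table(tertile_classify(v))
  expect_true(all(abs(tab - 10) <= 1))
})

test_that("rank-sum p-values match exhaustive enumeration", {
  # identical groups: no evidence
  expect_equal(group_association(c(1, 2, 3, 1, 2, 3),
                                 rep(c("a", "b"), each = 3))$p_value, 1)
  # the documented 3 vs 3 extreme case
  ga <- group_association(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(ga$p_value, 0.1)
  expect_true(ga$exact)
  expect_equal(ga$p_value, enumerate_ranksum_p(c(1, 2, 3), c(10, 11, 12)))
  # random small groups against the enumeration oracle
  set.seed(7)
  for (i in 1:10) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    v <- sample(1:100, nx + ny)   # distinct values: no ties
    g <- rep(c("a", "b"), c(nx, ny))
    expect_equal(group_association(v, g)$p_value,
                 enumerate_ranksum_p(v[1:nx], v[-(1:nx)]),
                 tolerance = 1e-12)
  }
})

test_that("chi-square matches the textbook formula and handles degeneracy", {
  r <- frequency_chi2(5, 50, 10, 100)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- frequency_chi2(10, 50, 46, 100)
  expect_equal(r2$statistic, chi2_formula(10, 40, 46, 54), tolerance = 1e-12)
  expect_equal(r2$p_value, pchisq(r2$statistic, 1, lower.tail = FALSE))
  set.seed(11)
  for (i in 1:20) {
    na <- sample(10:80, 1); nb <- sample(10:80, 1)
    ma <- sample(1:(na - 1), 1); mb <- sample(1:(nb - 1), 1)
    expect_equal(frequency_chi2(ma, na, mb, nb)$statistic,
                 chi2_formula(ma, na - ma, mb, nb - mb), tolerance = 1e-10)
  }
  expect_warning(r3 <- frequency_chi2(0, 20, 0, 30), "degenerate")
  expect_equal(r3$statistic, 0)
  # Yates flag reproduces the corrected statistic
  ry <- frequency_chi2(10, 50, 46, 100, correct = TRUE)
  expect_lt(ry$statistic, r2$statistic)
})

test_that("replicate concordance partitions discordance by type", {
  a <- c(0L, 0L, 1L, -1L, 0L, 0L, 0L, 0L, 0L, 0L)
  b <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
  r <- replicate_concordance(a, b)
  expect_equal(r$concordance, 0.8)
  expect_equal(unname(r$breakdown["gain_nochange"]), 0.1)
  expect_equal(unname(r$breakdown["loss_nochange"]), 0.1)
  ident <- replicate_concordance(a, a)
  expect_equal(ident$concordance, 1)
  expect_length(ident$breakdown, 0)
})

test_that("duplicate simulations of one plan give concordant calls", {
  ann <- small_annotation(2000)
  plan <- event_plan("s", c("1", "2"), c(20e6, 40e6), c(70e6, 90e6),
                     c(3L, 1L), c(1L, 0L))
  cfg <- run_config(seed = 23, seg_n_perm = 200L)
  calls <- lapply(1:2, function(rep) {
    sig <- simulate_sample(plan, ann, noise_model(), seed = 100 + rep)$signals
    probe_calls(segment_sample(sig, ann, cfg, "s"), ann)
  })
  r <- replicate_concordance(calls[[1]], calls[[2]])
  expect_gt(r$concordance, 0.95)
})
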