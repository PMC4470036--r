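ann <- small_annotation()

test_that("a diploid genome has centered LogR and tri-modal BAF", {
  sig <- diploid_sample(ann, seed = 1)
  expect_lt(abs(mean(sig$logR, na.rm = TRUE)), 0.01)
  d <- pmin(abs(sig$baf), abs(sig$baf - 0.5), abs(sig$baf - 1))
  expect_gt(mean(d < 0.1, na.rm = TRUE), 0.99)
})

test_that("planted events carry the analytic LogR and BAF signal", {
  plan <- event_plan("s", c("1", "2"), c(20e6, 30e6), c(60e6, 60e6),
                     c(6L, 2L), c(1L, 0L))
  sim <- simulate_sample(plan, ann,
                         noise_model(logR_sd = 1e-6, baf_sd = 0,
                                     dropout = 0), seed = 5)
  sig <- sim$signals
  in_amp <- sig$chromosome == "1" & sig$position - 1 >= 20e6 &
    sig$position - 1 < 60e6
  expect_equal(mean(sig$logR[in_amp]), log2(6 / 2), tolerance = 1e-4)
  # copy-neutral LOH: logR stays at 0, heterozygous calls vanish
  in_upd <- sig$chromosome == "2" & sig$position - 1 >= 30e6 &
    sig$position - 1 < 60e6
  expect_equal(mean(sig$logR[in_upd]), 0, tolerance = 1e-4)
  expect_equal(sum(sig$genotype[in_upd] == "AB"), 0)
  expect_gt(mean(sig$genotype[sig$chromosome == "1" & !in_amp] == "AB"), 0.2)
})

test_that("copy-neutral LOH regions lose heterozygosity across seeds", {
  plan <- event_plan("s", "1", 30e6, 80e6, 2L, 0L)
  for (seed in 1:20) {
    sig <- simulate_sample(plan, ann, noise_model(), seed = seed)$signals
    inside <- sig$chromosome == "1" & sig$position - 1 >= 30e6 &
      sig$position - 1 < 80e6
    expect_equal(sum(sig$genotype[inside] == "AB"), 0)
    expect_lt(abs(mean(sig$logR[inside], na.rm = TRUE)), 0.05)
  }
})

test_that("homozygous deletions give saturated LogR and noise BAF", {
  plan <- event_plan("s", "1", 10e6, 40e6, 0L, 0L)
  sig <- simulate_sample(plan, ann, noise_model(), seed = 2)$signals
  inside <- sig$chromosome == "1" & sig$position - 1 >= 10e6 &
    sig$position - 1 < 40e6
  expect_lt(mean(sig$logR[inside], na.rm = TRUE), -2)
  # BAF approximately uniform: substantial mass away from {0, 0.5, 1}
  d <- pmin(abs(sig$baf[inside]), abs(sig$baf[inside] - 0.5),
            abs(sig$baf[inside] - 1))
  expect_gt(mean(d > 0.1, na.rm = TRUE), 0.4)
})

test_that("the same seed reproduces byte-identical output", {
  plan <- event_plan("s", "1", 10e6, 40e6, 3L, 1L)
  a <- simulate_sample(plan, ann, noise_model(), seed = 77)
  b <- simulate_sample(plan, ann, noise_model(), seed = 77)
  expect_identical(a, b)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_probe_matrix(list(s = a$signals), p1)
  write_probe_matrix(list(s = b$signals), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(simulate_sample(plan, ann, noise_model()), "seed")
})

test_that("event plans reject overlaps and out-of-range coordinates", {
  expect_error(event_plan("s", c("1", "1"), c(0, 5e6), c(10e6, 20e6),
                          c(3L, 1L), c(1L, 0L)), "overlap")
  bad <- event_plan("s", "1", 200e6, 210e6, 3L, 1L)
  expect_error(simulate_sample(bad, ann, noise_model(), seed = 1), "extent")
  expect_error(event_plan("s", "1", 0, 1e6, 2L, 2L))
})

test_that("cohort penetrance rounding and the null cohort behave", {
  shared <- data.frame(chromosome = "1", start = 50e6, end = 55e6,
                       total = 3L, minor = 1L)
  co <- simulate_cohort(20, ann, shared, penetrance = 0.6,
                        background_rate = 0, seed = 9)
  carriers <- unique(co$truth$sample[co$truth$shared])
  expect_equal(length(carriers), 12)
  co2 <- simulate_cohort(10, ann, shared, penetrance = 1, seed = 9)
  expect_equal(length(unique(co2$truth$sample)), 10)
  null_co <- simulate_cohort(3, ann, NULL, background_rate = 0, seed = 9)
  expect_equal(nrow(null_co$truth), 0)
  expect_error(simulate_cohort(5, ann, shared, penetrance = 1.5, seed = 1),
               "penetrance")
})

test_that("expression simulator honors sd, assignment, and degeneracies", {
  set.seed(1)
  centroids <- matrix(rnorm(40), 20, 2,
                      dimnames = list(paste0("g", 1:20), c("A", "B")))
  asg <- c(s1 = "A", s2 = "B", s3 = "A")
  m <- simulate_expression(centroids, asg, sd = 0, seed = 4)
  expect_equal(m[, "s1"], centroids[, "A"], ignore_attr = TRUE)
  expect_equal(m[, "s2"], centroids[, "B"], ignore_attr = TRUE)
  expect_error(simulate_expression(centroids, c(s1 = "C"), 0.1, seed = 1),
               "unknown class")
  dup <- cbind(A = centroids[, 1], B = centroids[, 1])
  rownames(dup) <- rownames(centroids)
  expect_warning(simulate_expression(dup, asg, 0.1, seed = 1), "tie")
})
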