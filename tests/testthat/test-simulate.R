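test_that("generators are bit-reproducible under a fixed seed", {
  d1 <- simulate_droplets(0.3, 2000, seed = 8)
  d2 <- simulate_droplets(0.3, 2000, seed = 8)
  expect_identical(d1, d2)
  m <- build_toy_ar_model()
  r1 <- simulate_spliced_reads(m, c("AR-V7" = 5), n_background = 5, seed = 8)
  r2 <- simulate_spliced_reads(m, c("AR-V7" = 5), n_background = 5, seed = 8)
  expect_identical(r1, r2)
  c1 <- simulate_cohort(seed = 8)
  c2 <- simulate_cohort(seed = 8)
  expect_identical(c1, c2)
  expect_false(identical(simulate_cohort(seed = 9)$records, c1$records))
})

test_that("droplet loading follows the Poisson occupancy", {
  z <- simulate_droplets(0, 1000, seed = 1)
  expect_equal(sum(z$truth$template), 0L)
  sim <- simulate_droplets(0.3, 15000, seed = 2)
  p <- 1 - exp(-0.3)
  frac <- mean(sim$truth$template)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 15000))
  expect_error(simulate_droplets(-1, 100, seed = 1), "lambda")
  expect_error(simulate_droplets(0.3, 100, rain_fraction = 0.5, seed = 1),
               "rain")
})

test_that("rain droplets land between the amplitude modes", {
  sim <- simulate_droplets(0.3, 5000, rain_fraction = 0.05, seed = 3)
  rain_amp <- sim$droplets$amplitude[sim$truth$is_rain]
  expect_equal(length(rain_amp), 250)
  expect_true(all(rain_amp >= 1000 & rain_amp <= 8000))
})

test_that("simulated junction reads are recovered exactly", {
  m <- build_toy_ar_model()
  sim <- simulate_spliced_reads(m, c("AR-V7" = 10), anchor_range = c(6, 20),
                                seed = 4)
  counts <- count_junction_reads(parse_sam(sim$sam), m, min_overhang = 6)
  expect_equal(counts$spanning_reads[counts$transcript_id == "AR-V7"], 10L)
  expect_equal(sum(counts$spanning_reads), 10L)

  # empty mixture: header-only SAM
  empty <- simulate_spliced_reads(m, seed = 4)
  expect_true(all(startsWith(empty$sam, "@")))

  # anchors all below the min_overhang downstream: nothing is counted
  short <- simulate_spliced_reads(m, c("AR-FL" = 8), anchor_range = c(1, 5),
                                  seed = 4)
  c2 <- count_junction_reads(parse_sam(short$sam), m, min_overhang = 6)
  expect_equal(sum(c2$spanning_reads), 0L)
  # ...but they are genuine junction reads at min_overhang 1
  c3 <- count_junction_reads(parse_sam(short$sam), m, min_overhang = 1)
  expect_equal(c3$spanning_reads[c3$transcript_id == "AR-FL"], 8L)

  expect_error(simulate_spliced_reads(m, read_len = 1, seed = 1),
               "read_len")
  expect_error(simulate_spliced_reads(m, c("NOPE" = 3), seed = 1),
               "not in model")
})

test_that("mixtures over all transcripts match truth end to end", {
  m <- build_toy_ar_model()
  mix <- c("AR-FL" = 12, "AR-V7" = 7, "AR-v567es" = 3)
  sim <- simulate_spliced_reads(m, mix, anchor_range = c(8, 25),
                                n_background = 30, seed = 6)
  counts <- count_junction_reads(parse_sam(sim$sam), m, min_overhang = 6)
  got <- setNames(counts$spanning_reads, counts$transcript_id)
  expect_equal(got[names(mix)], sim$truth[names(mix)])
  expect_equal(unique(counts$total_reads_screened), sum(mix) + 30L)
})

test_that("cohort generator honours prevalence extremes and labels", {
  all_pos <- simulate_cohort(29, prevalence = c("AR-FL" = 1), seed = 10)
  expect_equal(all_pos$truth$n_positive, 29L)
  expect_true(all(all_pos$records$copies > 0))
  none <- simulate_cohort(10, prevalence = c("AR-V7" = 0), seed = 10)
  expect_true(all(none$records$copies == 0))
  sim <- simulate_cohort(seed = 12, disease_group = "NEPC",
                         unit = "single_CTC")
  expect_equal(unique(sim$records$disease_group), "NEPC")
  expect_equal(nrow(sim$records), 29 * 3)
  expect_error(simulate_cohort(prevalence = c("AR-FL" = 1.5), seed = 1),
               "prevalence")
})

test_that("droplet simulation and quantification close the loop", {
  # clean wells: unbiased recovery within Monte-Carlo error
  for (lam in c(0.05, 0.5, 1.5)) {
    lh <- vapply(1:10, function(s) {
      sim <- simulate_droplets(lam, 15000, seed = 300 + s)
      cls <- classify_droplets(sim$droplets$amplitude, "auto")
      poisson_concentration(cls$n_pos, cls$n_total)$lambda_hat
    }, numeric(1))
    se <- sd(lh) / sqrt(length(lh))
    expect_lt(abs(mean(lh) - lam), 3 * se + 1e-9)
  }
  # rainy wells: uniform rain crosses the midpoint threshold half the
  # time, pulling the positive fraction toward 0.5 by a known amount;
  # the estimate matches that analytic expectation
  r <- 0.04
  for (lam in c(0.05, 0.5)) {
    p <- 1 - exp(-lam)
    lam_expected <- -log(1 - (p * (1 - r) + 0.5 * r))
    lh <- vapply(1:10, function(s) {
      sim <- simulate_droplets(lam, 15000, rain_fraction = r,
                               seed = 600 + s)
      cls <- classify_droplets(sim$droplets$amplitude, "auto")
      poisson_concentration(cls$n_pos, cls$n_total)$lambda_hat
    }, numeric(1))
    se <- sd(lh) / sqrt(length(lh))
    # 1e-3 allowance for higher-order rain effects (threshold shift,
    # O(r^2) terms) outside the first-order expectation
    expect_lt(abs(mean(lh) - lam_expected), 3 * se + 1e-3)
  }
})
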