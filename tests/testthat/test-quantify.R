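test_that("QC gates read exactly as stated", {
  target <- c(1L, 2L, 11L)  # amygdala subtree of the tiny atlas
  # 19 starters, all in target: fails the minimum-of-20 gate
  s19 <- make_sample(starters = c(`1` = 19L), presynaptic = c(`1` = 100L))
  qc <- qc_pass(s19, target)
  expect_false(qc$pass)
  expect_match(qc$reason, "minimum of 20")
  # exactly 60.0% in target: strict "over 60%" fails
  s60 <- make_sample(starters = c(`1` = 18L, `3` = 12L),
                     presynaptic = c(`1` = 100L))
  qc <- qc_pass(s60, target)
  expect_false(qc$pass)
  expect_match(qc$reason, "over 60")
  # 20 starters at 61% target passes (boundary min_starters inclusive)
  s61 <- make_sample(starters = c(`1` = 61L, `3` = 39L),
                     presynaptic = c(`1` = 10L))
  expect_true(qc_pass(s61, target)$pass)
  s25 <- make_sample(starters = c(`1` = 18L, `3` = 7L),
                     presynaptic = c(`1` = 10L))
  expect_true(qc_pass(s25, target)$pass)  # 25 starters, 72% in target
})

test_that("metrics match their definitions and invariants", {
  s <- make_sample(starters = c(`1` = 20L),
                   presynaptic = c(`1` = 8648L, `2` = 304L))
  m <- compute_metrics(s)
  # the worked FPR example: 304 of 8,952 -> 0.03 at two decimals
  expect_equal(m$fpr[["2"]], 304 / 8952)
  expect_equal(round(m$fpr[["2"]], 2), 0.03)
  expect_equal(sum(m$fpr), 1)
  expect_equal(sum(m$starter_dist), 1)
  # PPS: 100 presynaptic, 20 starters -> 5
  s2 <- make_sample(starters = c(`1` = 20L), presynaptic = c(`2` = 100L))
  expect_equal(compute_metrics(s2)$pps[["2"]], 5.0)
  # degenerate distribution
  expect_equal(compute_metrics(s2)$fpr[["2"]], 1.0)
  # pps additivity: sum_r pps_r == total_presyn / total_starters
  expect_equal(sum(m$pps), m$total_presynaptic / m$total_starters)
  # pps_r * total_starters recovers the counts
  expect_equal(unname(m$pps * m$total_starters),
               as.numeric(s$presynaptic))

  # FPR is scale-invariant, PPS is not
  s_scaled <- make_sample(starters = c(`1` = 40L),
                          presynaptic = c(`1` = 2 * 8648L, `2` = 2 * 304L))
  m_s <- compute_metrics(s_scaled)
  expect_equal(m_s$fpr, m$fpr)
  expect_equal(m_s$pps, m$pps)  # both scaled by 2 -> ratio unchanged
  s_presyn_only <- make_sample(starters = c(`1` = 20L),
                               presynaptic = c(`1` = 2 * 8648L, `2` = 2 * 304L))
  expect_equal(compute_metrics(s_presyn_only)$pps, 2 * m$pps)

  expect_error(compute_metrics(make_sample(starters = c(`1` = 0L),
                                           presynaptic = c(`1` = 5L))),
               "zero starters")
  expect_error(compute_metrics(make_sample(starters = c(`1` = 5L),
                                           presynaptic = c(`1` = 0L))),
               "zero presynaptic")
})

test_that("region inclusion uses a strict per-sex mean threshold", {
  mk <- function(sex, n1, n2) {
    make_sample(id = paste0(sex, n1, n2), sex = sex,
                starters = c(`1` = 30L),
                presynaptic = stats::setNames(c(n1, n2), c(2L, 3L)))
  }
  # region 2: male mean 31, female mean 0 -> included
  # region 3: both means exactly 30 -> excluded
  samples <- list(mk("male", 31L, 30L), mk("female", 0L, 30L))
  expect_equal(region_inclusion(samples), 2L)
  # all zeros -> empty set
  z <- list(mk("male", 0L, 0L), mk("female", 0L, 0L))
  expect_length(region_inclusion(z), 0)
  expect_error(region_inclusion(list(mk("male", 1L, 1L))), "each sex")
  # unassigned pseudo-region never enters testing
  u <- list(make_sample("m", "male", starters = c(`1` = 30L),
                        presynaptic = c(`0` = 500L)),
            make_sample("f", "female", starters = c(`1` = 30L),
                        presynaptic = c(`0` = 500L)))
  expect_length(region_inclusion(u), 0)
})

test_that("build_cohort pools sections, applies QC and logs exclusions", {
  atlas <- tiny_atlas(2)
  mk_calls <- function(sid, sex, n_start, n_pre, ap = 1) {
    rbind(
      if (n_start) data.frame(sample_id = sid, sex = sex, target = "amygdala",
                              side = "left", ap_mm = ap, region_id = 1L,
                              kind = "starter")[rep(1, n_start), ],
      if (n_pre) data.frame(sample_id = sid, sex = sex, target = "amygdala",
                            side = "left", ap_mm = ap, region_id = 2L,
                            kind = "presynaptic")[rep(1, n_pre), ])
  }
  calls <- rbind(
    mk_calls("A", "male", 25, 40), mk_calls("B", "male", 10, 40),
    mk_calls("C", "female", 30, 10), mk_calls("D", "female", 10, 5),
    mk_calls("E", "male", 10, 5))
  res <- build_cohort(calls, atlas, target_region_ids = list(amygdala = 11L))
  expect_length(res$samples, 2)
  expect_equal(nrow(res$exclusions), 3)
  expect_true(all(grepl("minimum of 20", res$exclusions$reason)))

  # sections across slices pool; out-of-window sections are dropped
  two_sec <- rbind(mk_calls("P", "male", 15, 20, ap = 1),
                   mk_calls("P", "male", 15, 20, ap = 0),
                   mk_calls("P", "male", 50, 50, ap = 5))  # outside window
  res2 <- build_cohort(two_sec, atlas, target_region_ids = list(amygdala = 11L))
  expect_length(res2$samples, 1)
  expect_equal(sum(res2$samples[[1]]$starters), 30)
  expect_equal(sum(res2$samples[[1]]$presynaptic), 40)

  # independent group-by tally oracle on a passing sample
  sub <- calls[calls$sample_id == "A", ]
  oracle <- tapply(rep(1, nrow(sub)), list(sub$kind, sub$region_id), sum)
  smp <- res$samples[[which(vapply(res$samples, `[[`, character(1),
                                   "sample_id") == "A")]]
  expect_equal(unname(smp$starters[["1"]]), unname(oracle["starter", "1"]))
  expect_equal(unname(smp$presynaptic[["2"]]), unname(oracle["presynaptic", "2"]))

  # empty input -> empty cohort and log
  res0 <- build_cohort(calls[0, ], atlas)
  expect_length(res0$samples, 0)
  expect_equal(nrow(res0$exclusions), 0)

  # inconsistent metadata for one sample_id errors
  bad <- rbind(mk_calls("X", "male", 25, 10), mk_calls("X", "female", 25, 10))
  expect_error(build_cohort(bad, atlas,
                            target_region_ids = list(amygdala = 11L)),
               "sample_id")
})

test_that("cohort CSV round-trips", {
  atlas <- make_synthetic_atlas(1, 4, c(48, 48), seed = 1)
  spec <- cohort_spec(data.frame(region_id = 1:4, base_pps = 3,
                                 male_multiplier = 2),
                      n_male = 2, n_female = 2, seed = 5)
  sim <- simulate_cohort(spec, atlas)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(sim$samples, path)
  back <- read_cohort_csv(path)
  orig <- sim$samples[order(vapply(sim$samples, `[[`, character(1), "sample_id"))]
  for (i in seq_along(orig)) {
    b <- back[[orig[[i]]$sample_id]]
    expect_equal(b$sex, orig[[i]]$sex)
    expect_equal(sum(b$starters), sum(orig[[i]]$starters))
    expect_equal(sum(b$presynaptic), sum(orig[[i]]$presynaptic))
  }
})
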