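test_that("synthetic atlas mosaics are minimal, mirrored and deterministic", {
  a <- make_synthetic_atlas(1, 2, c(64, 64), seed = 7)
  mask <- a$slices[[1]]$label_mask
  expect_setequal(unique(as.vector(mask)), c(0L, 1L, 2L))
  b <- make_synthetic_atlas(1, 2, c(64, 64), seed = 7)
  expect_identical(mask, b$slices[[1]]$label_mask)
  # mirrored about midline_x = w/2
  expect_identical(mask, mask[, ncol(mask):1])

  a3 <- make_synthetic_atlas(3, 12, c(96, 128), seed = 1)
  leaf <- a3$nodes$id[a3$nodes$level_tag == "leaf"]
  present <- vapply(leaf, function(r) {
    any(vapply(a3$slices, function(s) any(s$label_mask == r), logical(1)))
  }, logical(1))
  expect_true(all(present))  # every region appears in >= 1 slice
  expect_true(all(diff(vapply(a3$slices, `[[`, numeric(1), "ap_mm")) < 0))

  expect_error(make_synthetic_atlas(1, 5000, c(32, 32), seed = 1),
               "representable")
  expect_error(make_synthetic_atlas(1, 2, c(16, 16), seed = 1), "32x32")
})

test_that("rendering matches its truth table", {
  noise <- list(background_mean = 100, background_sd = 8, psf_sigma_px = 1)
  # empty cell list: both channels pure noise around background_mean
  img0 <- render_section(truth_cells(numeric(0), numeric(0), numeric(0),
                                     numeric(0), character(0), integer(0)),
                         c(64, 64), noise, seed = 2)
  expect_equal(mean(img0$helper), 100, tolerance = 0.05)
  expect_equal(mean(img0$rabies), 100, tolerance = 0.05)

  # one "both" cell: local maximum at (x, y) in both channels
  cells <- truth_cells(30, 20, 5, 120, "both", 1L)
  img <- render_section(cells, c(64, 64), noise, seed = 3)
  for (ch in img) {
    peak <- which(ch == max(ch), arr.ind = TRUE)
    expect_lt(abs(peak[1, "col"] - 1 - 30), 3)  # 0-based x vs column
    expect_lt(abs(peak[1, "row"] - 1 - 20), 3)
    expect_gt(max(ch), 100 + 100)
  }

  expect_error(render_section(truth_cells(500, 2, 3, 50, "rabies", 1L),
                              c(64, 64), noise, seed = 1), "bounds")

  # determinism
  img2 <- render_section(cells, c(64, 64), noise, seed = 3)
  expect_identical(img, img2)
})

test_that("placed cells reproduce requested counts and atlas labels", {
  atlas <- make_synthetic_atlas(1, 6, c(96, 128), seed = 4)
  slice <- atlas$slices[[1]]
  want <- stats::setNames(c(4L, 3L, 2L), c(1L, 2L, 3L))
  cells <- place_cells(slice, want, "rabies", radius_px = 3,
                       min_spacing_px = 8, seed = 6)
  got <- table(cells$region_id)
  expect_equal(as.integer(got[names(want)]), as.integer(want))
  # perfect-oracle counting: mask lookup at rounded coordinates == truth
  looked <- slice$label_mask[cbind(round(cells$y) + 1, round(cells$x) + 1)]
  expect_equal(looked, cells$region_id)
  expect_true(all(cells$is_starter == (cells$channel == "both")))
})

test_that("simulated cohorts respect rates, nulls and determinism", {
  atlas <- make_synthetic_atlas(1, 10, c(64, 96), seed = 2)
  regions <- data.frame(region_id = 1:10, base_pps = c(0, rep(5, 9)),
                        male_multiplier = 1)
  spec <- cohort_spec(regions, n_male = 3, n_female = 3, starter_mean = 40,
                      starter_target_region = 2L, seed = 11)
  sim <- simulate_cohort(spec, atlas)
  expect_length(sim$samples, 6)
  # base_pps = 0 -> always zero counts in that region
  expect_true(all(vapply(sim$samples, function(s) s$presynaptic[["1"]] == 0,
                         logical(1))))
  for (s in sim$samples) {
    expect_true(sum(s$starters) >= 1)
    expect_true(all(s$presynaptic >= 0))
  }
  sim2 <- simulate_cohort(spec, atlas)
  expect_identical(lapply(sim$samples, unclass), lapply(sim2$samples, unclass))

  expect_error(
    simulate_cohort(cohort_spec(data.frame(region_id = 999, base_pps = 1,
                                           male_multiplier = 1), seed = 1),
                    atlas), "999")
})

test_that("multiplicative sex effect lands in the expected fold range", {
  # generator-level Monte Carlo: 100 seeds, multiplier 5, base 5, 7v7
  atlas <- make_synthetic_atlas(1, 2, c(64, 64), seed = 1)
  regions <- data.frame(region_id = 1:2, base_pps = 5,
                        male_multiplier = c(5, 1))
  ratios <- vapply(1:100, function(s) {
    spec <- cohort_spec(regions, n_male = 7, n_female = 7, starter_mean = 50,
                        starter_target_region = 1L, seed = s)
    sim <- simulate_cohort(spec, atlas)
    pps <- vapply(sim$samples, function(x) {
      x$presynaptic[["1"]] / sum(x$starters)
    }, numeric(1))
    sexes <- vapply(sim$samples, `[[`, character(1), "sex")
    mean(pps[sexes == "male"]) / mean(pps[sexes == "female"])
  }, numeric(1))
  expect_true(all(ratios >= 3 & ratios <= 8))
})
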