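test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(n_mci = 0), class = "boldhurst_invalid_input")
  expect_error(cohort_spec(baseline_H = 1.1), class = "boldhurst_invalid_input")
  expect_error(cohort_spec(baseline_H = 0.9, delta_H = 0.2),
               class = "boldhurst_invalid_input")
  expect_error(cohort_spec(n_rois = 10, affected_rois = c(3, 11)),
               class = "boldhurst_invalid_input")
  expect_silent(cohort_spec(n_mci = 1, n_hc = 1, n_rois = 4, affected_rois = 1:2))
})

test_that("block atlas has a uniform label histogram and cuboid parcels", {
  atlas <- build_block_atlas(246, 8)
  tab <- table(atlas[atlas > 0])
  expect_length(tab, 246)
  expect_true(all(tab == 8))
  expect_identical(build_block_atlas(1, 1), array(1L, dim = c(1, 1, 1)))
})

test_that("cohort sizes, labels and reproducibility contracts hold", {
  spec <- cohort_spec(n_mci = 3, n_hc = 2, n_rois = 4, voxels_per_roi = 8,
                      n_timepoints = 64, affected_rois = 1:2, seed = 9)
  co <- simulate_cohort(spec)
  expect_length(co$bold, 5)
  expect_identical(co$participants$group, c(rep("MCI", 3), rep("HC", 2)))
  expect_identical(dim(co$bold[[1]]), c(dim(co$atlas), 64L))
  co2 <- simulate_cohort(spec)
  expect_identical(co$bold, co2$bold)  # bit-identical given the seed
})

test_that("a 64 + 60 cohort emits 124 subjects", {
  spec <- cohort_spec(n_mci = 64, n_hc = 60, n_rois = 2, voxels_per_roi = 1,
                      n_timepoints = 8, affected_rois = 1L)
  co <- simulate_cohort(spec)
  expect_identical(nrow(co$participants), 124L)
})

test_that("delta_H shifts downstream group ROI means in exactly the affected ROIs", {
  # direct check on generated series (no estimator in the loop): the series
  # variance of fGn + noise is the same in both groups, but affected-ROI MCI
  # voxels carry different temporal structure; compare estimated H via the
  # package's own estimator at alpha = 0.001 over 30 + 30 subjects
  spec <- cohort_spec(n_mci = 30, n_hc = 30, n_rois = 6, voxels_per_roi = 9,
                      n_timepoints = 128, affected_rois = c(2, 5),
                      delta_H = -0.15, noise_sd = 0.05, seed = 77)
  co <- simulate_cohort(spec)
  mask <- co$atlas > 0
  fm <- build_feature_matrix(
    lapply(co$bold, function(b) suppressMessages(hurst_map(b, mask))),
    co$atlas, co$participants)
  p <- vapply(1:6, function(j) two_sample_t(fm$values[, j], fm$groups)$p,
              numeric(1))
  expect_true(all(p[c(2, 5)] < 0.001))
  expect_true(all(p[-c(2, 5)] > 0.001))
})

test_that("null cohorts (delta_H = 0) are exchangeable between groups", {
  spec <- cohort_spec(n_mci = 12, n_hc = 12, n_rois = 4, voxels_per_roi = 8,
                      n_timepoints = 96, delta_H = 0, affected_rois = 1:2,
                      seed = 5)
  co <- simulate_cohort(spec)
  # same generative law: per-subject voxel variances from both groups are
  # draws from one distribution
  v <- vapply(co$bold, function(b) stats::var(as.vector(b[1, 1, 1, ])), numeric(1))
  expect_gt(stats::t.test(v[1:12], v[13:24])$p.value, 0.01)
})

test_that("written cohorts round-trip through NIfTI and TSV", {
  spec <- cohort_spec(n_mci = 1, n_hc = 1, n_rois = 2, voxels_per_roi = 4,
                      n_timepoints = 32, affected_rois = 1L, seed = 3)
  co <- simulate_cohort(spec)
  dir <- tempfile("cohort_")
  write_cohort(co, dir)
  back <- boldhurst:::read_cohort(dir, tr_seconds = 2)
  expect_equal(back$participants$group, co$participants$group)
  expect_equal(back$atlas, co$atlas, ignore_attr = TRUE)
  expect_equal(back$bold[[1]], co$bold[[1]], tolerance = 1e-6,
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
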