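test_that("gas/tissue fractions follow the air-water mixture with clamping", {
  f <- gas_tissue_fractions(c(-1200, -1000, -500, 0, 100))
  expect_equal(f$gas, c(1, 1, 0.5, 0, 0))
  expect_equal(f$tissue, c(0, 0, 0.5, 1, 1))
})

test_that("aeration classification uses the printed closed integer bins", {
  one <- function(hu) {
    rep <- classify_aeration(ct_volume(array(hu, c(1, 1, 1))))
    as.character(rep$compartment[rep$n_voxels == 1])
  }
  expect_equal(one(-950), "over_distended")
  expect_equal(one(-901), "over_distended")
  expect_equal(one(-900), "normally_aerated")
  expect_equal(one(-500), "poorly_aerated")
  expect_equal(one(-101), "poorly_aerated")
  expect_equal(one(-100), "atelectasis")
  expect_equal(one(100), "atelectasis")
  # below -1000 clamps into over-distended; above +100 is excluded
  expect_equal(one(-1024), "over_distended")
  rep <- classify_aeration(ct_volume(array(500, c(1, 1, 1))))
  expect_equal(sum(rep$n_voxels), 0L)
  expect_equal(attr(rep, "n_excluded"), 1L)
})

test_that("hand-counted toy volume gives the expected A/N and O/N ratios", {
  hu <- array(c(-950, -950, -800, -800, -800, -800, -800, -400, -400, 0),
              c(10, 1, 1))
  rep <- classify_aeration(ct_volume(hu))
  expect_equal(rep$n_voxels, c(2L, 5L, 2L, 1L))
  r <- aeration_ratios(rep)
  expect_equal(r$a_n, 0.2)
  expect_equal(r$o_n, 0.4)
})

test_that("a uniform normally aerated volume occupies one compartment exactly", {
  hu <- array(-900, c(6, 5, 4))
  rep <- classify_aeration(ct_volume(hu, spacing = c(0.5, 0.5, 5)))
  expect_equal(rep$volume_ml[rep$compartment == "normally_aerated"],
               6 * 5 * 4 * 0.5 * 0.5 * 5 / 1000)
  expect_equal(sum(rep$n_voxels[rep$compartment != "normally_aerated"]), 0L)
})

test_that("compartment counts partition the masked in-range voxels", {
  for (seed in 1:3) {
    ct <- random_masked_ct(seed, shape = c(16, 16, 6))
    rep <- classify_aeration(ct)
    expect_equal(sum(rep$n_voxels) + attr(rep, "n_excluded"), sum(ct$mask))
  }
  expect_error(classify_aeration(ct_volume(array(-500, c(2, 2, 2)),
                                           array(FALSE, c(2, 2, 2)))),
               "empty")
})

test_that("ring geometry is in-plane at 5 mm slices and fails when empty", {
  ct <- ct_volume(array(-700, c(12, 12, 4)))
  map <- cressoni_index(ct)
  # independent count of in-plane offsets with 0.5 mm pixels:
  # 4.82 <= sqrt(i^2+j^2) <= 7.35
  cnt <- 0
  for (i in -8:8) for (j in -8:8) {
    d <- 0.5 * sqrt(i^2 + j^2)
    if (d >= 2.41 && d <= 3.675) cnt <- cnt + 1
  }
  expect_equal(map$n_ring_offsets, cnt)
  expect_error(cressoni_index(ct_volume(array(-700, c(4, 4, 2)),
                                        spacing = c(10, 10, 10))),
               "configuration")
  expect_error(cressoni_index(ct, r1 = 4, r2 = 3), "smaller")
})

test_that("uniform fields are perfectly homogeneous and a dense voxel stands out", {
  uni <- cressoni_index(ct_volume(array(-700, c(20, 20, 6))))
  expect_equal(uni$index[uni$valid], rep(1, sum(uni$valid)))
  expect_equal(h_ct(uni), 0)

  hu <- array(-800, c(21, 21, 5))
  hu[11, 11, 3] <- -100
  map <- cressoni_index(ct_volume(hu))
  expect_equal(map$index[11, 11, 3], 0.8 / 0.1, tolerance = 1e-12)
  expect_gt(map$index[11, 11, 3], 1.61)
})

test_that("vectorized inhomogeneity index equals the brute-force oracle", {
  for (seed in 1:3) {
    ct <- random_masked_ct(seed)
    map <- cressoni_index(ct)
    oracle <- cressoni_oracle(ct)
    expect_identical(map$valid, oracle$valid)
    expect_equal(map$index, oracle$index, tolerance = 1e-12)
  }
})

test_that("the index map is invariant under in-plane quarter rotation", {
  ct <- random_masked_ct(11, shape = c(24, 24, 6))
  map <- cressoni_index(ct)
  rot <- function(a) aperm(a[, dim(a)[2]:1, ], c(2, 1, 3))
  ct_rot <- ct_volume(rot(ct$hu), rot(ct$mask), spacing = ct$spacing)
  map_rot <- cressoni_index(ct_rot)
  expect_equal(map_rot$index, rot(map$index), tolerance = 1e-12)
})

test_that("H_CT is the pathologic-to-normal voxel ratio with flagged edge cases", {
  fake <- structure(
    list(index = array(c(rep(2, 10), rep(1, 90)), c(10, 10, 1)),
         valid = array(TRUE, c(10, 10, 1)), n_ring_offsets = 1),
    class = "inhomogeneity_map")
  expect_equal(h_ct(fake), 10 / 90)
  all_path <- structure(
    list(index = array(5, c(2, 2, 1)), valid = array(TRUE, c(2, 2, 1)),
         n_ring_offsets = 1),
    class = "inhomogeneity_map")
  expect_warning(expect_equal(h_ct(all_path), Inf), "infinite")
})

test_that("CT volumes round-trip through NIfTI with spacing preserved", {
  ct <- random_masked_ct(5, shape = c(8, 8, 4))
  hu_path <- withr::local_tempfile(fileext = ".nii.gz")
  mask_path <- withr::local_tempfile(fileext = ".nii.gz")
  write_ct_volume(ct, hu_path, mask_path)
  back <- read_ct_volume(hu_path, mask_path)
  expect_equal(back$hu, ct$hu, ignore_attr = TRUE)
  expect_equal(back$mask, ct$mask)
  expect_equal(back$spacing, ct$spacing, tolerance = 1e-6)
})
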