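test_that("lv_volume is voxel count times voxel volume and additive", {
  vox <- array(0L, c(4, 10, 10))
  vox[sample(length(vox), 100)] <- 1L
  m <- mask_stack(vox, c(1.5, 0.5, 0.5))
  expect_equal(lv_volume(m), 100 * 0.375)
  expect_equal(lv_volume(mask_stack(array(0L, c(2, 2, 2)))), 0)

  # per-slice summation oracle on a random 1000-voxel mask
  big <- random_mask(c(10L, 20L, 20L), n_fg = 1000L, seed = 2L)
  per_slice <- sum(vapply(seq_len(10), function(z) sum(big$voxels[z, , ]),
                          numeric(1)))
  expect_equal(lv_volume(big), per_slice * prod(big$spacing_mm))

  # additivity over a disjoint union
  a <- array(0L, c(4, 6, 6)); a[1:2, , ] <- 1L
  b <- array(0L, c(4, 6, 6)); b[4, 1:3, ] <- 1L
  expect_equal(lv_volume(mask_stack(a | b)),
               lv_volume(mask_stack(a)) + lv_volume(mask_stack(b)))
})

test_that("dice_score matches hand counts and is symmetric", {
  a <- array(0L, c(2, 4, 4)); a[1, 1, 1:4] <- 1L
  b <- array(0L, c(2, 4, 4)); b[1, 1, 3:4] <- 1L; b[2, 2, 1:2] <- 1L
  expect_equal(dice_score(mask_stack(a), mask_stack(a)), 1)
  expect_equal(dice_score(mask_stack(a), mask_stack(b)), 0.5)  # 2*2/(4+4)
  expect_equal(dice_score(mask_stack(b), mask_stack(a)), 0.5)
  disjoint <- array(0L, c(2, 4, 4)); disjoint[2, 4, ] <- 1L
  expect_equal(dice_score(mask_stack(a), mask_stack(disjoint)), 0)
  expect_equal(dice_score(mask_stack(array(0L, c(2, 4, 4))),
                          mask_stack(array(0L, c(2, 4, 4)))), 1)
  expect_error(dice_score(mask_stack(a), mask_stack(array(0L, c(2, 4, 5)))),
               "share one shape")
})

test_that("class_imbalance is the foreground/background ratio", {
  half <- array(0L, c(2, 4, 4)); half[1, , ] <- 1L
  expect_equal(class_imbalance(mask_stack(half)), 1)
  expect_equal(class_imbalance(mask_stack(array(0L, c(2, 4, 4)))), 0)
  ten <- array(0L, c(12, 86, 98)); ten[6, 40, 1:10] <- 1L
  expect_equal(class_imbalance(mask_stack(ten)), 10 / (12 * 86 * 98 - 10))
})

test_that("postprocess fills holes, removes protrusions, keeps solids, is idempotent", {
  # solid block survives opening untouched
  solid <- array(0, c(7, 9, 9)); solid[2:6, 2:8, 2:8] <- 0.9
  out <- postprocess(solid, postprocess_spec(), c(1, 1, 1))
  expect_identical(out$voxels, array(as.integer(solid > 0.5), dim(solid)))

  # interior zero-voxel is refilled
  holed <- array(0, c(7, 9, 9)); holed[2:6, 2:6, 2:6] <- 0.9
  holed[4, 4, 4] <- 0.1
  filled <- postprocess(holed, postprocess_spec(), c(1, 1, 1))
  expect_equal(filled$voxels[4, 4, 4], 1L)
  expect_equal(sum(filled$voxels), 125)

  # 1-voxel-wide 3-voxel protrusion is eroded away, cube kept: 125 voxels
  prot <- array(0, c(9, 11, 11)); prot[3:7, 3:7, 3:7] <- 0.9
  prot[5, 5, 8:10] <- 0.9
  cleaned <- postprocess(prot, postprocess_spec(), c(1, 1, 1))
  expect_equal(sum(cleaned$voxels), 125)
  expect_true(all(cleaned$voxels[, , 8:10] == 0))

  # idempotence under the default spec
  twice <- postprocess(cleaned$voxels * 1.0, postprocess_spec(), c(1, 1, 1))
  expect_identical(twice$voxels, cleaned$voxels)

  expect_warning(postprocess(array(0.1, c(3, 3, 3)), postprocess_spec(),
                             c(1, 1, 1)), "empty mask")
})

test_that("select_variance_slice finds the only varying slice and breaks ties low", {
  phases <- lapply(0:3, function(i) {
    vox <- array(0L, c(8, 10, 10))
    vox[4, 1:(i + 2), 1:5] <- 1L  # constant nonzero elsewhere
    vox[2, 1:3, 1:3] <- 1L
    list(phase_index = i, mask = mask_stack(vox, c(1, 1, 1)))
  })
  s <- cine_series(phases, spacing_mm = c(1, 1, 1))
  sv <- select_variance_slice(s)
  expect_equal(sv$slice_index, 4)
  expect_equal(sv$areas_mm2, (2:5) * 5)

  flat <- lapply(0:2, function(i) {
    vox <- array(0L, c(4, 6, 6)); vox[2, 1:2, 1:2] <- 1L
    list(phase_index = i, mask = mask_stack(vox, c(1, 1, 1)))
  })
  expect_warning(sv2 <- select_variance_slice(cine_series(flat, spacing_mm = c(1, 1, 1))),
                 "constant|tie")
  expect_equal(sv2$slice_index, 1)
})

test_that("surface_area matches analytic oracles and scales with spacing", {
  ball <- ball_mask(r = 10)
  a <- surface_area(ball)
  expect_lt(abs(a - 4 * pi * 100) / (4 * pi * 100), 0.05)

  # doubling every spacing multiplies the area by ~4 (exactly: same mesh scaled)
  ball2 <- mask_stack(ball$voxels, c(2, 2, 2))
  expect_equal(surface_area(ball2) / a, 4, tolerance = 1e-12)

  # single voxel still has a positive finite area
  single <- array(0L, c(5, 5, 5)); single[3, 3, 3] <- 1L
  a1 <- surface_area(mask_stack(single, c(1, 1, 1)))
  expect_true(is.finite(a1) && a1 > 0)

  expect_error(surface_area(mask_stack(array(0L, c(3, 3, 3)))), "empty")
})

test_that("voxelised ellipsoid and sphere volumes match analytic values", {
  ell <- ellipsoid_mask(20, 15, 8)
  expect_lt(abs(lv_volume(ell) - 4 / 3 * pi * 20 * 15 * 8) /
              (4 / 3 * pi * 20 * 15 * 8), 0.02)
  ball <- ball_mask(r = 10)
  expect_lt(abs(lv_volume(ball) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
})

test_that("cycle_metric_curve carries metric, phases, and slice index", {
  res <- generate_synthetic_cine(small_spec(n_phases = 6L))
  cv <- cycle_metric_curve(res$series, "volume")
  expect_s3_class(cv, "cycle_curve")
  expect_equal(cv$phase_indices, 0:5)
  expect_equal(cv$values,
               vapply(res$series$phases, function(p) lv_volume(p$mask), numeric(1)))
  sa <- cycle_metric_curve(res$series, "slice_area")
  expect_false(is.na(sa$selected_slice_index))
  expect_true(all(sa$values >= 0))
})
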