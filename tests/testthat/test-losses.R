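# 8-voxel fixture with 4 foreground / 4 background voxels
fix8 <- function() {
  t <- array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2))
  t
}

test_that("soft Dice loss reproduces its closed forms", {
  t <- fix8()
  # perfect prediction: 1 - 5/9 - 5/9 = -1/9
  expect_equal(soft_dice_loss(t, t), -1 / 9, tolerance = 1e-15)
  # anti-perfect: 1 - 1/9 - 1/9 = 7/9
  expect_equal(soft_dice_loss(t, 1 - t), 7 / 9, tolerance = 1e-15)
  # perfect prediction at a million voxels is 0 within the epsilon bound
  n <- 1e6
  big <- array(rep(c(1, 0), each = n / 2), c(100, 100, 100))
  loss <- soft_dice_loss(big, big)
  expect_lt(abs(loss), 2 * 1 / (n / 2 + 1))
  expect_lt(abs(loss), 1e-5)
})

test_that("soft Dice loss is complement-symmetric and minimised at p = t", {
  t <- array(c(1, 0, 1, 0, 0, 1), c(1, 2, 3))
  p <- array(runif(6), c(1, 2, 3))
  expect_equal(soft_dice_loss(t, p), soft_dice_loss(1 - t, 1 - p), tolerance = 1e-14)

  # brute-force grid search over p on <= 4-voxel instances
  grid <- seq(0, 1, by = 0.1)
  for (tv in list(c(1, 0), c(1, 1, 0), c(0, 1, 0, 1))) {
    tt <- array(tv, c(1, 1, length(tv)))
    best <- Inf; best_p <- NULL
    combos <- do.call(expand.grid, rep(list(grid), length(tv)))
    for (i in seq_len(nrow(combos))) {
      pp <- array(as.numeric(combos[i, ]), dim(tt))
      v <- soft_dice_loss(tt, pp)
      if (v < best) { best <- v; best_p <- pp }
    }
    expect_equal(as.vector(best_p), tv)
    expect_equal(best, soft_dice_loss(tt, tt), tolerance = 1e-12)
  }
})

test_that("border weight map matches hand-computed values", {
  # a 3-voxel-thick slab: background voxels adjacent to it sit on the border
  t <- array(0L, c(5, 7, 7)); t[2:4, 2:4, 2:4] <- 1L
  wm <- weight_map(t)
  # adjacent background voxel: d1 = d2 = 0 -> border term w0 = 2
  expect_equal(wm$border[3, 5, 3], 2, tolerance = 1e-9)
  # one voxel further: d1 = d2 = 1 -> 2 exp(-(1+1)^2/2) = 2 e^-2
  expect_equal(wm$border[3, 6, 3], 2 * exp(-2), tolerance = 1e-9)
  # far corner: both distances large -> essentially zero
  far <- array(0L, c(3, 20, 20)); far[2, 1:2, 1:2] <- 1L
  wmf <- weight_map(far)
  expect_lt(wmf$border[2, 20, 20], 1e-20)
  # border term is zero on foreground
  expect_true(all(wm$border[t == 1] == 0))
  # weights decompose as w_c + border
  expect_equal(wm$weights, wm$w_c + wm$border, tolerance = 1e-15)
})

test_that("class-balancing term always has mean 1", {
  for (seed in 1:20) {
    m <- random_mask(c(4L, 8L, 8L), n_fg = sample(1:200, 1), seed = seed)
    wm <- weight_map(m$voxels)
    expect_equal(mean(wm$w_c), 1, tolerance = 1e-12)
  }
  expect_warning(uni <- weight_map(array(1L, c(2, 2, 2))), "single-class")
  expect_true(all(uni$weights == 1))
})

test_that("two components use the two nearest borders", {
  t <- array(0L, c(1, 1, 9)); t[1, 1, c(1, 9)] <- 1L
  wm <- weight_map(t)
  # centre voxel: d1 = |5-1|-1 = 3 to either component -> 2 exp(-(3+3)^2/2)
  expect_equal(wm$border[1, 1, 5], 2 * exp(-36 / 2), tolerance = 1e-12)
  # voxel next to the left component: d1 = 0, d2 = 6 -> 2 exp(-36/2)
  expect_equal(wm$border[1, 1, 2], 2 * exp(-36 / 2), tolerance = 1e-12)
})

test_that("weighted soft Dice reduces to unweighted and emphasises border errors", {
  t <- fix8()
  w1 <- array(1, dim(t))
  expect_equal(weighted_soft_dice_loss(t, t, weights = w1),
               soft_dice_loss(t, t), tolerance = 1e-12)
  p <- array(runif(8), dim(t))
  expect_equal(weighted_soft_dice_loss(t, p, weights = w1),
               soft_dice_loss(t, p), tolerance = 1e-12)

  # with weights entering all sums, a perfect prediction stays near the
  # unweighted optimum (difference bounded by the epsilon smoothing)
  slab <- array(0L, c(5, 7, 7)); slab[2:4, 2:4, 2:4] <- 1L
  expect_lt(abs(weighted_soft_dice_loss(slab, slab) - soft_dice_loss(slab, slab)),
            2 * 1 / sum(slab))

  # doubling w0 raises the loss for a border error, not for a distant error
  # (the border emphasis sits on background voxels adjacent to the ROI, so
  # the border error is a false positive next to the slab)
  base <- loss_config(w0 = 2); strong <- loss_config(w0 = 4)
  border_err <- slab * 1.0; border_err[3, 5, 3] <- 1      # false positive on the border
  distant_err <- slab * 1.0; distant_err[5, 7, 7] <- 1    # error far from the ROI
  expect_gt(weighted_soft_dice_loss(slab, border_err, strong),
            weighted_soft_dice_loss(slab, border_err, base))
  d_base <- weighted_soft_dice_loss(slab, distant_err, base)
  d_strong <- weighted_soft_dice_loss(slab, distant_err, strong)
  expect_lt(abs(d_strong - d_base),
            abs(weighted_soft_dice_loss(slab, border_err, strong) -
                weighted_soft_dice_loss(slab, border_err, base)))
})

test_that("binary cross-entropy and hybrid loss match closed forms", {
  ones <- array(1, c(2, 2, 2))
  expect_equal(bce_loss(ones, ones), -log(1 - 1e-7), tolerance = 1e-12)
  half <- array(0.5, c(2, 2, 2))
  expect_equal(bce_loss(ones, half), log(2), tolerance = 1e-12)
  # extreme mispredictions stay finite thanks to clipping
  expect_true(is.finite(bce_loss(ones, array(0, c(2, 2, 2)))))

  t <- fix8()
  expect_equal(hybrid_loss(t, t), bce_loss(t, t) + soft_dice_loss(t, t),
               tolerance = 1e-12)
  expect_equal(hybrid_loss(t, t), -log(1 - 1e-7) - 1 / 9, tolerance = 1e-9)
})
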