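test_that("resampling a 1 mm volume is the identity", {
  v <- generate_phantom(small_spec(seed = 1))
  expect_identical(resample_isotropic(v)$breast_mask, v$breast_mask)
})

test_that("resampling a 2 mm ellipsoid recovers the analytic volume", {
  # solid ellipsoid voxelized at 2 mm, independent of the phantom code
  dm <- c(24, 28, 30); sp <- c(2, 2, 2); ax <- c(15, 20, 22)
  ctr <- (dm - 1) * sp / 2
  x <- (seq_len(dm[1]) - 1) * sp[1] - ctr[1]
  y <- (seq_len(dm[2]) - 1) * sp[2] - ctr[2]
  z <- (seq_len(dm[3]) - 1) * sp[3] - ctr[3]
  q <- outer(outer((x / ax[1])^2, (y / ax[2])^2, "+"), (z / ax[3])^2, "+")
  vol <- labeled_volume((q <= 1) * 1L, spacing = sp)
  iso <- resample_isotropic(vol)
  expect_equal(iso$spacing, c(1, 1, 1))
  expect_lt(abs(sum(iso$breast_mask) - 4 / 3 * pi * prod(ax)) /
              (4 / 3 * pi * prod(ax)), 0.05)
})

test_that("fibroglandular composition survives resampling", {
  for (s in 1:2) {
    v <- generate_phantom(small_spec_2mm(ft_mode = "sparse", seed = s))
    expect_lt(abs(fibroglandular_composition(v) -
                    fibroglandular_composition(resample_isotropic(v))), 0.02)
  }
})

test_that("nipple angle recovers the constructed offset", {
  v0 <- generate_phantom(small_spec(nipple_offset_deg = 0, seed = 2))
  expect_lt(abs(nipple_angle(v0)), 2)
  v30 <- generate_phantom(small_spec(nipple_offset_deg = 30, seed = 2))
  expect_lt(abs(nipple_angle(v30) - 30), 2)
  vneg <- generate_phantom(small_spec(nipple_offset_deg = -25, seed = 2))
  expect_lt(abs(nipple_angle(vneg) + 25), 2)
  for (th in c(-60, -10, 45, 80)) {
    v <- generate_phantom(phantom_spec(shape = c(48L, 60L, 60L),
                                       breast_halfaxes_mm = c(18, 22, 20),
                                       nipple_offset_deg = th, seed = 2))
    a <- nipple_angle(v)
    expect_gt(a, -90); expect_lte(a, 90)
  }
  v0$nipple <- NULL
  expect_error(nipple_angle(v0), "landmark")
})

test_that("the surface auto-detector recovers the constructed nipple", {
  for (th in c(0, 20)) {
    v <- generate_phantom(small_spec(nipple_offset_deg = th, seed = 6))
    expect_lte(sqrt(sum((detect_nipple(v) - v$nipple)^2)), 3, label = th)
  }
})

test_that("rotation by zero is the identity and inverses compose to Dice >= 0.98", {
  v <- generate_phantom(small_spec(ft_mode = "nonsparse", seed = 8))
  ob0 <- rotate_about_si(v, 0)
  expect_identical(ob0$breast_mask, v$breast_mask)
  expect_identical(ob0$ft_mask, v$ft_mask)

  fwd <- rotate_about_si(v, 30)
  back <- rotate_about_si(ob_as_volume(fwd), -30)
  expect_gte(dice(back$breast_mask, v$breast_mask), 0.98)
  expect_gte(dice(back$ft_mask, v$ft_mask), 0.98)
})

test_that("rotation aligns the nipple with the anterior axis through the centroid", {
  for (th in c(10, 25)) {
    v <- generate_phantom(small_spec(nipple_offset_deg = th, seed = 9))
    ob <- rotate_about_si(v, nipple_angle(v))
    w <- which(ob$breast_mask > 0, arr.ind = TRUE)
    expect_lte(abs(ob$nipple[3] - mean(w[, 3])), 2, label = th)
  }
})

test_that("region curves of a symmetric phantom are rotation invariant", {
  mk <- function(th, mode) preprocess_volume(generate_phantom(phantom_spec(
    breast_halfaxes_mm = c(40, 50, 50), ft_mode = mode,
    nipple_offset_deg = th, seed = 1)))
  # radially symmetric FT: curves agree pointwise except where the
  # sharp annulus transitions land inside a one-pixel ring
  a0 <- subject_rgf(mk(0, "annulus")); a30 <- subject_rgf(mk(30, "annulus"))
  for (reg in names(a0)) {
    d <- abs(a0[[reg]]$value - a30[[reg]]$value)
    r <- a0[[reg]]$r
    away <- abs(r - 0.3) > 0.07 & abs(r - 0.6) > 0.07
    expect_lt(max(d[away], na.rm = TRUE), 0.05, label = reg)
  }
  # textured (uniform-field) FT: one-pixel rings crossing tissue-blob
  # boundaries flip under resampling, so agreement is on average
  c0 <- subject_rgf(mk(0, "uniform")); c30 <- subject_rgf(mk(30, "uniform"))
  for (reg in names(c0))
    expect_lt(mean(abs(c0[[reg]]$value - c30[[reg]]$value), na.rm = TRUE),
              0.05, label = reg)
})

test_that("coronal slices run chest wall to nipple with subset masks", {
  v <- generate_phantom(phantom_spec(seed = 3))   # 60 mm anterior extent
  ob <- preprocess_volume(v)
  sl <- coronal_slices(ob)
  expect_gte(length(sl), 57)
  expect_lte(length(sl), 63)
  # posterior end is broad, anterior (nipple) end narrow; sum over three
  # slices so interpolation slivers at the chest wall do not dominate
  n <- length(sl)
  expect_gt(sum(sapply(sl[1:3], function(s) sum(s$breast))),
            sum(sapply(sl[(n - 2):n], function(s) sum(s$breast))))
  for (s in sl) expect_true(all(s$ft[s$breast == 0] == 0))
  empty <- ob
  empty$breast_mask[] <- 0L
  expect_error(coronal_slices(empty), "empty")
})
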