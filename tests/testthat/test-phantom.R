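test_that("full and empty FT modes hit their degenerate definitions", {
  vf <- generate_phantom(small_spec(ft_mode = "full"))
  expect_identical(vf$ft_mask, vf$breast_mask)
  ve <- generate_phantom(small_spec(ft_mode = "empty"))
  expect_equal(sum(ve$ft_mask), 0)

  # downstream RGF is identically 1 (full) and 0 (empty) where defined
  obf <- preprocess_volume(vf)
  curf <- subject_rgf(obf)$middle
  expect_true(all(curf$value[!is.na(curf$value)] == 1))
  obe <- preprocess_volume(ve)
  cure <- subject_rgf(obe)$middle
  expect_true(all(cure$value[!is.na(cure$value)] == 0))
})

test_that("uniform mode realizes its FC target with a flat radial profile", {
  v <- generate_phantom(small_spec(ft_mode = "uniform", ft_fraction = 0.3,
                                   seed = 1))
  fc <- fibroglandular_composition(v)
  expect_gte(fc, 0.25)
  expect_lte(fc, 0.35)
  cur <- subject_rgf(preprocess_volume(v))$middle
  expect_lt(abs(mean(cur$value, na.rm = TRUE) - 0.3), 0.05)
})

test_that("every FT mode keeps FT inside the breast and in the grid interior", {
  for (mode in c("nonsparse", "sparse", "uniform", "annulus")) {
    v <- generate_phantom(small_spec(ft_mode = mode, nipple_offset_deg = 10,
                                     seed = 11))
    expect_true(all(v$ft_mask[v$breast_mask == 0] == 0), label = mode)
    fc <- fibroglandular_composition(v)
    if (mode %in% c("nonsparse", "sparse", "uniform"))
      expect_lt(abs(fc - 0.25), 0.05, label = mode)
  }
})

test_that("generation is deterministic under a fixed seed", {
  c1 <- generate_cohort(1, 1, small_spec(), seed = 0)
  c2 <- generate_cohort(1, 1, small_spec(), seed = 0)
  expect_identical(c1[[1]]$volume$breast_mask, c2[[1]]$volume$breast_mask)
  expect_identical(c1[[1]]$volume$ft_mask, c2[[1]]$volume$ft_mask)
  expect_identical(c1[[2]]$volume$ft_mask, c2[[2]]$volume$ft_mask)
})

test_that("cohorts have the requested sizes and labels", {
  coh <- generate_cohort(15, 8, small_spec(), seed = 7)
  expect_length(coh, 23)
  expect_equal(sum(vapply(coh, `[[`, "", "group") == "nonsparse"), 15)
  expect_equal(sum(vapply(coh, `[[`, "", "group") == "sparse"), 8)
  expect_equal(vapply(coh, `[[`, "", "id"), sprintf("S%02d", 1:23))
})

test_that("non-sparse phantoms have a strictly decreasing radial trend", {
  for (s in 1:3) {
    v <- generate_phantom(small_spec(ft_mode = "nonsparse", seed = s))
    cur <- subject_rgf(preprocess_volume(v))$middle
    ok <- !is.na(cur$value)
    expect_lt(oracle_ols_slope(cur$r[ok], cur$value[ok]), 0)
  }
})

test_that("sparse phantoms have flatter radial profiles than non-sparse", {
  sds <- sapply(1:10, function(s) {
    vs <- generate_phantom(small_spec(ft_mode = "sparse", seed = s))
    vn <- generate_phantom(small_spec(ft_mode = "nonsparse", seed = s))
    c(sd(subject_rgf(preprocess_volume(vs))$middle$value, na.rm = TRUE),
      sd(subject_rgf(preprocess_volume(vn))$middle$value, na.rm = TRUE))
  })
  expect_lt(mean(sds[1, ]), mean(sds[2, ]))
})

test_that("an oversized breast is rejected with a size error", {
  expect_error(
    generate_phantom(phantom_spec(shape = c(48L, 46L, 56L),
                                  breast_halfaxes_mm = c(60, 80, 70))),
    "exceeds the grid")
})

test_that("intensity rendering exercises both tissue levels", {
  v <- render_intensities(generate_phantom(small_spec(seed = 2)),
                          noise_sd = 0)
  expect_equal(sort(unique(v$intensities[v$breast_mask > 0])), c(-100, 40))
  expect_true(all(v$intensities[v$breast_mask == 0] == -1000))
})
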