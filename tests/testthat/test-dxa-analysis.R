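# DXA image analysis: strips, boundary detection, cross-section, sagittal
# diameter and abdominal fat recovery.

test_that("full-height strip masses match ROI queries and the exact oracle", {
  ph <- generate_phantom(phantom_config())
  strips <- strip_profile(ph$grid)
  n <- nrow(strips)
  whole <- roi_mass(ph$grid)
  expect_lte(abs(sum(strips$fat) - whole[["fat"]]), n * 0.5)
  expect_lte(abs(sum(strips$total_mass) - whole[["total"]]), 3 * n * 0.5)
  # integer-gram grid: quantization is a no-op, strip masses exact
  g <- dxa_grid(matrix(3, 5, 7), matrix(4, 5, 7))
  s <- strip_profile(g)
  expect_identical(s$fat, rep(15, 7))
  expect_identical(s$total_mass, rep(35, 7))
  # air strips beyond the ellipse
  expect_true(all(strips$is_air[1:2]))
  expect_true(all(is.na(strips$pct_fm[strips$is_air])))
})

test_that("uniform-composition phantoms have flat tissue %FM profiles", {
  ph <- generate_phantom(phantom_config(sfl_thickness = 0,
                                        visceral_fat_fraction = 0.3,
                                        sfl_fat_fraction = 0.3,
                                        roi_height = 28.8))
  strips <- strip_profile(ph$grid)
  # judge flatness on strips carrying enough mass that the 1-g reporting
  # resolution moves %FM by well under half a percentage point
  pct <- strips$pct_fm[strips$total_mass >= 200]
  expect_gt(length(pct), 10)
  expect_lt(max(pct) - min(pct), 1)
})

test_that("outer boundaries sit at the air/tissue junctions", {
  strips <- make_strips(c(0, 0, 5, 6, 5, 0), c(NA, NA, 50, 50, 50, NA))
  out <- detect_outer_boundaries(strips)
  expect_equal(out$left_x, 2 * 0.48) # junction between strips 2 and 3
  expect_equal(out$right_x, 5 * 0.48) # junction between strips 5 and 6
  expect_error(
    detect_outer_boundaries(make_strips(rep(0, 4), rep(NA, 4))),
    class = "vatmets_no_tissue_error"
  )
  w <- testthat::capture_warnings(
    all_tissue <- detect_outer_boundaries(make_strips(rep(5, 4), rep(50, 4)))
  )
  expect_length(w, 2) # one per side without an air margin
  expect_match(w, "no air margin", all = TRUE)
  expect_equal(all_tissue$left_x, 0)
  expect_equal(all_tissue$right_x, 4 * 0.48)
})

test_that("inner boundary maximizes the signed %FM drop, ties outermost", {
  pct <- c(NA, NA, 85, 82, 40, 35, 33, 33, 35, 40, 82, 85, NA, NA)
  total <- ifelse(is.na(pct), 0, 100)
  strips <- make_strips(total, pct)
  inner <- detect_inner_boundaries(strips)
  expect_equal(inner$left_x, strips$x_right[[4]]) # 82|40 junction
  expect_equal(inner$right_x, strips$x_left[[11]]) # 40|82 junction
  # two equal maximal drops: the outermost junction wins
  pct_tie <- c(NA, 80, 40, 0, 40, 80, NA) # drops of 40 at 2|3 and 3|4
  strips_tie <- make_strips(ifelse(is.na(pct_tie), 0, 100), pct_tie)
  tie <- detect_inner_boundaries(strips_tie, min_mass_frac = 0)
  expect_equal(tie$left_x, strips_tie$x_right[[2]])
  expect_error(
    detect_inner_boundaries(make_strips(c(0, 5, 6, 0), c(NA, 80, 30, NA))),
    class = "vatmets_boundary_error"
  )
})

test_that("phantom boundaries are recovered within one strip width", {
  for (cfg in list(phantom_config(),
                   phantom_config(width = 26, sagittal = 20,
                                  sfl_thickness = 2.5))) {
    ph <- generate_phantom(cfg)
    strips <- strip_profile(ph$grid)
    outer <- detect_outer_boundaries(strips)
    inner <- detect_inner_boundaries(strips, outer)
    expect_lte(abs(outer$left_x - ph$truth$outer_left_x), 0.48)
    expect_lte(abs(outer$right_x - ph$truth$outer_right_x), 0.48)
    expect_lte(abs(inner$left_x - ph$truth$inner_left_x), 0.48)
    expect_lte(abs(inner$right_x - ph$truth$inner_right_x), 0.48)
    cs <- average_cross_section(strips, ph$truth$roi_height)
    expect_lte(abs(cs$abdominal_width - cfg$width), 0.96)
    expect_lte(abs(cs$sfl_width - cfg$sfl_thickness), 0.48)
  }
})

test_that("cross-section averaging scales to a 1-cm slice", {
  ph <- generate_phantom(phantom_config())
  strips <- strip_profile(ph$grid)
  cs <- average_cross_section(strips, ph$truth$roi_height)
  # AbFM of the averaged slice close to analytic truth
  expect_lt(abs(sum(cs$strips$fat_1cm) - ph$truth$true_abfm) /
              ph$truth$true_abfm, 0.03)
  # doubling the ROI height with identical rows leaves the slice unchanged
  strips2 <- strips
  for (col in c("fat", "lean", "bone", "total_mass")) {
    strips2[[col]] <- strips[[col]] * 2
  }
  cs2 <- average_cross_section(strips2, 2 * ph$truth$roi_height)
  expect_equal(cs2$strips$fat_1cm, cs$strips$fat_1cm)
  expect_equal(cs2$sfl_width, cs$sfl_width)
  # unit ROI height: slice masses equal strip masses
  cs1 <- average_cross_section(strips, 1)
  expect_identical(cs1$strips$fat_1cm, strips$fat)
})

test_that("sagittal diameter inverts the elliptical area relation", {
  # direct evaluation: area 450 cm^2 at width 30 cm
  fake <- structure(
    list(
      strips = tibble::tibble(fat_1cm = 450 * 0.9, lean_1cm = 0, bone_1cm = 0,
                              total_1cm = 450 * 0.9,
                              x_left = 0, x_right = 0.48, is_air = FALSE),
      abdominal_width = 30
    ),
    class = "cross_section"
  )
  expect_equal(dxa_sagittal_diameter(fake), 4 * 450 / (pi * 30),
               tolerance = 1e-10)
  # circular phantom section: recovered diameter close to the true one
  ph <- generate_phantom(phantom_config(width = 20, sagittal = 20))
  strips <- strip_profile(ph$grid)
  cs <- average_cross_section(strips, ph$truth$roi_height)
  expect_lt(abs(dxa_sagittal_diameter(cs) - 20), 0.5)
  # across sagittal diameters 18-26 cm: within 5% of truth
  for (sd_true in c(18, 22, 26)) {
    ph <- generate_phantom(phantom_config(width = 32, sagittal = sd_true))
    cs <- average_cross_section(strip_profile(ph$grid), ph$truth$roi_height)
    expect_lt(abs(dxa_sagittal_diameter(cs) - sd_true) / sd_true, 0.05)
  }
})

test_that("abdominal fat variables are internally consistent", {
  ph <- generate_phantom(phantom_config())
  res <- analyze_dxa(ph, height = 1.70)
  expect_lte(abs(res$vfm + res$sfm - res$abfm), 2)
  expect_equal(res$vfm_ht2, res$vfm / 1.70^2)
  expect_equal(res$vat_sat_ratio, res$vat_a / res$sat_a)
  expect_equal(res$pct_vfm + res$pct_sfm, res$pct_abfm, tolerance = 1e-10)
  # normalization example: 150 g at 1.70 m
  expect_equal(150 / 1.7^2, 51.9, tolerance = 0.01)
})

test_that("a uniform section yields zero subcutaneous fat and flagged ratio", {
  ph <- generate_phantom(phantom_config(sfl_thickness = 0,
                                        sfl_fat_fraction = 0.3,
                                        visceral_fat_fraction = 0.3))
  res <- analyze_dxa(ph)
  expect_false(res$sfl_detected)
  expect_equal(res$sfm, 0)
  expect_equal(res$vfm, res$abfm)
  expect_equal(res$sat_a, 0)
  expect_true(is.na(res$vat_sat_ratio))
})

test_that("estimated VFM never decreases in the visceral fat fraction", {
  vfms <- vapply(c(0.2, 0.3, 0.4, 0.5), function(fv) {
    ph <- generate_phantom(phantom_config(visceral_fat_fraction = fv))
    analyze_dxa(ph)$vfm
  }, numeric(1))
  expect_true(all(diff(vfms) >= 0))
})

test_that("gram quantization error is under 5% for ROI masses over 100 g", {
  ph <- generate_phantom(phantom_config())
  strips <- strip_profile(ph$grid)
  heavy <- strips$total_mass >= 100
  exact <- vapply(which(heavy), function(j) {
    roi_mass(ph$grid, cols = j, quantize = FALSE)[["total"]]
  }, numeric(1))
  expect_true(all(abs(strips$total_mass[heavy] - exact) / exact < 0.05))
})
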