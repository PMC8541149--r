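test_that("synthesized anatomy satisfies the geometric invariants", {
  anat <- default_anatomy()
  params <- attr(anat, "params")

  expect_equal(anat$x_mm[1], -15)
  expect_equal(max(anat$x_mm), 340)
  expect_true(all(abs(diff(anat$x_mm) - 1) < 1e-12))
  # dura shell thickness is exact at every station
  expect_equal(anat$r_dura_outer_mm - anat$r_dura_inner_mm,
               rep(1, nrow(anat)))
  # radius nesting at every station
  expect_true(all(anat$r_syrinx_max_mm >= 0))
  expect_true(all(anat$r_syrinx_max_mm < anat$r_cord_mm))
  expect_true(all(anat$r_cord_mm < anat$r_dura_inner_mm))
  # smoothness: no step larger than 0.2 mm per station
  for (col in c("r_syrinx_max_mm", "r_cord_mm", "r_dura_inner_mm")) {
    expect_lt(max(abs(diff(anat[[col]]))), 0.2 + 1e-12)
  }
  # excitation mask covers exactly [205, 325]
  expect_equal(range(anat$x_mm[anat$excitation]), c(205, 325))
  # determinism: identical params give identical profiles
  expect_identical(synthesize_anatomy(anatomy_params()),
                   synthesize_anatomy(anatomy_params()))
})

test_that("cross-sectional areas are consistent and positive", {
  anat <- default_anatomy()
  areas <- cross_section_areas(make_single_syrinx(anat, 8))
  expect_true(all(areas$a_cord_m2 > 0))
  expect_true(all(areas$a_sas_m2 > 0))
  # syrinx lumen + cord annulus recompose the full cord disc
  disc <- pi * (anat$r_cord_mm * 1e-3)^2
  expect_equal(areas$a_syrinx_m2 + areas$a_cord_m2, disc,
               tolerance = 1e-12)
})

test_that("uniform anchors produce a uniform tube", {
  anat <- uniform_anatomy()
  expect_equal(unique(anat$r_cord_mm), 3)
  expect_equal(unique(anat$r_dura_inner_mm), 4.5)
  expect_equal(unique(anat$r_syrinx_max_mm), 0)
})

test_that("region classification follows the half-open convention", {
  anat <- default_anatomy()
  expect_equal(classify_region(40, anat), "C")
  expect_equal(classify_region(300, anat), "L")
  # boundaries take the caudal label
  expect_equal(classify_region(c(85, 230), anat), c("T", "L"))
  expect_error(classify_region(400, anat), "span")
})

test_that("radius tables round-trip through CSV and load_anatomy", {
  anat <- default_anatomy()
  path <- withr::local_tempfile(fileext = ".csv")
  write_anatomy_csv(anat, path)
  reloaded <- load_anatomy(read_anatomy_csv(path), attr(anat, "params"))
  expect_equal(reloaded$r_cord_mm, anat$r_cord_mm, tolerance = 1e-9)
  expect_equal(reloaded$r_syrinx_max_mm, anat$r_syrinx_max_mm,
               tolerance = 1e-9)
  expect_equal(reloaded$r_dura_inner_mm, anat$r_dura_inner_mm,
               tolerance = 1e-9)
})

test_that("load_anatomy validates nesting, coverage and gaps", {
  params <- anatomy_params()
  x <- seq(-15, 340, by = 1)
  good <- tibble::tibble(x_mm = x, r_syrinx_mm = 0, r_cord_mm = 3,
                         r_dura_inner_mm = 4.5)
  # a two-row table spanning the model gives a uniform profile
  two <- good[c(1, nrow(good)), ]
  prof <- load_anatomy(two, params)
  expect_equal(unique(prof$r_cord_mm), 3)

  bad <- good
  bad$r_syrinx_mm[bad$x_mm == 100] <- 3.5 # above the cord radius
  expect_error(load_anatomy(bad, params), "100")

  gappy <- good[good$x_mm < 50 | good$x_mm > 60, ]
  expect_error(load_anatomy(gappy, params), "gap")

  short <- good[good$x_mm >= 0, ]
  expect_error(load_anatomy(short, params), "span")
})

test_that("invalid anatomy parameters are rejected with diagnostics", {
  expect_error(anatomy_params(segment_lengths_mm = rep(10, 28)),
               "sum")
  expect_error(anatomy_params(excitation_span_mm = c(205, 400)),
               "excitation_span")
  expect_error(anatomy_params(dura_thickness_mm = -1), "positive")
  expect_error(
    anatomy_params(radius_anchors = tibble::tibble(
      x_mm = c(0, 0), r_cord_mm = c(3, 3), r_dura_inner_mm = c(4.5, 4.5)
    )),
    "increasing"
  )
  expect_error(
    anatomy_params(radius_anchors = tibble::tibble(
      x_mm = c(-15, 340), r_cord_mm = c(3, 3), r_dura_inner_mm = c(2, 4.5)
    )),
    "nesting"
  )
})
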