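test_that("calibration is an exact scale fix and is idempotent", {
  anat <- default_anatomy()
  num <- slosh_numerics_smoke()
  cal <- calibrate_gamma(band_pa = c(100, 100), anatomy = anat,
                         numerics = num)
  expect_equal(cal$achieved_pa, 100, tolerance = 1e-12)
  # doubling the band doubles gamma (pure linearity)
  cal2 <- calibrate_gamma(band_pa = c(200, 200), anatomy = anat,
                          numerics = num)
  expect_equal(cal2$gamma, 2 * cal$gamma, tolerance = 1e-12)
  # recalibration against the same run is unchanged
  cal3 <- calibrate_gamma(band_pa = c(100, 100), anatomy = anat,
                          numerics = num)
  expect_equal(cal3$gamma, cal$gamma, tolerance = 1e-12)
  expect_error(calibrate_gamma(band_pa = c(300, 100)), "ordered")
})

test_that("suite runs are deterministic and resumable", {
  anat <- default_anatomy()
  num <- slosh_numerics_smoke()
  dir <- withr::local_tempdir()
  nms <- c("baseline", "S8", "S1-3")
  s1 <- run_suite(anat, numerics = num, out_dir = dir, names = nms,
                  quiet = TRUE)
  expect_equal(nrow(s1$manifest), 3)
  expect_setequal(names(s1$profiles), nms)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "profile_S1_3.csv")))

  # determinism: a fresh in-memory run reproduces the summary exactly
  s2 <- run_suite(anat, numerics = num, names = nms, quiet = TRUE)
  expect_equal(s1$single, s2$single)
  expect_equal(s1$expanding, s2$expanding)

  # resumability: cached profiles are reused when the digest matches ...
  marker <- file.path(dir, "profile_S8.csv")
  tab <- readr::read_csv(marker, show_col_types = FALSE)
  tab$median_peak_stress_pa[1] <- 12345
  readr::write_csv(tab, marker)
  s3 <- run_suite(anat, numerics = num, out_dir = dir, names = nms,
                  quiet = TRUE)
  expect_equal(s3$profiles$S8$median_peak_stress_pa[1], 12345)
  # ... and deleting a profile forces only that run to be recomputed
  file.remove(marker)
  s4 <- run_suite(anat, numerics = num, out_dir = dir, names = nms,
                  quiet = TRUE)
  expect_equal(s4$profiles$S8$median_peak_stress_pa,
               s2$profiles$S8$median_peak_stress_pa)
  expect_error(run_suite(anat, names = "S99"), "unknown")
})

test_that("suite summaries, tidiers and plots are well-formed", {
  suite <- smoke_suite()
  expect_s3_class(suite, "slosh_suite")
  expect_equal(nrow(suite$manifest), 57)
  expect_equal(nrow(suite$single), 28)
  expect_equal(nrow(suite$expanding), 28)
  expect_true(all(c("min_percent", "median_percent", "max_percent") %in%
                    names(suite$percent_stats)))

  long <- generics::tidy(suite)
  expect_equal(dplyr::n_distinct(long$name), 57)
  gl <- generics::glance(suite)
  expect_equal(gl$n_configs, 57)

  p1 <- ggplot2::autoplot(suite$profiles$S8, baseline = suite$profiles$baseline,
                          syrinx_extent_mm = c(70, 80))
  expect_s3_class(p1, "ggplot")
  expect_s3_class(plot_sigma_bars(suite), "ggplot")
  expect_s3_class(plot_sigma_bars(suite, "delta_sigma"), "ggplot")
  expect_s3_class(plot_caudal_trajectory(suite), "ggplot")
  expect_s3_class(plot_suite_profiles(suite), "ggplot")
  expect_error(plot_suite_profiles(suite, names = "S99"), "lacks")
})

test_that("result tidiers and CSV export expose the field histories", {
  res <- smoke_run("S3")
  gl <- generics::glance(res)
  expect_equal(gl$name, "S3")
  expect_gt(gl$peak_p_s_pa, 1000)
  expect_lt(gl$audit_residual_fraction, 1e-9)

  long <- generics::tidy(res, fields = c("p_s", "u_s"), stride = 50)
  expect_setequal(unique(long$field), c("p_s", "u_s"))
  expect_true(all(is.finite(long$value)))

  p <- ggplot2::autoplot(smoke_run("S8"), x_mm = 75)
  expect_s3_class(p, "ggplot")

  path <- withr::local_tempfile(fileext = ".csv")
  write_result_csv(res, path, stride = 100)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.csv$", "_summary.csv", path)))
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_setequal(unique(back$field),
                  c("p_s", "p_f", "u_s", "u_f", "v_c", "w"))
})

test_that("parameter files round-trip through the YAML schema", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_slosh_params(path, numerics = slosh_numerics(dx_mm = 0.5,
                                                     K_a = 2e6))
  p <- read_slosh_params(path)
  expect_equal(p$numerics$dx_mm, 0.5)
  expect_equal(p$numerics$K_a, 2e6)
  expect_equal(p$materials$E_cord, 62.5e3)
  expect_equal(p$anatomy$excitation_span_mm, c(205, 325))
  expect_equal(as.data.frame(p$anatomy$radius_anchors),
               as.data.frame(default_radius_anchors()))
  # reconstructed objects re-validate: corrupt file is rejected
  doc <- yaml::read_yaml(path)
  doc$anatomy$dura_thickness_mm <- -1
  yaml::write_yaml(doc, path)
  expect_error(read_slosh_params(path), "positive")
  doc$schema <- "other/9"
  yaml::write_yaml(doc, path)
  expect_error(read_slosh_params(path), "schema")
})
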