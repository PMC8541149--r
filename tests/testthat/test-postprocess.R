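test_that("peak maps keep each element's own temporal maximum", {
  # two elements peaking at different times are both retained
  hist <- rbind(c(1, 5, 2), c(4, 1, 0))
  map <- peak_stress_map(hist, x_mm = c(0, 1))
  expect_equal(map$peak_stress_pa, c(5, 4))
  # constant-in-time field: the map is the field
  const <- matrix(3, nrow = 4, ncol = 7)
  expect_equal(peak_stress_map(const, x_mm = 0:3)$peak_stress_pa,
               rep(3, 4))
  # single time sample: identity
  one <- matrix(c(1, 2), ncol = 1)
  expect_equal(peak_stress_map(one, x_mm = 0:1)$peak_stress_pa, c(1, 2))
  expect_error(peak_stress_map(matrix(numeric(0), 2, 0), x_mm = 0:1),
               "empty")
  expect_error(peak_stress_map(matrix(c(1, NaN), 1), x_mm = 0),
               "non-finite")
})

test_that("slice medians equal a brute-force per-slice median oracle", {
  set.seed(42)
  x <- runif(50, 0, 10)
  v <- rexp(50, rate = 0.01)
  map <- peak_stress_map(tibble::tibble(x_mm = x, peak_stress_pa = v))
  prof <- slice_medians(map, width_mm = 1, span_mm = c(0, 10))
  # independent sort-based oracle over half-open slices
  for (k in 1:10) {
    inside <- x >= (k - 1) & x < k
    if (any(inside)) {
      sorted <- sort(v[inside])
      n <- length(sorted)
      oracle <- if (n %% 2 == 1) sorted[(n + 1) / 2] else
        (sorted[n / 2] + sorted[n / 2 + 1]) / 2
      expect_equal(prof$median_peak_stress_pa[k], oracle)
      expect_false(prof$filled[k])
    } else {
      expect_true(prof$filled[k])
    }
  }
  expect_equal(nrow(prof), 10)
})

test_that("slice medians handle degenerate inputs", {
  map <- peak_stress_map(tibble::tibble(x_mm = c(0.5, 1.5, 2.5),
                                        peak_stress_pa = c(1, 2, 3)))
  # one element per slice: pass-through
  prof <- slice_medians(map, width_mm = 1, span_mm = c(0, 3))
  expect_equal(prof$median_peak_stress_pa, c(1, 2, 3))
  # {1, 2, 3} in one slice: median 2
  one <- slice_medians(map, width_mm = 3, span_mm = c(0, 3))
  expect_equal(one$median_peak_stress_pa, 2)
  expect_error(slice_medians(map, width_mm = 0.5), "spacing")
})

test_that("sigma_max windows and tie-breaks behave as specified", {
  flat <- structure(tibble::tibble(x_mm = 0:20 + 0.5,
                                   median_peak_stress_pa = rep(7, 21),
                                   region = "C", filled = FALSE),
                    class = c("slosh_profile", class(tibble::tibble())))
  sm <- sigma_max(flat, extent_mm = c(5, 10), margin_mm = 5)
  expect_equal(sm$value_pa, 7)
  expect_equal(sm$x_mm, 0.5) # tie broken toward the cranial side
  spike <- flat
  spike$median_peak_stress_pa[9] <- 50
  sm2 <- sigma_max(spike, extent_mm = c(5, 10), margin_mm = 5)
  expect_equal(sm2$value_pa, 50)
  expect_equal(sm2$x_mm, 8.5)
  expect_error(sigma_max(flat, extent_mm = c(100, 110), margin_mm = 1),
               "empty")
})

test_that("delta_sigma matches a brute-force windowed difference", {
  base <- structure(tibble::tibble(x_mm = 0:30 + 0.5,
                                   median_peak_stress_pa = 100 + (0:30),
                                   region = "C", filled = FALSE),
                    class = c("slosh_profile", class(tibble::tibble())))
  same <- base
  expect_equal(delta_sigma(same, base, c(10, 20)), 0)
  up <- base
  up$median_peak_stress_pa <- up$median_peak_stress_pa + 100
  expect_equal(delta_sigma(up, base, c(10, 20)), 100)

  set.seed(7)
  noisy <- base
  noisy$median_peak_stress_pa <- base$median_peak_stress_pa +
    rnorm(31, sd = 20)
  win <- base$x_mm >= 5 & base$x_mm <= 25
  oracle <- max((noisy$median_peak_stress_pa - base$median_peak_stress_pa)[win])
  expect_equal(delta_sigma(noisy, base, c(10, 20), margin_mm = 5), oracle)

  # at-the-peak policy evaluates the difference at the sigma_max location
  sm <- sigma_max(noisy, c(10, 20), 5)
  at <- delta_sigma(noisy, base, c(10, 20), 5, policy = "at_sigma_max")
  i <- which(base$x_mm == sm$x_mm)
  expect_equal(at, noisy$median_peak_stress_pa[i] -
                 base$median_peak_stress_pa[i])

  shifted <- base
  shifted$x_mm <- shifted$x_mm + 0.25
  expect_error(delta_sigma(shifted, base, c(10, 20)), "grid")
})

test_that("percent increase is plain arithmetic with a guarded baseline", {
  expect_equal(percent_increase(100, 100), 100)
  expect_equal(percent_increase(0, 100), 0)
  expect_equal(percent_increase(54, 100), 54)
  expect_error(percent_increase(10, 0), "positive")
})

test_that("regional tables summarize a synthetic suite correctly", {
  mk <- function(vals) {
    structure(tibble::tibble(x_mm = seq(0.5, 284.5, by = 1),
                             median_peak_stress_pa = vals,
                             region = "C", filled = FALSE),
              class = c("slosh_profile", class(tibble::tibble())))
  }
  flatvals <- rep(100, 285)
  profiles <- c(list(baseline = mk(flatvals)),
                purrr::map(1:28, ~ mk(flatvals)))
  names(profiles)[-1] <- paste0("S", 1:28)
  # one spiked configuration
  spiked <- flatvals
  spiked[76] <- 300
  profiles$S8 <- mk(spiked)
  extents <- purrr::map(1:28, function(i) {
    e <- segment_extent(i)
    c(e$x_start_mm, e$x_end_mm)
  })
  names(extents) <- paste0("S", 1:28)
  tables <- regional_table(profiles, extents)
  expect_equal(nrow(tables$single), 28)
  expect_equal(sum(tables$single$delta_sigma_pa > 0), 1)
  expect_equal(tables$single$name[tables$single$delta_sigma_pa > 0], "S8")
  expect_equal(tables$single$percent_increase[tables$single$name == "S8"],
               200)
  # identical profiles give identical rows elsewhere
  others <- tables$single[tables$single$name != "S8", ]
  expect_true(all(others$sigma_max_pa == 100))
  expect_true(all(others$delta_sigma_pa == 0))
  expect_error(regional_table(profiles[-1], extents), "baseline")
  expect_error(regional_table(profiles, extents[-3]), "S3")
})
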