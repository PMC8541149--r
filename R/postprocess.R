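#' Peak-over-time stress map
#'
#' Assigns to each element (axial station in the 1-D surrogate) the
#' maximum stress it experienced over the whole simulated event,
#' regardless of when that peak occurred.  For a `slosh_result` the map
#' is built from the running maxima recorded at every integration step,
#' so it is independent of the output stride; a plain matrix of stress
#' histories (elements x times) can be supplied for testing and for
#' element maps from other discretizations.
#'
#' @param stress A `slosh_result`, or a numeric matrix (elements x
#'   times), or a tibble with columns `x_mm` and `peak_stress_pa`.
#' @param x_mm Element coordinates when `stress` is a matrix.
#' @param gamma Stress-scale override for `slosh_result` input.
#' @return A tibble of class `slosh_peakmap` with columns `x_mm`,
#'   `peak_stress_pa`.
#' @export
peak_stress_map <- function(stress, x_mm = NULL, gamma = NULL) {
  if (inherits(stress, "slosh_result")) {
    map <- stress_running_max(stress, gamma)
    attr(map, "params") <- stress$params
  } else if (is.matrix(stress)) {
    if (is.null(x_mm)) stop("x_mm required for matrix input", call. = FALSE)
    if (ncol(stress) < 1) stop("empty stress history", call. = FALSE)
    if (any(!is.finite(stress))) stop("non-finite stress values", call. = FALSE)
    map <- tibble::tibble(x_mm = x_mm,
                          peak_stress_pa = apply(stress, 1, max))
  } else {
    map <- tibble::as_tibble(stress)
    if (!all(c("x_mm", "peak_stress_pa") %in% names(map))) {
      stop("tibble input needs columns x_mm and peak_stress_pa",
           call. = FALSE)
    }
  }
  class(map) <- c("slosh_peakmap", setdiff(class(map), "slosh_peakmap"))
  map
}

#' Slice-median stress profile
#'
#' Divides the cord into transverse slices of `width_mm` (default 1 mm)
#' and takes, per slice, the median of the peak stress values of all
#' elements whose centers fall in the half-open slice interval
#' `[lo, lo + width)`.  Slices containing no element are filled by linear
#' interpolation and flagged.
#'
#' @param map A `slosh_peakmap` (or tibble with `x_mm`,
#'   `peak_stress_pa`).
#' @param width_mm Slice width; must not be smaller than the element
#'   spacing.
#' @param span_mm Model span `c(lo, hi)`; defaults to the anatomy span
#'   carried by the map, else the element range.
#' @param region_bounds_mm C/T and T/L boundaries for labeling.
#' @return A tibble of class `slosh_profile` with columns `x_mm` (slice
#'   centers), `median_peak_stress_pa`, `region`, `filled`.
#' @export
slice_medians <- function(map, width_mm = 1, span_mm = NULL,
                          region_bounds_mm = NULL) {
  params <- attr(map, "params")
  spacing <- min(diff(sort(unique(map$x_mm))))
  if (width_mm < spacing - 1e-9) {
    stop("slice width (", width_mm, " mm) is smaller than the element ",
         "spacing (", spacing, " mm)", call. = FALSE)
  }
  if (is.null(span_mm)) {
    span_mm <- if (!is.null(params)) {
      c(-params$extrusion_length_mm,
        params$total_length_mm - params$extrusion_length_mm)
    } else {
      range(map$x_mm)
    }
  }
  if (is.null(region_bounds_mm)) {
    region_bounds_mm <- if (!is.null(params)) params$region_bounds_mm else NULL
  }
  n_slice <- max(1L, round((span_mm[2] - span_mm[1]) / width_mm))
  lo <- span_mm[1] + width_mm * (seq_len(n_slice) - 1)
  centers <- lo + width_mm / 2
  idx <- floor((map$x_mm - span_mm[1]) / width_mm) + 1L
  keep <- idx >= 1L & idx <= n_slice
  med <- rep(NA_real_, n_slice)
  agg <- tapply(map$peak_stress_pa[keep], idx[keep], stats::median)
  med[as.integer(names(agg))] <- as.numeric(agg)
  filled <- is.na(med)
  if (any(filled)) {
    if (all(filled)) stop("no elements fall inside the span", call. = FALSE)
    med[filled] <- stats::approx(centers[!filled], med[!filled],
                                 xout = centers[filled], rule = 2)$y
  }
  profile <- tibble::tibble(
    x_mm = centers,
    median_peak_stress_pa = med,
    region = if (!is.null(region_bounds_mm)) {
      region_label(centers, region_bounds_mm)
    } else {
      NA_character_
    },
    filled = filled
  )
  attr(profile, "width_mm") <- width_mm
  attr(profile, "params") <- params
  class(profile) <- c("slosh_profile", class(profile))
  profile
}

#' Summary statistics of a stress profile near a syrinx
#'
#' `sigma_max()` is the peak slice-median stress in a window around the
#' syrinx extent (default margin 5 mm), with ties broken toward the
#' cranial side.  `delta_sigma()` is the stress increase over the
#' syrinx-free baseline: by default the windowed maximum of the pointwise
#' difference (`policy = "windowed_max"`); `policy = "at_sigma_max"`
#' instead evaluates the difference at the `sigma_max()` location.
#' `percent_increase()` converts an increase to a percentage of the
#' baseline value.
#'
#' @param profile,baseline A `slosh_profile` (baseline: syrinx-free).
#' @param extent_mm Syrinx extent `c(start, end)`, mm.
#' @param margin_mm Window margin around the extent.
#' @return `sigma_max()`: list with `value_pa` and `x_mm`;
#'   `delta_sigma()`: numeric (Pa, may be negative);
#'   `percent_increase()`: numeric (%).
#' @export
sigma_max <- function(profile, extent_mm, margin_mm = 5) {
  win <- profile$x_mm >= extent_mm[1] - margin_mm &
    profile$x_mm <= extent_mm[2] + margin_mm
  if (!any(win)) stop("empty sigma_max window", call. = FALSE)
  v <- profile$median_peak_stress_pa[win]
  x <- profile$x_mm[win]
  i <- which(v >= max(v) - 0)[1]
  list(value_pa = v[i], x_mm = x[i])
}

#' @rdname sigma_max
#' @param policy Windowed-max of differences (default) or difference at
#'   the `sigma_max` location.
#' @export
delta_sigma <- function(profile, baseline, extent_mm, margin_mm = 5,
                        policy = c("windowed_max", "at_sigma_max")) {
  policy <- match.arg(policy)
  if (length(profile$x_mm) != length(baseline$x_mm) ||
      any(abs(profile$x_mm - baseline$x_mm) > 1e-9)) {
    stop("profile and baseline must share the same slice grid",
         call. = FALSE)
  }
  win <- profile$x_mm >= extent_mm[1] - margin_mm &
    profile$x_mm <= extent_mm[2] + margin_mm
  if (!any(win)) stop("empty delta_sigma window", call. = FALSE)
  diffs <- profile$median_peak_stress_pa - baseline$median_peak_stress_pa
  if (policy == "windowed_max") {
    max(diffs[win])
  } else {
    sm <- sigma_max(profile, extent_mm, margin_mm)
    diffs[which.min(abs(profile$x_mm - sm$x_mm))]
  }
}

#' @rdname sigma_max
#' @param delta_pa Stress increase, Pa.
#' @param baseline_pa Baseline stress at the reference location, Pa.
#' @export
percent_increase <- function(delta_pa, baseline_pa) {
  if (any(baseline_pa <= 0)) {
    stop("baseline stress must be positive for a percent increase",
         call. = FALSE)
  }
  100 * delta_pa / baseline_pa
}

#' One-row stress summary for a configuration
#'
#' Combines [sigma_max()], [delta_sigma()] and [percent_increase()] (the
#' percentage uses the baseline value at the `sigma_max` location) with
#' the syrinx region label.
#'
#' @inheritParams sigma_max
#' @param name Configuration name.
#' @param policy Passed to [delta_sigma()].
#' @return A one-row tibble: `name`, `sigma_max_pa`, `x_at_max_mm`,
#'   `delta_sigma_pa`, `percent_increase`, `region`.
#' @export
stress_summary <- function(profile, baseline, extent_mm, name = "config",
                           margin_mm = 5,
                           policy = c("windowed_max", "at_sigma_max")) {
  sm <- sigma_max(profile, extent_mm, margin_mm)
  ds <- delta_sigma(profile, baseline, extent_mm, margin_mm, policy)
  base_at <- baseline$median_peak_stress_pa[
    which.min(abs(baseline$x_mm - sm$x_mm))]
  params <- attr(profile, "params")
  region <- if (!is.null(params)) {
    region_label(mean(extent_mm), params$region_bounds_mm)
  } else {
    NA_character_
  }
  tibble::tibble(
    name = name,
    sigma_max_pa = sm$value_pa,
    x_at_max_mm = sm$x_mm,
    delta_sigma_pa = ds,
    percent_increase = percent_increase(ds, base_at),
    region = region
  )
}

#' Regional summary tables for a full suite
#'
#' Builds the two study tables: per single-syrinx configuration
#' (`S<i>`) the `sigma_max`, `delta_sigma`, percent increase and syrinx
#' region; per expanding configuration (`S1-<j>`) the `sigma_max`
#' location and its distance from the syrinx caudal end.
#'
#' @param profiles Named list of `slosh_profile` objects containing
#'   `"baseline"` and the `S<i>` / `S1-<j>` entries.
#' @param extents Named list of syrinx extents (`c(start, end)` mm) for
#'   the non-baseline entries, e.g. from [config_extent()].
#' @param margin_mm Window margin for the summary statistics.
#' @return A list with tibbles `single` and `expanding`.
#' @export
regional_table <- function(profiles, extents, margin_mm = 5) {
  if (!"baseline" %in% names(profiles)) {
    stop("profiles must contain a 'baseline' entry", call. = FALSE)
  }
  non_base <- setdiff(names(profiles), "baseline")
  missing <- setdiff(non_base, names(extents))
  if (length(missing)) {
    stop("missing extents for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  baseline <- profiles$baseline
  single_names <- grep("^S[0-9]+$", non_base, value = TRUE)
  expand_names <- grep("^S1-[0-9]+$", non_base, value = TRUE)
  single <- purrr::map_dfr(single_names, function(nm) {
    stress_summary(profiles[[nm]], baseline, extents[[nm]], nm, margin_mm)
  })
  expanding <- purrr::map_dfr(expand_names, function(nm) {
    sm <- sigma_max(profiles[[nm]], extents[[nm]], margin_mm)
    tibble::tibble(
      name = nm,
      sigma_max_pa = sm$value_pa,
      x_at_max_mm = sm$x_mm,
      caudal_end_mm = extents[[nm]][2],
      caudal_distance_mm = extents[[nm]][2] - sm$x_mm
    )
  })
  list(single = single, expanding = expanding)
}

#' Full post-processing pipeline for one run
#'
#' Peak map (from running maxima) then 1 mm slice medians.
#'
#' @param result A `slosh_result`.
#' @param width_mm Slice width; defaults to 1 mm or the cell width,
#'   whichever is larger.
#' @return A `slosh_profile`.
#' @export
run_profile <- function(result, width_mm = NULL) {
  width_mm <- width_mm %||% max(1, result$dx_m * 1e3)
  slice_medians(peak_stress_map(result), width_mm = width_mm)
}
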