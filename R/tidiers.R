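#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation result into a long tibble
#'
#' One row per field, station and stored output time.  Pressures live at
#' cell centers, velocities and cord displacement at cell faces.
#'
#' @param x A `slosh_result`.
#' @param fields Which fields to include.
#' @param stride Keep every `stride`-th output time.
#' @param ... Unused.
#' @return A tibble with columns `field`, `x_mm`, `t_s`, `value`.
#' @method tidy slosh_result
#' @export
tidy.slosh_result <- function(x, fields = c("p_s", "p_f", "u_s", "u_f",
                                            "v_c", "w"),
                              stride = 1L, ...) {
  fields <- match.arg(fields, several.ok = TRUE)
  keep <- seq(1, length(x$t_s), by = stride)
  centers <- c(p_s = TRUE, p_f = TRUE, u_s = FALSE, u_f = FALSE,
               v_c = FALSE, w = FALSE)
  purrr::map_dfr(fields, function(f) {
    tidy_field(x[[f]], if (centers[[f]]) x$x_cent_mm else x$x_face_mm,
               x$t_s, keep, f)
  })
}

#' One-row summary of a simulation result
#'
#' @param x A `slosh_result`.
#' @param ... Unused.
#' @return A one-row tibble: configuration name, peak SAS and syrinx
#'   pressures, peak layer speeds, peak calibrated stress, the
#'   volume-audit residual fraction, and the discretization.
#' @method glance slosh_result
#' @export
glance.slosh_result <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    peak_p_s_pa = max(abs(x$p_s)),
    peak_p_f_pa = if (any(x$fluid)) max(abs(x$p_f)) else NA_real_,
    peak_u_s_m_s = max(abs(x$u_s)),
    peak_v_c_m_s = max(abs(x$v_c)),
    peak_stress_pa = max(stress_running_max(x)$peak_stress_pa),
    audit_residual_fraction = volume_audit(x)$residual_fraction,
    dx_mm = x$dx_m * 1e3,
    dt_s = x$dt_s,
    duration_s = max(x$t_s)
  )
}

#' Tidy / summarize a suite
#'
#' `tidy()` binds the per-configuration stress profiles into one long
#' tibble; `glance()` gives the headline numbers.
#'
#' @param x A `slosh_suite` from [run_suite()].
#' @param ... Unused.
#' @method tidy slosh_suite
#' @export
tidy.slosh_suite <- function(x, ...) {
  purrr::imap_dfr(x$profiles, function(p, nm) {
    dplyr::mutate(tibble::as_tibble(p), name = nm, .before = 1)
  })
}

#' @rdname tidy.slosh_suite
#' @method glance slosh_suite
#' @export
glance.slosh_suite <- function(x, ...) {
  tibble::tibble(
    n_configs = nrow(x$manifest),
    baseline_peak_pa = x$baseline_peak_pa,
    max_sigma_max_pa = if (nrow(x$single)) max(x$single$sigma_max_pa)
      else NA_real_,
    max_delta_sigma_pa = if (nrow(x$single)) max(x$single$delta_sigma_pa)
      else NA_real_,
    median_percent_increase = x$percent_stats$median_percent
  )
}

#' @export
print.slosh_suite <- function(x, ...) {
  cat("<slosh_suite> ", nrow(x$manifest), " configurations, baseline peak ",
      signif(x$baseline_peak_pa, 4), " Pa\n", sep = "")
  invisible(x)
}

#' @export
print.slosh_calibration <- function(x, ...) {
  cat("<slosh_calibration> gamma = ", signif(x$gamma, 8),
      " (baseline peak ", signif(x$achieved_pa, 4), " Pa in band [",
      x$band_pa[1], ", ", x$band_pa[2], "])\n", sep = "")
  invisible(x)
}

#' Plot a slice-median stress profile against the baseline
#'
#' Mirrors the study's profile figures: the baseline as a shaded area,
#' the configuration's profile as a line, with cervical/thoracic/lumbar
#' dividers.
#'
#' @param object A `slosh_profile`.
#' @param baseline Optional baseline `slosh_profile` for the shading.
#' @param syrinx_extent_mm Optional `c(start, end)` to mark the syrinx.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot slosh_profile
#' @export
autoplot.slosh_profile <- function(object, baseline = NULL,
                                   syrinx_extent_mm = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x_mm))
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_area(
      data = baseline,
      ggplot2::aes(y = .data$median_peak_stress_pa),
      fill = "grey80"
    )
  }
  params <- attr(object, "params")
  if (!is.null(params)) {
    p <- p + ggplot2::geom_vline(xintercept = params$region_bounds_mm,
                                 linetype = "dashed", colour = "grey40")
  }
  if (!is.null(syrinx_extent_mm)) {
    p <- p + ggplot2::annotate("segment", x = syrinx_extent_mm,
                               xend = syrinx_extent_mm, y = 0,
                               yend = 0.03 * max(object$median_peak_stress_pa),
                               linewidth = 1)
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$median_peak_stress_pa),
                       linewidth = 0.7) +
    ggplot2::labs(x = "x (mm, cranial to caudal)",
                  y = "median peak stress (Pa)")
}

#' Pressure traces at a station (input, SAS, syrinx)
#'
#' @param object A `slosh_result`.
#' @param x_mm Station at which to trace pressures.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot slosh_result
#' @export
autoplot.slosh_result <- function(object, x_mm = 75, ...) {
  i <- which.min(abs(object$x_cent_mm - x_mm))
  df <- tibble::tibble(
    t_s = rep(object$t_s, 3),
    pressure_pa = c(epidural_pressure(object$t_s, object$excitation),
                    object$p_s[i, ], object$p_f[i, ]),
    trace = rep(c("epidural input", "SAS", "syrinx"),
                each = length(object$t_s))
  )
  if (!object$fluid[i]) df <- dplyr::filter(df, .data$trace != "syrinx")
  ggplot2::ggplot(df, ggplot2::aes(.data$t_s, .data$pressure_pa,
                                   colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pressure (Pa)",
                  title = paste0("pressure traces at x = ",
                                 round(object$x_cent_mm[i], 1), " mm"))
}

#' Summary bar charts across the single-syrinx set
#'
#' Bars of `sigma_max` (or `delta_sigma`) versus syrinx position with
#' region dividers, mirroring the study's summary figure.
#'
#' @param suite A `slosh_suite`.
#' @param what `"sigma_max"` or `"delta_sigma"`.
#' @param region_bounds_mm Region dividers.
#' @return A ggplot object.
#' @export
plot_sigma_bars <- function(suite, what = c("sigma_max", "delta_sigma"),
                            region_bounds_mm = c(85, 230)) {
  what <- match.arg(what)
  df <- dplyr::mutate(suite$single,
                      i = as.integer(sub("^S", "", .data$name)),
                      mid_mm = purrr::map_dbl(.data$i, function(k) {
                        e <- segment_extent(k)
                        (e$x_start_mm + e$x_end_mm) / 2
                      }))
  col <- if (what == "sigma_max") "sigma_max_pa" else "delta_sigma_pa"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_mm, y = .data[[col]])) +
    ggplot2::geom_col(width = 8) +
    ggplot2::geom_vline(xintercept = region_bounds_mm, linetype = "dashed") +
    ggplot2::labs(x = "syrinx position (mm)", y = paste0(what, " (Pa)"))
}

#' Caudal-peak trajectory of the expanding-syrinx series
#'
#' Location of the stress peak versus the syrinx caudal end; points on
#' the identity line have their peak at the caudal end of the cavity.
#'
#' @param suite A `slosh_suite`.
#' @return A ggplot object.
#' @export
plot_caudal_trajectory <- function(suite) {
  ggplot2::ggplot(suite$expanding,
                  ggplot2::aes(.data$caudal_end_mm, .data$x_at_max_mm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "syrinx caudal end (mm)",
                  y = "location of peak stress (mm)")
}

#' Multi-panel profile figure for a set of configurations
#'
#' @param suite A `slosh_suite`.
#' @param names Configuration names, one panel each.
#' @return A ggplot object (faceted).
#' @export
plot_suite_profiles <- function(suite,
                                names = c("S1", "S8", "S15", "S25")) {
  missing <- setdiff(names, base::names(suite$profiles))
  if (length(missing)) {
    stop("suite lacks profiles for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  base <- dplyr::mutate(tibble::as_tibble(suite$profiles$baseline))
  df <- purrr::map_dfr(names, function(nm) {
    dplyr::mutate(tibble::as_tibble(suite$profiles[[nm]]), panel = nm)
  })
  df$panel <- factor(df$panel, levels = names)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm)) +
    ggplot2::geom_area(data = function(d) {
      tidyr::crossing(base, panel = factor(names, levels = names))
    }, ggplot2::aes(y = .data$median_peak_stress_pa), fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median_peak_stress_pa)) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "x (mm, cranial to caudal)",
                  y = "median peak stress (Pa)")
}
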