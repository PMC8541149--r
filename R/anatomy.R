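#' Anatomy parameters for the canine spinal-canal model
#'
#' Bundles the geometric constants and anchor tables from which a smooth
#' per-station anatomy profile is synthesized.  The axial coordinate `x`
#' runs cranio-caudally with `x = 0` at the cranial end of the syrinx
#' region; the cranial extrusion occupies `[-extrusion_length_mm, 0)`.
#'
#' Default anchors encode a cervical bulge, thoracic narrowing and a mild
#' lumbar widening of the cord, with a uniform 1.5 mm subarachnoid (SAS)
#' gap and a 1 mm dura shell.  The "MRI-like" syrinx anchors give the
#' maximum admissible syrinx radius profile used by expanding-syrinx
#' configurations.
#'
#' @param total_length_mm Full modeled length including the cranial
#'   extrusion; the caudal terminus sits at
#'   `total_length_mm - extrusion_length_mm` on the `x` axis.
#' @param extrusion_length_mm Length of the cranial extruded section.
#' @param syrinx_region_length_mm Length of the segmented syrinx region.
#' @param segment_lengths_mm Lengths of the syrinx segments (default
#'   twenty-seven 10 mm segments plus one 15 mm caudal segment).
#' @param dura_thickness_mm Dura shell thickness.
#' @param control_volume_thickness_mm Thickness of the epidural venous
#'   control volume (recorded; enters the dynamics only through the wall
#'   compliance).
#' @param excitation_span_mm Axial interval over which the epidural
#'   pressure acts.
#' @param region_bounds_mm Cervical/thoracic and thoracic/lumbar boundary
#'   coordinates (half-open intervals, caudal label at a boundary).
#' @param radius_anchors Tibble with columns `x_mm`, `r_cord_mm`,
#'   `r_dura_inner_mm`: control points for the cord and inner dura radii.
#' @param mri_like_syrinx_anchors Tibble with columns `x_mm`,
#'   `r_syrinx_mm`: control points for the maximum syrinx radius.
#' @param grid_spacing_mm Uniform station spacing.
#'
#' @return A list of class `slosh_params`.
#' @export
#' @examples
#' p <- anatomy_params()
#' sum(p$segment_lengths_mm) # 285
anatomy_params <- function(total_length_mm = 355,
                           extrusion_length_mm = 15,
                           syrinx_region_length_mm = 285,
                           segment_lengths_mm = c(rep(10, 27), 15),
                           dura_thickness_mm = 1,
                           control_volume_thickness_mm = 0.5,
                           excitation_span_mm = c(205, 325),
                           region_bounds_mm = c(85, 230),
                           radius_anchors = default_radius_anchors(),
                           mri_like_syrinx_anchors = default_syrinx_anchors(),
                           grid_spacing_mm = 1) {
  params <- list(
    total_length_mm = total_length_mm,
    extrusion_length_mm = extrusion_length_mm,
    syrinx_region_length_mm = syrinx_region_length_mm,
    segment_lengths_mm = segment_lengths_mm,
    dura_thickness_mm = dura_thickness_mm,
    control_volume_thickness_mm = control_volume_thickness_mm,
    excitation_span_mm = excitation_span_mm,
    region_bounds_mm = region_bounds_mm,
    radius_anchors = tibble::as_tibble(radius_anchors),
    mri_like_syrinx_anchors = tibble::as_tibble(mri_like_syrinx_anchors),
    grid_spacing_mm = grid_spacing_mm
  )
  class(params) <- "slosh_params"
  validate_anatomy_params(params)
  params
}

#' @rdname anatomy_params
#' @export
default_radius_anchors <- function() {
  tibble::tibble(
    x_mm = c(-15, 0, 40, 140, 250, 285, 340),
    r_cord_mm = c(3.0, 3.0, 3.15, 2.6, 2.85, 2.8, 2.0),
    r_dura_inner_mm = c(3.0, 3.0, 3.15, 2.6, 2.85, 2.8, 2.0) + 1.5
  )
}

#' @rdname anatomy_params
#' @export
default_syrinx_anchors <- function() {
  tibble::tibble(
    x_mm = c(-15, 0, 60, 140, 230, 285, 340),
    r_syrinx_mm = c(0, 1.35, 1.95, 2.0, 1.9, 1.5, 0)
  )
}

validate_anatomy_params <- function(p) {
  stopifnot(is.list(p))
  lens <- c(p$total_length_mm, p$extrusion_length_mm,
            p$syrinx_region_length_mm, p$segment_lengths_mm,
            p$dura_thickness_mm, p$control_volume_thickness_mm,
            p$grid_spacing_mm)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all lengths in anatomy_params must be strictly positive", call. = FALSE)
  }
  if (abs(sum(p$segment_lengths_mm) - p$syrinx_region_length_mm) > 1e-9) {
    stop("segment_lengths_mm must sum to syrinx_region_length_mm (",
         sum(p$segment_lengths_mm), " != ", p$syrinx_region_length_mm, ")",
         call. = FALSE)
  }
  caudal_end <- p$total_length_mm - p$extrusion_length_mm
  if (p$excitation_span_mm[1] < 0 || p$excitation_span_mm[2] > caudal_end ||
      diff(p$excitation_span_mm) <= 0) {
    stop("excitation_span_mm must be an increasing interval inside [0, ",
         caudal_end, "] mm", call. = FALSE)
  }
  if (length(p$region_bounds_mm) != 2 || diff(p$region_bounds_mm) <= 0) {
    stop("region_bounds_mm must be two increasing coordinates", call. = FALSE)
  }
  check_anchor_table(p$radius_anchors, c("x_mm", "r_cord_mm", "r_dura_inner_mm"))
  check_anchor_table(p$mri_like_syrinx_anchors, c("x_mm", "r_syrinx_mm"))
  bad <- which(p$radius_anchors$r_cord_mm >= p$radius_anchors$r_dura_inner_mm)
  if (length(bad)) {
    stop("radius anchors violate nesting (r_cord >= r_dura_inner) at x = ",
         paste(p$radius_anchors$x_mm[bad], collapse = ", "), " mm",
         call. = FALSE)
  }
  invisible(p)
}

check_anchor_table <- function(tbl, cols) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing)) {
    stop("anchor table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tbl) >= 2 && any(diff(tbl$x_mm) <= 0)) {
    i <- which(diff(tbl$x_mm) <= 0)[1]
    stop("anchor table x_mm must be strictly increasing (offending x = ",
         tbl$x_mm[i + 1], " mm)", call. = FALSE)
  }
  invisible(tbl)
}

# Shape-preserving interpolation of an anchor table onto the station grid.
# Fritsch-Carlson monotone Hermite avoids overshoot between anchors, so
# nesting that holds at the anchors holds between them too.  Constant data
# interpolates to a constant; anchor values are reproduced exactly.
interp_anchors <- function(x_anchor, y_anchor, x_out) {
  if (length(x_anchor) == 1L) return(rep(y_anchor, length(x_out)))
  if (length(x_anchor) == 2L) {
    return(stats::approx(x_anchor, y_anchor, xout = x_out, rule = 2)$y)
  }
  f <- stats::splinefun(x_anchor, y_anchor, method = "monoH.FC")
  y <- f(pmin(pmax(x_out, min(x_anchor)), max(x_anchor)))
  y
}

#' Synthesize a smooth per-station anatomy profile
#'
#' Interpolates the anchor tables of an [anatomy_params()] object onto a
#' uniform axial grid, producing per-station rest radii for the maximum
#' admissible syrinx, the cord, and the inner/outer dura, together with
#' region labels (cervical/thoracic/lumbar) and the epidural excitation
#' mask.  Stands in for MRI-derived radii when no measured table is
#' supplied; user tables go through [load_anatomy()].
#'
#' The result satisfies, at every station, the nesting
#' `0 <= r_syrinx_max < r_cord < r_dura_inner < r_dura_outer` and a
#' smoothness bound (default 0.2 mm change per station at 1 mm spacing).
#' Synthesis is deterministic: identical parameters give identical
#' profiles.
#'
#' @param params An [anatomy_params()] object.
#' @return A tibble of class `slosh_anatomy` with columns `x_mm`,
#'   `r_syrinx_max_mm`, `r_cord_mm`, `r_dura_inner_mm`, `r_dura_outer_mm`,
#'   `region`, `excitation`; the parameters are attached as attribute
#'   `params`.
#' @export
#' @examples
#' anat <- synthesize_anatomy(anatomy_params())
#' range(anat$x_mm)                      # -15 .. 340
#' unique(anat$r_dura_outer_mm - anat$r_dura_inner_mm)  # 1 mm shell
synthesize_anatomy <- function(params = anatomy_params()) {
  validate_anatomy_params(params)
  dx <- params$grid_spacing_mm
  x0 <- -params$extrusion_length_mm
  x1 <- params$total_length_mm - params$extrusion_length_mm
  x <- seq(x0, x1, by = dx)
  if (abs(x[length(x)] - x1) > 1e-9) {
    stop("grid_spacing_mm must divide the model span evenly", call. = FALSE)
  }
  ra <- params$radius_anchors
  sa <- params$mri_like_syrinx_anchors
  r_cord <- interp_anchors(ra$x_mm, ra$r_cord_mm, x)
  r_dura_inner <- interp_anchors(ra$x_mm, ra$r_dura_inner_mm, x)
  r_syrinx <- pmax(interp_anchors(sa$x_mm, sa$r_syrinx_mm, x), 0)
  profile <- new_anatomy_profile(
    x_mm = x, r_syrinx_max_mm = r_syrinx, r_cord_mm = r_cord,
    r_dura_inner_mm = r_dura_inner, params = params
  )
  validate_anatomy_profile(profile)
  profile
}

new_anatomy_profile <- function(x_mm, r_syrinx_max_mm, r_cord_mm,
                                r_dura_inner_mm, params) {
  profile <- tibble::tibble(
    x_mm = x_mm,
    r_syrinx_max_mm = r_syrinx_max_mm,
    r_cord_mm = r_cord_mm,
    r_dura_inner_mm = r_dura_inner_mm,
    r_dura_outer_mm = r_dura_inner_mm + params$dura_thickness_mm,
    region = region_label(x_mm, params$region_bounds_mm),
    excitation = x_mm >= params$excitation_span_mm[1] &
      x_mm <= params$excitation_span_mm[2]
  )
  attr(profile, "params") <- params
  class(profile) <- c("slosh_anatomy", class(profile))
  profile
}

validate_anatomy_profile <- function(profile, smoothness_mm_per_station = NULL) {
  params <- attr(profile, "params")
  dx <- params$grid_spacing_mm
  if (is.null(smoothness_mm_per_station)) {
    smoothness_mm_per_station <- 0.2 * dx
  }
  x <- profile$x_mm
  if (any(abs(diff(x) - dx) > 1e-9)) {
    stop("x_mm grid must be uniform with spacing ", dx, " mm", call. = FALSE)
  }
  bad <- which(!(profile$r_syrinx_max_mm >= 0 &
                   profile$r_syrinx_max_mm < profile$r_cord_mm &
                   profile$r_cord_mm < profile$r_dura_inner_mm &
                   profile$r_dura_inner_mm < profile$r_dura_outer_mm))
  if (length(bad)) {
    stop("radius nesting violated at x = ",
         paste(utils::head(x[bad], 5), collapse = ", "),
         if (length(bad) > 5) " mm (and more)" else " mm", call. = FALSE)
  }
  for (col in c("r_syrinx_max_mm", "r_cord_mm", "r_dura_inner_mm")) {
    step <- abs(diff(profile[[col]]))
    if (any(step > smoothness_mm_per_station + 1e-12)) {
      i <- which(step > smoothness_mm_per_station + 1e-12)[1]
      stop(col, " changes by ", signif(step[i], 3), " mm between x = ",
           x[i], " and ", x[i + 1], " mm (smoothness bound ",
           smoothness_mm_per_station, " mm)", call. = FALSE)
    }
  }
  invisible(profile)
}

region_label <- function(x, bounds) {
  dplyr::case_when(
    x < bounds[1] ~ "C",
    x < bounds[2] ~ "T",
    TRUE ~ "L"
  )
}

#' Classify an axial coordinate into cervical/thoracic/lumbar
#'
#' Uses the half-open convention: a coordinate exactly at a boundary takes
#' the caudal label.
#'
#' @param x Axial coordinate(s) in mm; must lie within the profile span.
#' @param profile A `slosh_anatomy` profile.
#' @return Character vector of labels `"C"`, `"T"`, `"L"`.
#' @export
#' @examples
#' anat <- synthesize_anatomy()
#' classify_region(c(40, 300), anat)  # "C" "L"
classify_region <- function(x, profile) {
  span <- range(profile$x_mm)
  if (any(x < span[1] | x > span[2])) {
    stop("x outside the profile span [", span[1], ", ", span[2], "] mm",
         call. = FALSE)
  }
  region_label(x, attr(profile, "params")$region_bounds_mm)
}

#' Load a user-supplied per-station radius table
#'
#' Accepts a table (e.g. MRI-derived) with columns `x_mm`, `r_syrinx_mm`,
#' `r_cord_mm`, `r_dura_inner_mm`, resamples it onto the uniform station
#' grid of `params`, and enforces the profile invariants.  A table
#' exported by [write_anatomy_csv()] round-trips to an identical profile.
#'
#' @param table Data frame of per-station radii (mm).
#' @param params An [anatomy_params()] object supplying grid and shell
#'   constants.
#' @return A `slosh_anatomy` tibble, as from [synthesize_anatomy()].
#' @export
load_anatomy <- function(table, params = anatomy_params()) {
  validate_anatomy_params(params)
  table <- tibble::as_tibble(table)
  need <- c("x_mm", "r_syrinx_mm", "r_cord_mm", "r_dura_inner_mm")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("radius table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  table <- dplyr::arrange(table, .data$x_mm)
  if (any(diff(table$x_mm) <= 0)) {
    stop("radius table x_mm must be strictly increasing", call. = FALSE)
  }
  dx <- params$grid_spacing_mm
  gaps <- diff(table$x_mm)
  if (nrow(table) > 2 && any(gaps > 2 * dx + 1e-9)) {
    i <- which(gaps > 2 * dx + 1e-9)[1]
    stop("radius table has a gap of ", signif(gaps[i], 4), " mm after x = ",
         table$x_mm[i], " mm (limit ", 2 * dx, " mm)", call. = FALSE)
  }
  x0 <- -params$extrusion_length_mm
  x1 <- params$total_length_mm - params$extrusion_length_mm
  if (min(table$x_mm) > x0 + 1e-9 || max(table$x_mm) < x1 - 1e-9) {
    stop("radius table must cover the model span [", x0, ", ", x1, "] mm",
         call. = FALSE)
  }
  bad <- which(!(table$r_syrinx_mm >= 0 &
                   table$r_syrinx_mm < table$r_cord_mm &
                   table$r_cord_mm < table$r_dura_inner_mm))
  if (length(bad)) {
    stop("radius nesting violated in table at x = ",
         paste(utils::head(table$x_mm[bad], 5), collapse = ", "), " mm",
         call. = FALSE)
  }
  x <- seq(x0, x1, by = dx)
  profile <- new_anatomy_profile(
    x_mm = x,
    r_syrinx_max_mm = pmax(interp_anchors(table$x_mm, table$r_syrinx_mm, x), 0),
    r_cord_mm = interp_anchors(table$x_mm, table$r_cord_mm, x),
    r_dura_inner_mm = interp_anchors(table$x_mm, table$r_dura_inner_mm, x),
    params = params
  )
  validate_anatomy_profile(profile)
  profile
}

#' Read / write radius tables as CSV
#'
#' The CSV schema is `x_mm,r_syrinx_mm,r_cord_mm,r_dura_inner_mm` (all mm).
#'
#' @param profile A `slosh_anatomy` profile.
#' @param path File path.
#' @return `write_anatomy_csv()` returns `path` invisibly;
#'   `read_anatomy_csv()` returns a tibble suitable for [load_anatomy()].
#' @export
write_anatomy_csv <- function(profile, path) {
  out <- tibble::tibble(
    x_mm = profile$x_mm,
    r_syrinx_mm = profile$r_syrinx_max_mm,
    r_cord_mm = profile$r_cord_mm,
    r_dura_inner_mm = profile$r_dura_inner_mm
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_anatomy_csv
#' @export
read_anatomy_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Cross-sectional rest areas of the anatomy layers
#'
#' Areas are computed from the circular radii; the syrinx area plus the
#' cord annulus area equals the full cord disc area by construction.
#'
#' @param profile A `slosh_anatomy` profile (or a configuration from
#'   [make_single_syrinx()] and friends, which carries `r_syrinx_mm`).
#' @return A tibble with `x_mm` and areas in m^2: `a_syrinx_m2`
#'   (effective syrinx lumen; zero without a syrinx), `a_cord_m2` (cord
#'   tissue annulus), `a_sas_m2`, `a_dura_m2`.
#' @export
cross_section_areas <- function(profile) {
  r_syr <- if ("r_syrinx_mm" %in% names(profile)) {
    profile$r_syrinx_mm
  } else {
    rep(0, nrow(profile))
  }
  mm2 <- 1e-6 # mm^2 -> m^2 on squared radii in mm
  tibble::tibble(
    x_mm = profile$x_mm,
    a_syrinx_m2 = pi * r_syr^2 * mm2,
    a_cord_m2 = pi * (profile$r_cord_mm^2 - r_syr^2) * mm2,
    a_sas_m2 = pi * (profile$r_dura_inner_mm^2 - profile$r_cord_mm^2) * mm2,
    a_dura_m2 = pi * (profile$r_dura_outer_mm^2 - profile$r_dura_inner_mm^2) * mm2
  )
}
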