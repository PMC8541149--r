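#' Material constants of the spinal-canal model
#'
#' Linear-elastic and fluid constants for the tissues of the canine spinal
#' canal: spinal cord, dura, epidural fat, and CSF (the syrinx fluid shares
#' the CSF properties).  Defaults are the study values: cord
#' E = 62.5 kPa, nu = 0.49; dura E = 1.25 MPa, nu = 0.4; fat E = 1 kPa,
#' nu = 0.4999, rho = 900 kg/m^3; CSF mu = 0.001 Pa s, rho = 1000 kg/m^3.
#'
#' @param E_cord,E_dura,E_fat Young's moduli, Pa.
#' @param nu_cord,nu_dura,nu_fat Poisson ratios (< 0.5).
#' @param rho_cord,rho_dura,rho_fat,rho_csf Densities, kg/m^3.
#' @param mu_csf CSF dynamic viscosity, Pa s.
#' @return A list of class `material_set`.
#' @export
material_set <- function(E_cord = 62.5e3, nu_cord = 0.49, rho_cord = 1000,
                         E_dura = 1.25e6, nu_dura = 0.4, rho_dura = 1000,
                         E_fat = 1e3, nu_fat = 0.4999, rho_fat = 900,
                         mu_csf = 0.001, rho_csf = 1000) {
  m <- list(E_cord = E_cord, nu_cord = nu_cord, rho_cord = rho_cord,
            E_dura = E_dura, nu_dura = nu_dura, rho_dura = rho_dura,
            E_fat = E_fat, nu_fat = nu_fat, rho_fat = rho_fat,
            mu_csf = mu_csf, rho_csf = rho_csf)
  if (any(!vapply(m, function(v) is.finite(v) && v > 0, logical(1)))) {
    stop("all material constants must be positive and finite", call. = FALSE)
  }
  if (any(c(nu_cord, nu_dura, nu_fat) >= 0.5)) {
    stop("Poisson ratios must be < 0.5", call. = FALSE)
  }
  class(m) <- "material_set"
  m
}

#' Epidural (Valsalva-like) pressure pulse
#'
#' The excitation is a single raised-cosine pulse,
#' `p(t) = A [1 - cos(2 pi t / T)]` for `t < T` and exactly zero
#' afterwards, continuous at `t = T`.  At the defaults (`A` = 3000 Pa,
#' `T` = 0.2 s) this is `p(t) = 3000 [1 - cos(10 pi t)]`, peaking at
#' 6000 Pa (about 45 mmHg) at `t = 0.1` s.
#'
#' @param amplitude_half_pa Half-amplitude `A`, Pa.
#' @param pulse_duration_s Pulse duration `T`, s.
#' @param span_mm Axial interval over which the pressure acts.
#' @return A list of class `excitation_spec`.
#' @export
excitation_spec <- function(amplitude_half_pa = 3000,
                            pulse_duration_s = 0.2,
                            span_mm = c(205, 325)) {
  # zero amplitude is admitted as the homogeneous (no-excitation) limit
  if (!(amplitude_half_pa >= 0)) stop("amplitude_half_pa must be >= 0",
                                      call. = FALSE)
  if (!(pulse_duration_s > 0)) stop("pulse_duration_s must be > 0",
                                    call. = FALSE)
  structure(list(amplitude_half_pa = amplitude_half_pa,
                 pulse_duration_s = pulse_duration_s,
                 span_mm = span_mm),
            class = "excitation_spec")
}

#' @rdname excitation_spec
#' @param t Time(s) since pulse onset, s (non-negative; vectorized).
#' @param spec An `excitation_spec`.
#' @return `epidural_pressure()` returns the pressure in Pa.
#' @export
#' @examples
#' epidural_pressure(c(0, 0.05, 0.1, 0.25))  # 0 3000 6000 0
epidural_pressure <- function(t, spec = excitation_spec()) {
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  A <- spec$amplitude_half_pa
  T0 <- spec$pulse_duration_s
  ifelse(t < T0, A * (1 - cos(2 * pi * t / T0)), 0)
}

#' Korteweg pulse-wave speed in a compliant fluid-filled tube
#'
#' `c = sqrt(A0 / (rho * C))` for rest area `A0` and compliance per unit
#' length `C`.  Used as the closed-form oracle for solver validation.
#'
#' @param A0 Rest cross-sectional area, m^2.
#' @param C Compliance per unit length, m^2/Pa per m.
#' @param rho Fluid density, kg/m^3.
#' @return Wave speed, m/s.
#' @export
#' @examples
#' korteweg_speed(1e-5, 1e-9, 1000)  # 100 m/s
korteweg_speed <- function(A0, C, rho) {
  if (any(c(A0, C, rho) <= 0)) {
    stop("A0, C and rho must all be positive", call. = FALSE)
  }
  sqrt(A0 / (rho * C))
}

#' Numerical options for the reduced-order solver
#'
#' @param dx_mm Cell width of the axial grid, mm.
#' @param duration_s Simulated time (the 0.2 s pulse plus follow-on).
#' @param cfl_safety CFL safety factor in (0, 1].
#' @param K_a Artificial bulk modulus, Pa, regularizing the closed,
#'   nearly incompressible fluid system.
#' @param gamma Stress-scale calibration factor; multiplies only the
#'   reported stress measure, never the dynamics (see
#'   [calibrate_gamma()]).
#' @param output_dt_s Output stride for stored field histories (running
#'   stress maxima are updated every step regardless).
#' @param taper_mm Physical width over which the syrinx area ramps to
#'   zero at each fluid/tissue interface (at least one cell wide).
#' @param wall_ramp_mm Width of the compliance ramp just inside the
#'   excitation span edges.
#' @param compliance_variant `"plane_strain"` (axially constrained cord,
#'   default) or `"plane_stress"` for the annulus tube law.
#' @param fat_thickness_mm Lumped epidural fat layer thickness used in the
#'   wall-compliance series term.
#' @return A list of class `slosh_numerics`.
#' @export
slosh_numerics <- function(dx_mm = 1, duration_s = 0.4, cfl_safety = 0.5,
                           K_a = 1e6, gamma = slosh_default_gamma(),
                           output_dt_s = 1e-3, taper_mm = 1,
                           wall_ramp_mm = 5,
                           compliance_variant = c("plane_strain",
                                                  "plane_stress"),
                           fat_thickness_mm = 1) {
  compliance_variant <- match.arg(compliance_variant)
  if (!(cfl_safety > 0 && cfl_safety <= 1)) {
    stop("cfl_safety must lie in (0, 1]", call. = FALSE)
  }
  if (K_a <= 0) stop("K_a must be positive", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  structure(list(dx_mm = dx_mm, duration_s = duration_s,
                 cfl_safety = cfl_safety, K_a = K_a, gamma = gamma,
                 output_dt_s = output_dt_s, taper_mm = taper_mm,
                 wall_ramp_mm = wall_ramp_mm,
                 compliance_variant = compliance_variant,
                 fat_thickness_mm = fat_thickness_mm),
            class = "slosh_numerics")
}

#' @rdname slosh_numerics
#' @details `slosh_numerics_smoke()` is a coarse preset (2.5 mm cells,
#'   0.25 s simulated) for quick suite runs and continuous testing.
#' @param ... Overrides passed to [slosh_numerics()].
#' @export
slosh_numerics_smoke <- function(...) {
  args <- utils::modifyList(list(dx_mm = 2.5, duration_s = 0.25), list(...))
  do.call(slosh_numerics, args)
}

# Thick-walled annulus (Lame) compliance per unit length: inner lumen of
# radius a inside a sleeve of outer radius b.  The plane-strain variant
# keeps the printed bracket form; plane stress rescales E and nu.
compliance_annulus <- function(a_m, b_m, E, nu,
                               variant = "plane_strain") {
  if (variant == "plane_stress") {
    E <- E / (1 - nu^2)
    nu <- nu / (1 - nu)
  }
  ratio <- (b_m^2 + a_m^2) / (b_m^2 - a_m^2)
  (2 * pi * a_m^2 / E) * (ratio + nu)
}

# Thin-walled tube compliance per unit length of the dura shell, in series
# with a soft (shear-dominated, nearly incompressible) epidural fat layer.
wall_compliance <- function(r_mid_m, h_dura_m, E_dura,
                            h_fat_m, E_fat) {
  c_dura <- 2 * pi * r_mid_m^3 / (E_dura * h_dura_m)
  c_fat <- 2 * pi * r_mid_m * h_fat_m / E_fat
  1 / (1 / c_dura + 1 / c_fat)
}

#' Reduced-order coefficients for a configuration
#'
#' Derives, per station, the closure coefficients of the coaxial-tube
#' model: the syrinx tube-law compliance `C_f` from the thick-walled
#' (Lame) annulus formula
#' `C_f = (2 pi a^2 / E_cord) [(b^2 + a^2)/(b^2 - a^2) + nu_cord]`
#' with `a` the syrinx and `b` the cord radius; the wall compliance `C_w`
#' from the thin-walled dura shell `2 pi r^3 / (E_dura h)` in series with
#' an epidural-fat term, nonzero only on the excitation span (the canal
#' is rigid elsewhere); and the viscous drag coefficients
#' `D_f = D_s = 8 pi mu_csf`.
#'
#' @param materials A [material_set()].
#' @param config A `slosh_config` (or bare `slosh_anatomy` for the
#'   baseline).
#' @param numerics A [slosh_numerics()] (supplies `K_a`, `gamma`, the
#'   compliance variant and the fat thickness).
#' @return A tibble of class `slosh_coeffs` with columns `x_mm`,
#'   `C_f` and `C_w` (m^2/Pa per m), and scalar attributes `D_f`, `D_s`
#'   (N s/m per m), `K_a`, `gamma`.
#' @export
derive_coefficients <- function(materials = material_set(),
                                config,
                                numerics = slosh_numerics()) {
  r_syr <- if ("r_syrinx_mm" %in% names(config)) config$r_syrinx_mm else 0 * config$x_mm
  a <- r_syr * 1e-3
  b <- config$r_cord_mm * 1e-3
  if (any(a >= b)) {
    stop("degenerate cord annulus: syrinx radius >= cord radius at x = ",
         paste(utils::head(config$x_mm[a >= b], 5), collapse = ", "), " mm",
         call. = FALSE)
  }
  C_f <- ifelse(a > 0,
                compliance_annulus(a, b, materials$E_cord, materials$nu_cord,
                                   numerics$compliance_variant),
                0)
  params <- attr(config, "params")
  r_mid <- (config$r_dura_inner_mm + params$dura_thickness_mm / 2) * 1e-3
  C_w_full <- wall_compliance(r_mid, params$dura_thickness_mm * 1e-3,
                              materials$E_dura,
                              numerics$fat_thickness_mm * 1e-3,
                              materials$E_fat)
  C_w <- C_w_full * excitation_ramp(config$x_mm, params$excitation_span_mm,
                                    numerics$wall_ramp_mm)
  out <- tibble::tibble(x_mm = config$x_mm, C_f = C_f, C_w = C_w)
  attr(out, "D_f") <- 8 * pi * materials$mu_csf
  attr(out, "D_s") <- 8 * pi * materials$mu_csf
  attr(out, "K_a") <- numerics$K_a
  attr(out, "gamma") <- numerics$gamma
  class(out) <- c("slosh_coeffs", class(out))
  out
}

# Cosine ramp from 0 at the span edges to 1 in the interior, over
# ramp_mm just inside the span; zero outside.  Keeps the wall compliance
# supported exactly on the excitation span while avoiding a one-cell step.
excitation_ramp <- function(x, span, ramp_mm) {
  s <- pmin((x - span[1]) / ramp_mm, (span[2] - x) / ramp_mm)
  s <- pmin(pmax(s, 0), 1)
  0.5 * (1 - cos(pi * s)) * (x >= span[1] & x <= span[2])
}

#' Shipped stress-scale calibration
#'
#' The default `gamma` was fixed once by [calibrate_gamma()] on the
#' baseline configuration at default resolution, targeting the midpoint
#' of the 180--360 Pa band for the peak slice-median stress.  It scales
#' only the reported stress measure, so all relative and qualitative
#' results are calibration-independent.
#'
#' @return The default `gamma` (dimensionless).
#' @export
slosh_default_gamma <- function() 1.1258312
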