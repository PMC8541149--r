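test_that("stable timestep follows CFL scaling", {
  anat <- default_anatomy()
  cfg <- make_baseline(anat)
  s1 <- assemble_system(cfg, numerics = slosh_numerics(dx_mm = 1))
  s2 <- assemble_system(cfg, numerics = slosh_numerics(dx_mm = 0.5))
  expect_equal(s2$dt_s, s1$dt_s / 2, tolerance = 1e-12)
  # at defaults the artificial acoustic speed dominates, so 4x K_a halves dt
  s4 <- assemble_system(cfg, numerics = slosh_numerics(K_a = 4e6))
  expect_equal(s4$dt_s, s1$dt_s / 2, tolerance = 1e-12)
  expect_error(stable_timestep(s1, safety = 0), "positive")
})

test_that("zero-amplitude excitation leaves all fields identically zero", {
  sys <- assemble_system(config_by_name("S8"),
                         numerics = slosh_numerics_smoke(duration_s = 0.05),
                         excitation = excitation_spec(amplitude_half_pa = 0))
  res <- run_simulation(sys)
  expect_true(all(res$p_s == 0))
  expect_true(all(res$p_f == 0))
  expect_true(all(res$u_s == 0))
  expect_true(all(res$w == 0))
  expect_true(all(res$eps_max == 0))
})

test_that("field histories are exactly linear in the excitation amplitude", {
  sys <- assemble_system(config_by_name("S8"),
                         numerics = slosh_numerics_smoke())
  r1 <- run_simulation(sys, excitation_spec(amplitude_half_pa = 3000))
  r2 <- run_simulation(sys, excitation_spec(amplitude_half_pa = 6000))
  for (f in c("p_s", "p_f", "u_s", "u_f", "v_c", "w")) {
    denom <- max(abs(r2[[f]]))
    if (denom > 0) {
      expect_lt(max(abs(r2[[f]] - 2 * r1[[f]])) / denom, 1e-6)
    }
  }
})

test_that("running stress maxima are independent of the output stride", {
  r1 <- smoke_run("S3")
  r2 <- run_simulation(assemble_system(
    config_by_name("S3"), numerics = slosh_numerics_smoke(output_dt_s = 1e-2)
  ))
  expect_identical(r1$eps_max, r2$eps_max)
})

test_that("volume is conserved to roundoff in the discrete scheme", {
  for (nm in c("baseline", "S8")) {
    audit <- volume_audit(smoke_run(nm))
    expect_gt(audit$peak_injected_m3, 0)
    expect_lt(audit$residual_fraction, 1e-9)
  }
})

test_that("syrinx fields vanish off the cavity and at its termini", {
  res <- smoke_run("S8")
  expect_true(all(res$p_f[!res$fluid, ] == 0))
  expect_true(all(res$u_f[!res$fluid_face, ] == 0))
  # closed cavity: fluid faces are strictly interior to the block
  ext <- config_extent(config_by_name("S8"))
  xf <- res$x_face_mm[res$fluid_face]
  expect_true(all(xf > ext[1] & xf < ext[2]))
})

test_that("drag exchanged between syrinx fluid and cord balances exactly", {
  res <- smoke_run("S1-3")
  # nonzero exchange has taken place ...
  expect_gt(abs(res$drag_impulse[["on_cord"]]), 0)
  # ... and the impulse the fluid loses is exactly what the cord gains
  expect_identical(res$drag_impulse[["on_fluid"]],
                   -res$drag_impulse[["on_cord"]])
  # no drag at all without a cavity
  base <- smoke_run("baseline")
  expect_identical(base$drag_impulse,
                   c(on_fluid = 0, on_cord = 0))
})

test_that("a pressure front travels at the Korteweg speed in a uniform tube", {
  anat <- uniform_anatomy()
  mat <- material_set(E_dura = 5e5, nu_cord = 0.01)
  num <- slosh_numerics(dx_mm = 0.5, duration_s = 0.08, output_dt_s = 2e-4)
  exc <- excitation_spec(amplitude_half_pa = 500, pulse_duration_s = 0.005,
                         span_mm = c(-15, 15))
  sys <- assemble_system(make_baseline(anat), mat, num, exc,
                         wall_span_mm = c(-15, 340))
  res <- run_simulation(sys)
  mid <- which.min(abs(sys$x_cent_mm - 200))
  c_pred <- korteweg_speed(sys$A_s0[mid],
                           sys$C_w[mid] + sys$A_s0[mid] / num$K_a,
                           mat$rho_csf)
  arrival <- function(x) {
    i <- which.min(abs(res$x_cent_mm - x))
    tr <- res$p_s[i, ]
    thr <- 0.1 * max(tr)
    k <- which(tr >= thr)[1]
    res$t_s[k - 1] + (thr - tr[k - 1]) / (tr[k] - tr[k - 1]) *
      (res$t_s[k] - res$t_s[k - 1])
  }
  c_meas <- 0.160 / (arrival(280) - arrival(120))
  expect_lt(abs(c_meas - c_pred) / c_pred, 0.05)
})

test_that("the solver aborts with a diagnostic when integrated unstably", {
  sys <- assemble_system(config_by_name("baseline"),
                         numerics = slosh_numerics_smoke(duration_s = 0.1))
  sys$dt_s <- sys$dt_s * 4 # past the CFL bound
  expect_error(run_simulation(sys), "instability")
})

test_that("stress accessors validate gamma and scale exactly", {
  res <- smoke_run("S3")
  m1 <- stress_running_max(res, gamma = 1)
  m2 <- stress_running_max(res, gamma = 2)
  expect_equal(m2$peak_stress_pa, 2 * m1$peak_stress_pa)
  expect_error(stress_field(res, gamma = -1), "gamma")
  # rigid translation (no strain) gives zero stress: the strain field of a
  # zero-amplitude run is identically zero
  expect_true(all(stress_field(res)[, 1] == 0)) # t = 0 column
})
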