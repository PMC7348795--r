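# Transport module: diffusivity estimation, both device solvers,
# steady-state detection, field sampling.

test_that("Stokes-Einstein diffusivity matches closed-form evaluations", {
  # VEGF-sized sphere at culture conditions; reference value 9.0e-7 cm^2/s
  d_vegf <- stokes_einstein_diffusivity(3.6, 310, 6.9e-4)
  expect_lt(abs(d_vegf - 9.0e-7) / 9.0e-7, 0.03)
  # frozen independent hand evaluation at 298 K in water (8.9e-4 Pa.s)
  expect_equal(stokes_einstein_diffusivity(3.6, 298, 8.9e-4),
               6.8125e-7, tolerance = 1e-4)
  # D proportional to 1/r: doubling the radius halves D exactly
  expect_equal(stokes_einstein_diffusivity(7.2, 310, 6.9e-4), d_vegf / 2)
  expect_error(stokes_einstein_diffusivity(-1, 310, 6.9e-4), "positive")
  expect_error(stokes_einstein_diffusivity(3.6, 0, 6.9e-4), "positive")
})

test_that("radius-mass scaling is monotone and physically plausible", {
  expect_error(radius_from_mass(0), "positive")
  mw <- c(6, 10, 20, 45)
  r <- radius_from_mass(mw)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 1 & r < 5))     # globular-protein range, nm
})

test_that("ligand specs resolve diffusivity with the right precedence", {
  expect_equal(resolve_diffusivity(egf_ligand()), 2.0e-6)
  expect_equal(resolve_diffusivity(vegf_ligand()),
               stokes_einstein_diffusivity(3.6, 310, 6.9e-4))
  mw_only <- ligand_spec("X", molecular_weight = 20)
  expect_equal(resolve_diffusivity(mw_only),
               stokes_einstein_diffusivity(radius_from_mass(20), 310, 6.9e-4))
  expect_error(ligand_spec("X"), "at least one")
})

test_that("gLL solve honours initial conditions and mass-balance equilibrium", {
  g <- gll_geometry()
  p <- solve_gll(g, vegf_ligand(), transport_params(total_time = 6))
  expect_equal(p$concentration[, 1], rep(0, length(p$positions)))
  expect_equal(p$reservoir$source[1], 100)
  expect_equal(p$reservoir$sink[1], 0)
  expect_true(all(p$concentration >= 0))

  # t -> infinity (10x the slowest compartment time constant): uniform at
  # the hand-computed mass balance C0 * V_src / (V_src + V_snk + V_ch),
  # = 0.49877 * C0 for the default square-channel geometry
  D <- resolve_diffusivity(vegf_ligand())
  tau_h <- (0.098 * 0.098 / 0.196) * g$channel_length /
    (D * g$cross_section_area) / 3600
  pinf <- solve_gll(g, vegf_ligand(),
                    transport_params(total_time = 10 * tau_h,
                                     grid_points = 60,
                                     output_times = c(0, 10 * tau_h)))
  n <- length(pinf$times)
  expect_equal(pinf$reservoir$source[n] / 100, 0.49877, tolerance = 1e-3)
  expect_equal(pinf$reservoir$sink[n] / 100, 0.49877, tolerance = 1e-3)
  expect_lt(diff(range(pinf$concentration[, n])) / 100, 1e-3)
})

test_that("early-time gLL channel profile matches the erfc solution", {
  p <- solve_gll(gll_geometry(), vegf_ligand(),
                 transport_params(total_time = 6, grid_points = 130,
                                  output_times = c(0, 3, 6)))
  D <- resolve_diffusivity(vegf_ligand())
  for (t in c(3, 6)) {
    ana <- semi_infinite_profile(p$positions, t * 3600, D, 100)
    num <- p$concentration[, p$times == t]
    mask <- ana / 100 > 0.05
    expect_lt(max(abs(num[mask] - ana[mask]) / ana[mask]), 0.02)
  }
})

test_that("profiles stay monotone in x under monotone initial data", {
  p <- solve_gll(params = transport_params(total_time = 24, grid_points = 80,
                                           output_times = c(0, 6, 12, 24)))
  for (j in seq_along(p$times))
    expect_true(all(diff(p$concentration[, j]) <= 1e-9 * 100))
  tw <- solve_transwell(params = transport_params(total_time = 6,
                                                  grid_points = 30,
                                                  output_times = c(0, 1, 6)))
  for (j in seq_along(tw$times))
    expect_true(all(diff(tw$concentration[, j]) <= 1e-9 * 100))
})

test_that("transwell dynamics match the two-compartment exponential", {
  g <- transwell_geometry()
  tw <- solve_transwell(g, vegf_ligand(),
                        transport_params(total_time = 18, grid_points = 30))
  # t = 0: step profile, ligand below only
  expect_equal(tw$reservoir$source[1], 100)
  expect_equal(tw$reservoir$sink[1], 0)
  expect_equal(tw$concentration[, 1], rep(0, 30))
  # compartment difference decays as exp(-t/tau) with
  # tau = (Vt Vb / (Vt + Vb)) * Th / (D_eff A)
  D_eff <- resolve_diffusivity(vegf_ligand()) * g$effective_porosity
  tau_ana <- (0.1 * 0.6 / 0.7) * (10e-4) / (D_eff * g$membrane_area) / 3600
  d <- tw$reservoir$source - tw$reservoir$sink
  sel <- tw$times > 0.5 & tw$times < 10
  tau_sim <- -1 / coef(lm(log(d[sel]) ~ tw$times[sel]))[[2]]
  expect_lt(abs(tau_sim - tau_ana) / tau_ana, 0.05)
  # equilibration: both compartments at the volume-weighted mean
  peq <- solve_transwell(g, vegf_ligand(),
                         transport_params(total_time = 10 * tau_ana,
                                          grid_points = 30,
                                          output_times = c(0, 10 * tau_ana)))
  v_mem <- g$effective_porosity * g$membrane_area * 10e-4
  c_eq <- 100 * 0.6 / (0.7 + v_mem)
  n <- length(peq$times)
  expect_equal(peq$reservoir$source[n], c_eq, tolerance = 1e-4)
  expect_equal(peq$reservoir$sink[n], c_eq, tolerance = 1e-4)
})

test_that("mass is conserved to integrator precision in both devices", {
  p <- solve_gll(params = transport_params(total_time = 48, grid_points = 130))
  m <- total_mass(p)
  expect_lt(max(abs(m - m[1])) / m[1], 1e-6)
  tw <- solve_transwell(params = transport_params(total_time = 18,
                                                  grid_points = 30))
  m2 <- total_mass(tw)
  expect_lt(max(abs(m2 - m2[1])) / m2[1], 1e-6)
})

test_that("fixed-concentration boundary mode holds reservoirs constant", {
  p <- solve_gll(params = transport_params(total_time = 12, grid_points = 60,
                                           boundary = "fixed"))
  expect_true(all(p$reservoir$source == 100))
  expect_true(all(p$reservoir$sink == 0))
})

test_that("halving the grid spacing changes the profile by < 1%", {
  t_out <- c(0, 6)
  p1 <- solve_gll(params = transport_params(total_time = 6,
                                            grid_points = 130,
                                            output_times = t_out))
  p2 <- solve_gll(params = transport_params(total_time = 6,
                                            grid_points = 260,
                                            output_times = t_out))
  x <- p1$positions[5:125]   # interior of the coarse grid
  fine <- vapply(x, function(z) sample_field(p2, z, 6)[["concentration"]], 1)
  expect_lt(max(abs(p1$concentration[5:125, 2] - fine)) / 100, 0.01)
})

test_that("steady_state_time detects settling per its definition", {
  prof <- analytic_decay_profile(c_inf = 50, b = 50, tau_h = 2,
                                 times_h = seq(0, 40, by = 0.05))
  # closed-form inversion of the decay law for threshold 0.05, window 4 h
  th <- 0.05; w <- 4; tau <- 2
  t_star <- tau * log(50 * ((1 - exp(-w / tau)) - th) / (th * 50))
  got <- steady_state_time(prof, threshold = th, window = w)
  expect_lt(abs(got - t_star), 0.06)   # within one grid step
  # a constant-in-time profile settles immediately
  const <- analytic_decay_profile(c_inf = 50, b = 0, tau_h = 2,
                                  times_h = seq(0, 10, by = 0.5))
  expect_equal(steady_state_time(const, 0.05, window = 2), 0)
  # threshold 0 is unattainable for a strictly evolving profile
  expect_true(is.na(steady_state_time(prof, threshold = 0, window = 4)))
  # window must fit twice in the simulated span
  expect_error(steady_state_time(prof, 0.05, window = 30), "two windows")
})

test_that("sample_field interpolates the stored grid faithfully", {
  p <- solve_gll(params = transport_params(total_time = 6, grid_points = 60,
                                           output_times = c(0, 3, 6)))
  # grid node returns the stored value exactly
  s <- sample_field(p, p$positions[10], 3)
  expect_equal(s[["concentration"]], p$concentration[10, 2])
  # midpoint of two nodes (same time column) is their mean
  mid <- (p$positions[10] + p$positions[11]) / 2
  expect_equal(sample_field(p, mid, 3)[["concentration"]],
               mean(p$concentration[10:11, 2]))
  # a linear synthetic profile has constant gradient everywhere
  lin <- analytic_decay_profile(times_h = c(0, 1, 2))
  lin$concentration <- outer(lin$positions * 10, rep(1, 3))
  for (q in c(0.15, 0.27, 0.44))
    expect_equal(sample_field(lin, q, 1)[["gradient"]], 10)
  # out-of-domain queries are rejected
  expect_error(sample_field(p, -1, 3), "position")
  expect_error(sample_field(p, p$positions[10], 99), "time")
})

test_that("geometry constructors enforce their invariants", {
  expect_error(gll_geometry(channel_length = -1), "positive")
  expect_warning(gll_geometry(reservoir_volume_source = 3,
                              reservoir_volume_sink = 3), "10%")
  expect_error(transwell_geometry(pore_density = 1e9), "porosity")
  expect_error(transport_params(grid_points = 5), ">= 20")
  g <- transwell_geometry()
  expect_equal(g$effective_porosity, 1e5 * pi * (4e-4)^2)
})
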