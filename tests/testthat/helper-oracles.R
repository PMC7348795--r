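# Independent oracles used across the suite. These deliberately take
# different computational routes than the package code they check.

# Complementary error function via the normal CDF.
erfc_ <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# Semi-infinite-medium diffusion from a constant-concentration boundary:
# C(x, t) = C0 * erfc(x / (2 sqrt(D t))), the early-time channel solution
# while the source reservoir is effectively undepleted.
semi_infinite_profile <- function(x_cm, t_s, D_cm2s, c0) {
  c0 * erfc_(x_cm / (2 * sqrt(D_cm2s * t_s)))
}

# Brute-force Kruskal-Wallis statistic: ranks by pairwise counting and the
# general tie-robust variance-ratio form
# H = (N - 1) * sum n_g (Rbar_g - Rbar)^2 / sum (r_i - Rbar)^2.
brute_force_kw <- function(values, labels) {
  N <- length(values)
  r <- vapply(values, function(v)
    sum(values < v) + (sum(values == v) + 1) / 2, 1)
  rbar <- mean(r)
  num <- 0
  for (g in unique(labels)) {
    sel <- labels == g
    num <- num + sum(sel) * (mean(r[sel]) - rbar)^2
  }
  den <- sum((r - rbar)^2)
  (N - 1) * num / den
}

# Holm step-down applied by the textbook rule (sort, multiply, running max,
# cap at 1), independent of stats::p.adjust.
holm_by_hand <- function(p) {
  o <- order(p)
  m <- length(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Mean of a Rice(nu, sigma) step length by direct quadrature of the
# density r/sigma^2 * exp(-(r^2 + nu^2)/(2 sigma^2)) * I0(r nu / sigma^2).
rice_mean_quadrature <- function(nu, sigma) {
  f <- function(r)
    r^2 / sigma^2 *
      exp(-(r^2 + nu^2) / (2 * sigma^2) + r * nu / sigma^2) *
      besselI(r * nu / sigma^2, 0, expon.scaled = TRUE)
  stats::integrate(f, 0, nu + 12 * sigma, rel.tol = 1e-10)$value
}

# Analytic two-compartment equilibration profile object: a spatially
# uniform field C(x, t) = c_inf + b * exp(-t / tau_h), wrapped as a
# concentration_profile so steady_state_time() can scan it. The matching
# closed-form settling time for threshold th and window w (hours) is
# t* = tau * log(b * ((1 - exp(-w/tau)) - th) / (th * c_inf)).
analytic_decay_profile <- function(c_inf = 50, b = 50, tau_h = 2,
                                   times_h = seq(0, 40, by = 0.05),
                                   n_x = 5) {
  C <- outer(rep(1, n_x), c_inf + b * exp(-times_h / tau_h))
  gradlab:::.new_profile("synthetic",
                         positions = seq(0.1, 0.5, length.out = n_x),
                         times_h = times_h, C = C,
                         source = C[1, ], sink = C[1, ], c0 = c_inf + b,
                         cell_volume = 1e-4, V_src = 0.1, V_snk = 0.1,
                         flux_area = 1e-3, dx = 0.1,
                         geometry = NULL, ligand = NULL, params = NULL)
}

# Rigid rotation of a trajectory about the origin plus translation.
transform_trajectory <- function(traj, angle, dx = 0, dy = 0) {
  x <- traj$x * cos(angle) - traj$y * sin(angle) + dx
  y <- traj$x * sin(angle) + traj$y * cos(angle) + dy
  trajectory(traj$cell_id, traj$times, x, y)
}

# Small deterministic trajectory cohort builder.
make_cohort <- function(pls, condition = "T", n_points = 13) {
  trajs <- lapply(seq_along(pls), function(i) {
    step <- pls[i] / (n_points - 1)
    trajectory(paste0("c", i), seq(0, by = 30, length.out = n_points),
               cumsum(c(0, rep(step, n_points - 1))), rep(0, n_points))
  })
  suppressWarnings(condition_dataset(condition, "gLL", trajectories = trajs))
}
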