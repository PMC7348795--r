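# 1-D convective-diffusion transport with well-mixed end compartments.
#
# Both devices reduce to the same problem: a slender diffusion path
# (microchannel, or the pore space of a membrane) discretised by finite
# volumes, coupled at each end to a 0-D compartment by flux continuity.
# The finite-volume flux form conserves mass by construction; the stiff
# compartment/channel time-scale contrast is handled by lsoda with a
# banded Jacobian (the state ordering source, cells, sink is tridiagonal).

# Core method-of-lines integrator. All arguments in cgs units
# (cm, s, ng/cm^3); times_s is the output grid in seconds.
.solve_line <- function(D, u, L, N, A, V_src, V_snk, C_src0, C_snk0,
                        times_s, boundary, rtol, atol) {
  dx <- L / N
  fixed <- identical(boundary, "fixed")
  rhs <- function(t, y, parms) {
    Cs <- y[1L]; Ck <- y[N + 2L]; C <- y[2:(N + 1L)]
    # interface fluxes, ng/s; upwind advection (u >= 0, toward sink)
    q <- numeric(N + 1L)
    q[1L] <- A * (-D * (C[1L] - Cs) / (dx / 2) + u * Cs)
    if (N > 1L) {
      i <- seq_len(N - 1L)
      q[i + 1L] <- A * (-D * (C[i + 1L] - C[i]) / dx + u * C[i])
    }
    q[N + 1L] <- A * (-D * (Ck - C[N]) / (dx / 2) + u * C[N])
    dC <- (q[seq_len(N)] - q[2:(N + 1L)]) / (A * dx)
    dCs <- if (fixed) 0 else -q[1L] / V_src
    dCk <- if (fixed) 0 else q[N + 1L] / V_snk
    list(c(dCs, dC, dCk))
  }
  y0 <- c(C_src0, rep(0, N), C_snk0)
  sol <- deSolve::lsoda(y = y0, times = times_s, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol,
                        jactype = "bandint", bandup = 1L, banddown = 1L,
                        maxsteps = 50000L)
  if (attr(sol, "istate")[1L] < 0)
    stop("transport solver failed to converge; refine the grid or ",
         "tighten tolerances", call. = FALSE)
  c0 <- max(C_src0, C_snk0)
  if (min(sol[, -1L]) < -1e-6 * c0)
    stop("transport solver produced negative concentrations beyond ",
         "tolerance; refine 'grid_points' or tighten 'rtol'", call. = FALSE)
  C <- t(sol[, 3:(N + 2L), drop = FALSE])        # N x n_times
  dimnames(C) <- NULL
  list(times_s = sol[, 1L],
       source = unname(sol[, 2L]),
       sink = unname(sol[, N + 3L]),
       C = C,
       dx = dx)
}

.new_profile <- function(device, positions, times_h, C, source, sink, c0,
                         cell_volume, V_src, V_snk, flux_area, dx,
                         geometry, ligand, params,
                         source_label = "source", sink_label = "sink") {
  C[C < 0 & C > -1e-6 * c0] <- 0      # clip integrator noise at zero
  structure(list(device = device,
                 positions = positions,
                 times = times_h,
                 concentration = C,
                 reservoir = data.frame(time_h = times_h,
                                        source = source, sink = sink),
                 c0 = c0,
                 cell_volume_cm3 = cell_volume,
                 source_volume_cm3 = V_src, sink_volume_cm3 = V_snk,
                 flux_area_cm2 = flux_area, dx_cm = dx,
                 source_label = source_label, sink_label = sink_label,
                 geometry = geometry, ligand = ligand, params = params),
            class = "concentration_profile")
}

#' Simulate gradient development in a two-reservoir microfluidic device
#'
#' Solves the 1-D convective-diffusion equation
#' `dC/dt + u dC/dx = D d2C/dx2` along the microchannel, with the source
#' and sink reservoirs treated as finite well-mixed compartments coupled to
#' the channel ends by flux continuity. At `t = 0` the source reservoir
#' holds the ligand at its loading concentration and the channel and sink
#' are ligand-free. Position origin is the source end of the channel, +x
#' toward the sink.
#'
#' @param geometry A [gll_geometry()].
#' @param ligand A [ligand_spec()] with resolvable diffusivity.
#' @param params A [transport_params()].
#'
#' @return A `concentration_profile`: channel concentrations (ng/mL) on a
#'   `positions` (cm) by `times` (h) grid, plus per-time reservoir
#'   concentrations in `$reservoir`.
#' @examples
#' prof <- solve_gll(gll_geometry(), vegf_ligand(),
#'                   transport_params(total_time = 48))
#' head(as.data.frame(prof))
#' @export
solve_gll <- function(geometry = gll_geometry(), ligand = vegf_ligand(),
                      params = transport_params()) {
  stopifnot(inherits(geometry, "gll_geometry"),
            inherits(ligand, "ligand_spec"),
            inherits(params, "transport_params"))
  D <- resolve_diffusivity(ligand)            # cm^2/s
  u <- params$bulk_velocity * 100             # m/s -> cm/s
  c0 <- ligand$source_concentration           # ng/mL == ng/cm^3
  N <- params$grid_points
  L <- geometry$channel_length
  A <- geometry$cross_section_area
  V_src <- geometry$reservoir_volume_source * 1e-3   # uL -> cm^3
  V_snk <- geometry$reservoir_volume_sink * 1e-3
  sol <- .solve_line(D, u, L, N, A, V_src, V_snk, c0, 0,
                     params$output_times * 3600, params$boundary,
                     params$rtol, c0 * params$atol_frac)
  .new_profile("gll",
               positions = (seq_len(N) - 0.5) * sol$dx,
               times_h = sol$times_s / 3600,
               C = sol$C, source = sol$source, sink = sol$sink, c0 = c0,
               cell_volume = A * sol$dx, V_src = V_src, V_snk = V_snk,
               flux_area = A, dx = sol$dx,
               geometry = geometry, ligand = ligand, params = params)
}

#' Simulate ligand equilibration across a transwell membrane
#'
#' Quasi-1-D diffusion through the pore space of the membrane separating
#' two well-mixed compartments. The ligand is loaded in the bottom
#' compartment (the chemoattractant side) at its source concentration; the
#' cell-seeded top compartment starts ligand-free. Transport across the
#' membrane uses the open-pore area (`effective_porosity * membrane_area`)
#' and the in-pore diffusivity `D / tortuosity`, i.e. an effective membrane
#' diffusivity `D * effective_porosity / tortuosity` over the full area.
#' Position origin is the bottom face of the membrane, +x toward the top.
#'
#' @inheritParams solve_gll
#' @param geometry A [transwell_geometry()].
#'
#' @return A `concentration_profile` across the membrane thickness;
#'   `$reservoir$source` is the bottom compartment, `$reservoir$sink` the
#'   top.
#' @export
solve_transwell <- function(geometry = transwell_geometry(),
                            ligand = vegf_ligand(),
                            params = transport_params(total_time = 18,
                                                      grid_points = 30)) {
  stopifnot(inherits(geometry, "transwell_geometry"),
            inherits(ligand, "ligand_spec"),
            inherits(params, "transport_params"))
  D <- resolve_diffusivity(ligand) / geometry$tortuosity
  u <- params$bulk_velocity * 100
  c0 <- ligand$source_concentration
  N <- params$grid_points
  L <- geometry$membrane_thickness * 1e-4      # um -> cm
  A <- geometry$effective_porosity * geometry$membrane_area  # open-pore area
  V_bot <- geometry$bottom_volume * 1e-3
  V_top <- geometry$top_volume * 1e-3
  sol <- .solve_line(D, u, L, N, A, V_bot, V_top, c0, 0,
                     params$output_times * 3600, params$boundary,
                     params$rtol, c0 * params$atol_frac)
  .new_profile("transwell",
               positions = (seq_len(N) - 0.5) * sol$dx,
               times_h = sol$times_s / 3600,
               C = sol$C, source = sol$source, sink = sol$sink, c0 = c0,
               cell_volume = A * sol$dx, V_src = V_bot, V_snk = V_top,
               flux_area = A, dx = sol$dx,
               geometry = geometry, ligand = ligand, params = params,
               source_label = "bottom", sink_label = "top")
}

#' Total ligand mass in the simulated system over time
#'
#' Sums the two compartments and the integrated channel/membrane content.
#' Under the default `"finite"` boundary this is conserved to integrator
#' tolerance; under `"fixed"` boundaries mass enters and leaves freely.
#'
#' @param profile A `concentration_profile`.
#' @return Numeric vector of total mass (ng) at each output time.
#' @export
total_mass <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  profile$source_volume_cm3 * profile$reservoir$source +
    profile$sink_volume_cm3 * profile$reservoir$sink +
    profile$cell_volume_cm3 * colSums(profile$concentration)
}

#' Time to steady state of a concentration profile
#'
#' Earliest output time at which the profile's maximum relative change over
#' the following observation window falls below `threshold` (the assay
#' convention: "steady" means concentration changes of less than 5% over
#' the window). The relative change is evaluated only at positions whose
#' normalised concentration exceeds `floor`, to avoid 0/0 amplification in
#' the still-empty far channel.
#'
#' @param profile A `concentration_profile`.
#' @param threshold Maximum tolerated relative change (fraction; default
#'   0.05).
#' @param window Observation window, h.
#' @param floor Normalised-concentration floor for inclusion (default
#'   0.01).
#'
#' @return The earliest qualifying time (h), or `NA` if the profile never
#'   settles within the simulated span.
#' @export
steady_state_time <- function(profile, threshold = 0.05, window,
                              floor = 0.01) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (!is.finite(window) || window <= 0)
    stop("steady_state_time: 'window' must be positive", call. = FALSE)
  times <- profile$times
  span <- max(times) - min(times)
  if (span < 2 * window)
    stop("steady_state_time: profile must cover at least two windows (",
         "span ", signif(span, 3), " h < 2 x ", window, " h)", call. = FALSE)
  C <- profile$concentration
  c0 <- profile$c0
  interp_col <- function(t) {
    j <- findInterval(t, times, rightmost.closed = TRUE)
    if (j >= length(times)) return(C[, length(times)])
    w <- (t - times[j]) / (times[j + 1L] - times[j])
    (1 - w) * C[, j] + w * C[, j + 1L]
  }
  for (i in seq_along(times)) {
    t0 <- times[i]
    if (t0 + window > max(times)) break
    now <- C[, i]
    later <- interp_col(t0 + window)
    # guarded relative change: below the floor the denominator saturates at
    # floor * c0, so a still-empty region that is filling up is not
    # mistaken for a settled one, while a truly constant profile passes
    rel <- max(abs(later - now) / pmax(now, floor * c0))
    if (rel < threshold) return(t0)
  }
  NA_real_
}

#' Sample concentration and spatial gradient from a profile
#'
#' Bilinear interpolation of the stored concentration field at an arbitrary
#' in-domain (position, time) query, with the spatial gradient obtained by
#' centred differences on the grid (one-sided at the ends) and interpolated
#' the same way. This is the coupling surface between the transport model
#' and the trajectory simulator.
#'
#' @param profile A `concentration_profile`.
#' @param position Position along the transport axis, cm.
#' @param time Time, h.
#'
#' @return Named numeric vector `c(concentration = ..., gradient = ...)` in
#'   ng/mL and ng/mL/cm.
#' @export
sample_field <- function(profile, position, time) {
  stopifnot(inherits(profile, "concentration_profile"))
  x <- profile$positions; tt <- profile$times; C <- profile$concentration
  if (!is.finite(position) || position < x[1L] || position > x[length(x)])
    stop("sample_field: 'position' outside the simulated domain [",
         signif(x[1L], 4), ", ", signif(x[length(x)], 4), "] cm",
         call. = FALSE)
  if (!is.finite(time) || time < tt[1L] || time > tt[length(tt)])
    stop("sample_field: 'time' outside the simulated span [",
         signif(tt[1L], 4), ", ", signif(tt[length(tt)], 4), "] h",
         call. = FALSE)
  nx <- length(x)
  # centred-difference gradient per time column
  G <- apply(C, 2L, function(col) {
    g <- numeric(nx)
    if (nx >= 3L) {
      g[2:(nx - 1L)] <- (col[3:nx] - col[1:(nx - 2L)]) / (x[3:nx] - x[1:(nx - 2L)])
    }
    g[1L] <- (col[2L] - col[1L]) / (x[2L] - x[1L])
    g[nx] <- (col[nx] - col[nx - 1L]) / (x[nx] - x[nx - 1L])
    g
  })
  bilin <- function(M) {
    i <- min(max(findInterval(position, x), 1L), nx - 1L)
    j <- min(max(findInterval(time, tt), 1L), length(tt) - 1L)
    wx <- (position - x[i]) / (x[i + 1L] - x[i])
    wt <- (time - tt[j]) / (tt[j + 1L] - tt[j])
    unname((1 - wx) * ((1 - wt) * M[i, j] + wt * M[i, j + 1L]) +
             wx * ((1 - wt) * M[i + 1L, j] + wt * M[i + 1L, j + 1L]))
  }
  c(concentration = bilin(C), gradient = bilin(G))
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat("<concentration_profile>", x$device, "device,",
      if (!is.null(x$ligand)) x$ligand$name else "ligand", "\n")
  cat("  ", length(x$positions), "cells over",
      signif(max(x$positions) + x$dx_cm / 2, 4), "cm;",
      length(x$times), "output times to", max(x$times), "h\n")
  n <- length(x$times)
  cat("  ", x$source_label, "->", x$sink_label, "at t_end:",
      signif(x$reservoir$source[n], 4), "->",
      signif(x$reservoir$sink[n], 4), "ng/mL (C0 =", x$c0, ")\n")
  invisible(x)
}

#' Long-form data frame of a concentration profile
#'
#' @param x A `concentration_profile`.
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return Data frame with `position_cm`, `time_h`, `concentration` and
#'   `normalized_concentration` columns.
#' @export
as.data.frame.concentration_profile <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  data.frame(position_cm = rep(x$positions, times = length(x$times)),
             time_h = rep(x$times, each = length(x$positions)),
             concentration = as.vector(x$concentration),
             normalized_concentration = as.vector(x$concentration) / x$c0)
}

#' @export
plot.concentration_profile <- function(x, times = NULL, ...) {
  if (is.null(times)) {
    idx <- unique(round(seq(1, length(x$times), length.out = 6)))
  } else {
    idx <- vapply(times, function(t) which.min(abs(x$times - t)), 1L)
  }
  graphics::matplot(x$positions, x$concentration[, idx, drop = FALSE] / x$c0,
                    type = "l", lty = 1, xlab = "position (cm)",
                    ylab = "C / C0", ...)
  graphics::legend("topright", legend = paste0(signif(x$times[idx], 3), " h"),
                   lty = 1, col = seq_along(idx), bty = "n", cex = 0.8)
  invisible(x)
}
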