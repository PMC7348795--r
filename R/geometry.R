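# Device geometries: two-reservoir microfluidic line (gLL) and transwell.

#' Two-reservoir microfluidic device geometry
#'
#' Describes the gLL ("glia line") class of gradient generators: two
#' well-mixed volumetric reservoirs connected by a straight microchannel.
#' Defaults are the characterised device: 98 uL reservoirs, 1.3 cm channel,
#' 192.6 um hydraulic diameter. Only the hydraulic diameter is specified by
#' the device description, so the cross-section defaults to a square of side
#' equal to it; pass `cross_section_area` for other aspect ratios.
#'
#' @param reservoir_volume_source Source reservoir volume, uL.
#' @param reservoir_volume_sink Sink reservoir volume, uL.
#' @param channel_length Channel length, cm.
#' @param hydraulic_diameter Channel hydraulic diameter, um.
#' @param cross_section_area Channel cross-section area, cm^2; default
#'   `(hydraulic_diameter)^2` (square channel).
#'
#' @return An object of class `gll_geometry`.
#' @export
gll_geometry <- function(reservoir_volume_source = 98,
                         reservoir_volume_sink = 98,
                         channel_length = 1.3,
                         hydraulic_diameter = 192.6,
                         cross_section_area = NULL) {
  vals <- c(reservoir_volume_source, reservoir_volume_sink,
            channel_length, hydraulic_diameter)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("gll_geometry: all dimensions must be positive", call. = FALSE)
  if (is.null(cross_section_area))
    cross_section_area <- (hydraulic_diameter * 1e-4)^2   # um -> cm, square
  if (!is.finite(cross_section_area) || cross_section_area <= 0)
    stop("gll_geometry: 'cross_section_area' must be positive", call. = FALSE)
  channel_volume <- cross_section_area * channel_length * 1e3  # cm^3 -> uL
  if (channel_volume > 0.1 * min(reservoir_volume_source, reservoir_volume_sink))
    warning("gll_geometry: channel volume (", signif(channel_volume, 3),
            " uL) exceeds 10% of a reservoir; the well-mixed reservoir ",
            "reduction becomes questionable", call. = FALSE)
  structure(list(reservoir_volume_source = reservoir_volume_source,
                 reservoir_volume_sink = reservoir_volume_sink,
                 channel_length = channel_length,
                 hydraulic_diameter = hydraulic_diameter,
                 cross_section_area = cross_section_area,
                 channel_volume = channel_volume),
            class = "gll_geometry")
}

#' @export
print.gll_geometry <- function(x, ...) {
  cat("<gll_geometry>\n")
  cat("  reservoirs:", x$reservoir_volume_source, "uL (source),",
      x$reservoir_volume_sink, "uL (sink)\n")
  cat("  channel:", x$channel_length, "cm x",
      signif(x$cross_section_area, 4), "cm^2 (",
      signif(x$channel_volume, 3), "uL )\n")
  invisible(x)
}

#' Transwell (Boyden chamber) geometry
#'
#' Two stacked compartments separated by a thin track-etched porous
#' membrane. Defaults follow the 6.5 mm insert format used with 8 um pore
#' polyester membranes of 10 um thickness: 100 uL upper / 600 uL lower
#' compartments and 0.33 cm^2 membrane area. The effective porosity is the
#' open-pore area fraction, `pore_density * pi * (pore_diameter/2)^2`.
#'
#' @param top_volume Upper (cell-seeded) compartment volume, uL.
#' @param bottom_volume Lower (ligand-loaded) compartment volume, uL.
#' @param membrane_thickness Membrane thickness, um.
#' @param pore_diameter Pore diameter, um.
#' @param pore_density Pores per cm^2 of membrane.
#' @param membrane_area Membrane area, cm^2.
#' @param tortuosity Pore tortuosity factor (>= 1); path-length correction
#'   applied to the in-pore diffusivity. Track-etched pores are straight,
#'   hence default 1.
#'
#' @return An object of class `transwell_geometry`.
#' @export
transwell_geometry <- function(top_volume = 100,
                               bottom_volume = 600,
                               membrane_thickness = 10,
                               pore_diameter = 8,
                               pore_density = 1e5,
                               membrane_area = 0.33,
                               tortuosity = 1) {
  vals <- c(top_volume, bottom_volume, membrane_thickness, pore_diameter,
            pore_density, membrane_area, tortuosity)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("transwell_geometry: all dimensions must be positive", call. = FALSE)
  if (tortuosity < 1)
    stop("transwell_geometry: 'tortuosity' must be >= 1", call. = FALSE)
  porosity <- pore_density * pi * (pore_diameter * 1e-4 / 2)^2  # um -> cm
  if (porosity <= 0 || porosity >= 1)
    stop("transwell_geometry: effective porosity (", signif(porosity, 3),
         ") must lie in (0, 1); check pore density/diameter", call. = FALSE)
  structure(list(top_volume = top_volume,
                 bottom_volume = bottom_volume,
                 membrane_thickness = membrane_thickness,
                 pore_diameter = pore_diameter,
                 pore_density = pore_density,
                 membrane_area = membrane_area,
                 tortuosity = tortuosity,
                 effective_porosity = porosity),
            class = "transwell_geometry")
}

#' @export
print.transwell_geometry <- function(x, ...) {
  cat("<transwell_geometry>\n")
  cat("  compartments:", x$top_volume, "uL (top) /", x$bottom_volume,
      "uL (bottom)\n")
  cat("  membrane:", x$membrane_thickness, "um thick,", x$pore_diameter,
      "um pores,", format(x$pore_density, scientific = TRUE), "/cm^2, area",
      x$membrane_area, "cm^2\n")
  cat("  effective porosity:", signif(x$effective_porosity, 4), "\n")
  invisible(x)
}

#' Transport solver parameters
#'
#' @param total_time Simulated span, h.
#' @param grid_points Number of finite-volume cells along the transport
#'   axis (>= 20).
#' @param output_times Times at which the profile is reported, h; default
#'   an even grid of 97 points over `[0, total_time]`.
#' @param bulk_velocity Imposed bulk velocity along +x, m/s. The assays are
#'   quiescent, so the default is 0; the advective term is retained for
#'   perfusion scenarios.
#' @param boundary `"finite"` (reservoirs are finite well-mixed
#'   compartments that deplete/fill, the default) or `"fixed"`
#'   (reservoir concentrations held constant).
#' @param rtol,atol_frac Relative tolerance and absolute tolerance (as a
#'   fraction of the source concentration) passed to the stiff integrator.
#'
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(total_time = 48, grid_points = 130,
                             output_times = NULL, bulk_velocity = 0,
                             boundary = c("finite", "fixed"),
                             rtol = 1e-9, atol_frac = 1e-12) {
  boundary <- match.arg(boundary)
  if (!is.finite(total_time) || total_time <= 0)
    stop("transport_params: 'total_time' must be positive", call. = FALSE)
  if (!is.finite(grid_points) || grid_points < 20)
    stop("transport_params: 'grid_points' must be >= 20", call. = FALSE)
  if (!is.finite(bulk_velocity) || bulk_velocity < 0)
    stop("transport_params: 'bulk_velocity' must be >= 0", call. = FALSE)
  if (is.null(output_times))
    output_times <- seq(0, total_time, length.out = 97)
  output_times <- sort(unique(c(0, output_times)))
  if (max(output_times) > total_time)
    stop("transport_params: 'output_times' exceed 'total_time'", call. = FALSE)
  structure(list(total_time = total_time,
                 grid_points = as.integer(grid_points),
                 output_times = output_times,
                 bulk_velocity = bulk_velocity,
                 boundary = boundary,
                 rtol = rtol, atol_frac = atol_frac),
            class = "transport_params")
}
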