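# Ligand descriptions and diffusivity estimation.

# Boltzmann constant, J/K
.kB <- 1.380649e-23

#' Ligand specification
#'
#' Describes a diffusible ligand by name, source concentration, and enough
#' physical information to resolve a diffusion coefficient: either a
#' diffusivity directly, or a hydrodynamic radius from which the
#' Stokes-Einstein relation provides one.
#'
#' @param name Character label (e.g. `"VEGF"`).
#' @param source_concentration Loading concentration in the source
#'   compartment, ng/mL.
#' @param diffusivity Diffusion coefficient in cm^2/s, or `NULL` to derive
#'   it from `hydrodynamic_radius`.
#' @param hydrodynamic_radius Hydrodynamic (Stokes) radius in nm, or `NULL`.
#' @param molecular_weight Molecular weight in kDa, optional; used only to
#'   derive a radius via [radius_from_mass()] when no radius is given.
#' @param temperature Assay temperature in K (default 310, cell-culture
#'   conditions), used for Stokes-Einstein resolution.
#' @param viscosity Medium dynamic viscosity in Pa.s (default 6.9e-4,
#'   water at 37 C).
#'
#' @return An object of class `ligand_spec`.
#' @seealso [vegf_ligand()], [egf_ligand()], [resolve_diffusivity()]
#' @export
ligand_spec <- function(name, source_concentration = 100,
                        diffusivity = NULL, hydrodynamic_radius = NULL,
                        molecular_weight = NULL,
                        temperature = 310, viscosity = 6.9e-4) {
  if (is.null(diffusivity) && is.null(hydrodynamic_radius) &&
      is.null(molecular_weight)) {
    stop("ligand_spec: provide at least one of 'diffusivity', ",
         "'hydrodynamic_radius' or 'molecular_weight'", call. = FALSE)
  }
  for (nm in c("source_concentration", "diffusivity", "hydrodynamic_radius",
               "molecular_weight", "temperature", "viscosity")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0))
      stop("ligand_spec: '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(list(name = as.character(name),
                 source_concentration = source_concentration,
                 diffusivity = diffusivity,
                 hydrodynamic_radius = hydrodynamic_radius,
                 molecular_weight = molecular_weight,
                 temperature = temperature,
                 viscosity = viscosity),
            class = "ligand_spec")
}

#' @export
print.ligand_spec <- function(x, ...) {
  cat("<ligand_spec>", x$name, "\n")
  cat("  source concentration:", x$source_concentration, "ng/mL\n")
  cat("  diffusivity:", format(resolve_diffusivity(x), digits = 3), "cm^2/s",
      if (is.null(x$diffusivity)) "(Stokes-Einstein)" else "(given)", "\n")
  invisible(x)
}

#' Stokes-Einstein diffusivity of a spherical particle
#'
#' Computes `D = kB * T / (6 * pi * eta * r)` for a sphere of hydrodynamic
#' radius `r` in a fluid of viscosity `eta`, returned in cm^2/s. This is the
#' standard estimate for globular-protein diffusivity in aqueous media.
#'
#' @param radius Hydrodynamic radius, nm.
#' @param temperature Absolute temperature, K.
#' @param viscosity Dynamic viscosity, Pa.s.
#'
#' @return Diffusivity in cm^2/s.
#' @examples
#' # VEGF-sized protein at cell-culture temperature
#' stokes_einstein_diffusivity(3.6, 310, 6.9e-4)
#' @export
stokes_einstein_diffusivity <- function(radius, temperature, viscosity) {
  if (!is.numeric(radius) || any(!is.finite(radius)) || any(radius <= 0))
    stop("stokes_einstein_diffusivity: 'radius' must be positive", call. = FALSE)
  if (!is.numeric(temperature) || any(!is.finite(temperature)) || any(temperature <= 0))
    stop("stokes_einstein_diffusivity: 'temperature' must be positive", call. = FALSE)
  if (!is.numeric(viscosity) || any(!is.finite(viscosity)) || any(viscosity <= 0))
    stop("stokes_einstein_diffusivity: 'viscosity' must be positive", call. = FALSE)
  r_m <- radius * 1e-9
  D_m2s <- .kB * temperature / (6 * pi * viscosity * r_m)
  D_m2s * 1e4                      # m^2/s -> cm^2/s
}

#' Hydrodynamic radius from molecular weight
#'
#' Globular-protein scaling law `r = a * MW^b` with `MW` in kDa and `r` in
#' nm. The default constants (`a = 0.88` nm, `b = 1/3`) follow the common
#' minimal-protein parameterisation of radius-mass scaling for compact
#' folded proteins; both are configurable for other protein classes.
#'
#' @param molecular_weight Molecular weight, kDa.
#' @param a Prefactor, nm.
#' @param b Exponent (1/3 for compact spheres of constant density).
#'
#' @return Hydrodynamic radius in nm.
#' @export
radius_from_mass <- function(molecular_weight, a = 0.88, b = 1 / 3) {
  if (!is.numeric(molecular_weight) || any(!is.finite(molecular_weight)) ||
      any(molecular_weight <= 0))
    stop("radius_from_mass: 'molecular_weight' must be positive", call. = FALSE)
  if (a <= 0 || b <= 0)
    stop("radius_from_mass: scaling constants must be positive", call. = FALSE)
  a * molecular_weight^b
}

#' Resolve the diffusion coefficient of a ligand
#'
#' Returns the ligand's diffusivity in cm^2/s, using (in order of
#' preference) the value stored in the spec, the Stokes-Einstein relation on
#' its hydrodynamic radius, or a radius derived from molecular weight.
#'
#' @param ligand A [ligand_spec()].
#' @return Diffusivity in cm^2/s.
#' @export
resolve_diffusivity <- function(ligand) {
  stopifnot(inherits(ligand, "ligand_spec"))
  if (!is.null(ligand$diffusivity)) return(ligand$diffusivity)
  r <- ligand$hydrodynamic_radius
  if (is.null(r)) r <- radius_from_mass(ligand$molecular_weight)
  stokes_einstein_diffusivity(r, ligand$temperature, ligand$viscosity)
}

#' Built-in ligand presets
#'
#' `vegf_ligand()` carries the VEGF hydrodynamic radius (3.6 nm) so its
#' diffusivity (~9.1e-7 cm^2/s at 310 K) comes from the Stokes-Einstein
#' relation; `egf_ligand()` uses the literature EGF diffusivity
#' 2.0e-6 cm^2/s directly. Both default to 100 ng/mL source loading, the
#' concentration used in the migration assays.
#'
#' @param source_concentration Source loading, ng/mL.
#' @return A [ligand_spec()].
#' @export
vegf_ligand <- function(source_concentration = 100) {
  ligand_spec("VEGF", source_concentration = source_concentration,
              hydrodynamic_radius = 3.6, molecular_weight = 38.2)
}

#' @rdname vegf_ligand
#' @export
egf_ligand <- function(source_concentration = 100) {
  ligand_spec("EGF", source_concentration = source_concentration,
              diffusivity = 2.0e-6, molecular_weight = 6.2)
}
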