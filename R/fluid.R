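#' Fluid specifications
#'
#' \code{fluidSpec} builds an arbitrary Newtonian fluid; \code{prpFluid}
#' returns the plasma / platelet-rich-plasma values (rho = 1025 kg m^-3,
#' nu = 1.1e-6 m^2 s^-1) and \code{wholeBloodFluid} the continuum
#' whole-blood values (rho = 1060 kg m^-3, nu = 3.3e-6 m^2 s^-1).
#'
#' @param rho density (kg m^-3).
#' @param nu kinematic viscosity (m^2 s^-1).
#' @return A [FluidSpec-class].
#' @examples
#' dynamicViscosity(prpFluid())   # 1.1275e-3 Pa s
#' @export
fluidSpec <- function(rho, nu) {
  assertScalarNumeric(rho, "rho", positive = TRUE)
  assertScalarNumeric(nu, "nu", positive = TRUE)
  new("FluidSpec", rho = rho, nu = nu)
}

#' @rdname fluidSpec
#' @export
prpFluid <- function() fluidSpec(rho = 1025, nu = 1.1e-6)

#' @rdname fluidSpec
#' @export
wholeBloodFluid <- function() fluidSpec(rho = 1060, nu = 3.3e-6)

#' Fluid accessors
#'
#' @param f a [FluidSpec-class].
#' @return \code{fluidDensity}: rho (kg m^-3); \code{kinematicViscosity}:
#'   nu (m^2 s^-1); \code{dynamicViscosity}: mu = rho * nu (Pa s), exact by
#'   construction.
#' @name fluid-accessors
NULL

#' @rdname fluid-accessors
#' @export
fluidDensity <- function(f) f@rho
#' @rdname fluid-accessors
#' @export
kinematicViscosity <- function(f) f@nu
#' @rdname fluid-accessors
#' @export
dynamicViscosity <- function(f) f@rho * f@nu
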