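#' Tissue constants for muscle and tendon
#'
#' Bundle of the scalar material properties used throughout MTU
#' parameterization: the maximum isometric stress developed in muscle
#' fibres, muscle tissue density, tendon Young's modulus and tendon
#' density. Defaults are the standard values for vertebrate skeletal
#' muscle and tendon.
#'
#' @param sigma Maximum isometric muscle stress (N/m^2).
#' @param rho_muscle Muscle tissue density (kg/m^3).
#' @param E_tendon Tendon Young's modulus (Pa).
#' @param rho_tendon Tendon density (kg/m^3).
#'
#' @return An object of class `tissue_constants` (a named list).
#' @examples
#' tissue_constants()
#' @export
tissue_constants <- function(sigma = 3e5, rho_muscle = 1060,
                             E_tendon = 1.2e9, rho_tendon = 1120) {
  vals <- c(sigma = sigma, rho_muscle = rho_muscle,
            E_tendon = E_tendon, rho_tendon = rho_tendon)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all tissue constants must be strictly positive and finite")
  }
  structure(as.list(vals), class = "tissue_constants")
}

#' @export
print.tissue_constants <- function(x, ...) {
  cat("Tissue constants:\n")
  cat(sprintf("  sigma      = %g N/m^2 (max muscle stress)\n", x$sigma))
  cat(sprintf("  rho_muscle = %g kg/m^3\n", x$rho_muscle))
  cat(sprintf("  E_tendon   = %g Pa\n", x$E_tendon))
  cat(sprintf("  rho_tendon = %g kg/m^3\n", x$rho_tendon))
  invisible(x)
}
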