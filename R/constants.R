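# Unit system: kJ/mol, nm, ps, K, g/mol ("MD units").

#' Physical constants in MD units
#'
#' `kB_MD` is the Boltzmann constant in kJ mol^-1 K^-1; `COULOMB_MD` is the
#' Coulomb prefactor 1/(4 pi eps0) in kJ mol^-1 nm e^-2. In this unit system
#' 1 g/mol * (nm/ps)^2 = 1 kJ/mol, so kinetic energy needs no conversion
#' factor, and 1 nm^2/ps = 1e-6 m^2/s for diffusion coefficients.
#'
#' @name constants
#' @keywords internal
NULL

kB_MD <- 0.0083144626
COULOMB_MD <- 138.935458

# real part for discrete decisions (cutoff masks, image counts) so the force
# kernels stay analytic in complex-step differentiation
.re <- function(x) if (is.complex(x)) Re(x) else x
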