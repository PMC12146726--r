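#' Create a force field parameter set
#'
#' An ordered, named, unit-tagged parameter vector with trainable flags and
#' frozen starting values (training optimises parameters divided by their
#' starting values, so trainable entries must start nonzero), together with
#' the nonbonded functional form, cutoff and reaction-field dielectric.
#'
#' Parameter naming conventions used by the force kernels:
#' \itemize{
#'  \item `sigma_<type>`, `epsilon_<type>`: pair parameters per atom type
#'    (Lennard-Jones, double-exponential, soft-core). Types with no entry get
#'    epsilon = 0 (e.g. water hydrogens).
#'  \item `buck_A_<type>`, `buck_B_<type>`, `buck_C_<type>`: Buckingham;
#'    absent types get A = C = 0.
#'  \item `de_alpha`, `de_beta`: shared double-exponential shape parameters.
#'  \item `sc_alpha`, `sc_lambda`: shared soft-core parameters (p = 2 fixed).
#'  \item `charge_<type>`: trainable charge referenced by a topology's
#'    `charge_entry`/`charge_coeff`.
#'  \item `bond_<type>_r0`, `bond_<type>_k`, `angle_<type>_theta0`,
#'    `angle_<type>_k`, `tether_k`: bonded terms.
#' }
#' Unlike pairs combine by Lorentz-Berthelot for Lennard-Jones-like forms
#' (arithmetic on sigma, geometric on epsilon) and by geometric mean on
#' energy-like / arithmetic on length-like Buckingham parameters.
#'
#' @param entries data.frame with columns name, value, unit, trainable,
#'   starting_value (starting_value defaults to value).
#' @param nonbonded_form one of "lennard_jones", "double_exponential",
#'   "buckingham", "lj_softcore".
#' @param cutoff nonbonded cutoff (nm); plain truncation, no switching.
#' @param solvent_dielectric reaction-field solvent dielectric (Inf allowed).
#' @return An object of class `force_field`.
#' @export
force_field <- function(entries, nonbonded_form = "lennard_jones", cutoff = 1,
                        solvent_dielectric = 78.5) {
  forms <- c("lennard_jones", "double_exponential", "buckingham", "lj_softcore")
  if (!nonbonded_form %in% forms)
    stop("nonbonded_form must be one of: ", paste(forms, collapse = ", "))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!"unit" %in% names(entries)) entries$unit <- ""
  if (!"trainable" %in% names(entries)) entries$trainable <- FALSE
  if (!"starting_value" %in% names(entries)) entries$starting_value <- entries$value
  need <- c("name", "value", "unit", "trainable", "starting_value")
  if (!all(need %in% names(entries))) stop("entries needs columns: ", paste(need, collapse = ", "))
  entries <- entries[, need]
  if (anyDuplicated(entries$name)) stop("duplicate parameter names")
  if (any(entries$trainable & entries$starting_value == 0))
    stop("trainable parameters must have nonzero starting values (parameter scaling)")
  structure(list(entries = entries, nonbonded_form = nonbonded_form,
                 cutoff = cutoff, solvent_dielectric = solvent_dielectric),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf("force_field: %s, cutoff %.3g nm, %d parameters (%d trainable)\n",
              x$nonbonded_form, x$cutoff, nrow(x$entries), sum(x$entries$trainable)))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Get / set force-field parameter values
#'
#' @param ff A `force_field`.
#' @param name Parameter name.
#' @param default Value returned when the entry is absent (`ff_get`).
#' @param value New value (`ff_set`).
#' @return `ff_get`: the value; `ff_set`: the modified force field;
#'   `ff_values`: named vector of all values; `trainable_names`: character
#'   vector of trainable parameter names.
#' @export
ff_get <- function(ff, name, default = NULL) {
  i <- match(name, ff$entries$name)
  if (is.na(i)) {
    if (is.null(default)) stop("no force-field parameter named ", name)
    return(default)
  }
  # complex override used by the complex-step parameter derivative
  ov <- attr(ff, "value_override")
  if (!is.null(ov) && name %in% names(ov)) return(ov[[name]])
  ff$entries$value[i]
}

#' @rdname ff_get
#' @export
ff_set <- function(ff, name, value) {
  i <- match(name, ff$entries$name)
  if (is.na(i)) stop("no force-field parameter named ", name)
  ff$entries$value[i] <- value
  ff
}

#' @rdname ff_get
#' @export
ff_values <- function(ff) stats::setNames(ff$entries$value, ff$entries$name)

#' @rdname ff_get
#' @export
trainable_names <- function(ff) ff$entries$name[ff$entries$trainable]

# perturb one parameter by a complex step without touching the entries table
.ff_perturb <- function(ff, name, h) {
  ov <- list()
  ov[[name]] <- ff_get(ff, name) + 1i * h
  attr(ff, "value_override") <- ov
  ff
}

#' TIP3P-style water force field
#'
#' Starting parameters of the 3-point water model: O partial charge -0.834 e,
#' O-H bond 0.09572 nm with force constant 462750 kJ mol^-1 nm^-2, H-O-H
#' angle 1.824 rad with force constant 836.8 kJ/mol, and oxygen Lennard-Jones
#' sigma 0.315 nm, epsilon 0.636 kJ/mol. For the alternative nonbonded forms
#' the charge and bonded parameters are retained, hydrogens carry no
#' non-charge nonbonded interaction, and the published starting shape
#' parameters are used (double-exponential alpha 16.766, beta 4.427;
#' Buckingham A 359999 kJ/mol, B 37.795 nm^-1, C 0.002343 kJ mol^-1 nm^6;
#' soft-core alpha 0.1, lambda 0.1 with p = 2).
#'
#' @param form nonbonded functional form tag.
#' @param cutoff nonbonded cutoff (nm).
#' @param trainable logical: mark the model parameters trainable.
#' @return A `force_field`.
#' @export
tip3p_force_field <- function(form = "lennard_jones", cutoff = 1, trainable = TRUE) {
  e <- list(
    list("charge_OW", -0.834, "e", trainable),
    list("bond_OH_r0", 0.09572, "nm", trainable),
    list("bond_OH_k", 462750, "kJ/mol/nm^2", trainable),
    list("angle_HOH_theta0", 1.824, "rad", trainable),
    list("angle_HOH_k", 836.8, "kJ/mol", trainable))
  nb <- switch(form,
    lennard_jones = list(list("sigma_OW", 0.315, "nm", trainable),
                         list("epsilon_OW", 0.636, "kJ/mol", trainable)),
    double_exponential = list(list("sigma_OW", 0.315, "nm", trainable),
                              list("epsilon_OW", 0.636, "kJ/mol", trainable),
                              list("de_alpha", 16.766, "", trainable),
                              list("de_beta", 4.427, "", trainable)),
    buckingham = list(list("buck_A_OW", 359999, "kJ/mol", trainable),
                      list("buck_B_OW", 37.795, "1/nm", trainable),
                      list("buck_C_OW", 0.002343, "kJ/mol nm^6", trainable)),
    lj_softcore = list(list("sigma_OW", 0.315, "nm", trainable),
                       list("epsilon_OW", 0.636, "kJ/mol", trainable),
                       list("sc_alpha", 0.1, "", trainable),
                       list("sc_lambda", 0.1, "", trainable)),
    stop("unknown form ", form))
  e <- c(e, nb)
  entries <- do.call(rbind, lapply(e, function(z)
    data.frame(name = z[[1]], value = z[[2]], unit = z[[3]], trainable = z[[4]],
               starting_value = z[[2]], stringsAsFactors = FALSE)))
  force_field(entries, nonbonded_form = form, cutoff = cutoff)
}

#' Single-type Lennard-Jones fluid force field
#'
#' @param sigma,epsilon LJ parameters (nm, kJ/mol).
#' @param cutoff nonbonded cutoff (nm).
#' @param type atom type label.
#' @param trainable logical vector or scalar for (sigma, epsilon).
#' @return A `force_field`.
#' @export
lj_fluid_force_field <- function(sigma = 0.315, epsilon = 0.636, cutoff = 0.6,
                                 type = "AR", trainable = TRUE) {
  trainable <- rep(trainable, length.out = 2)
  entries <- data.frame(
    name = paste0(c("sigma_", "epsilon_"), type),
    value = c(sigma, epsilon), unit = c("nm", "kJ/mol"),
    trainable = trainable, starting_value = c(sigma, epsilon),
    stringsAsFactors = FALSE)
  force_field(entries, "lennard_jones", cutoff = cutoff)
}

#' Add diatomic oxygen gas parameters to a water force field
#'
#' Gas oxygen Lennard-Jones sigma 0.3297 nm, epsilon 0.438 kJ/mol (trainable),
#' plus a stiff harmonic O-O bond (not trained).
#'
#' @param ff Water `force_field` (Lennard-Jones-like form).
#' @return The extended `force_field`.
#' @export
add_oxygen_gas_params <- function(ff) {
  extra <- data.frame(
    name = c("sigma_OG", "epsilon_OG", "bond_OO_r0", "bond_OO_k"),
    value = c(0.3297, 0.438, 0.121, 250000),
    unit = c("nm", "kJ/mol", "nm", "kJ/mol/nm^2"),
    trainable = c(TRUE, TRUE, FALSE, FALSE),
    starting_value = c(0.3297, 0.438, 0.121, 250000),
    stringsAsFactors = FALSE)
  force_field(rbind(ff$entries, extra), ff$nonbonded_form, ff$cutoff,
              ff$solvent_dielectric)
}
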