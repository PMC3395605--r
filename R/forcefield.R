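# Debye-Hueckel electrostatics and the full Hamiltonian evaluation.

#' Inverse Debye screening length
#'
#' For monovalent salt in water at 298 K, \eqn{\kappa = 0.329\sqrt{C}} per
#' Angstrom with the concentration C in molar.  No ions means no screening.
#'
#' @param C Salt concentration (molar), >= 0.
#' @return kappa in 1/Angstrom.
#' @export
debye_kappa <- function(C) {
  if (any(C < 0)) stop("salt concentration must be >= 0")
  0.329 * sqrt(C)
}

#' Salt-dependent Debye-Hueckel prefactor
#'
#' The finite-ion-size coefficient \eqn{B(\kappa) = e^{\kappa a}/(1+\kappa a)}
#' with ion-exclusion radius `a`; B(0) = 1 and B grows monotonically with
#' screening.
#'
#' @param kappa Inverse Debye length (1/Angstrom), >= 0.
#' @param a Ion-exclusion radius (Angstrom), default 1.425.
#' @return Dimensionless prefactor > 0.
#' @export
dh_prefactor <- function(kappa, a = 1.425) {
  exp(kappa * a) / (1 + kappa * a)
}

#' Calibrate the electric conversion factor
#'
#' Solves for the K_coulomb that makes the Debye-Hueckel energy of a +1/-1
#' pair at the reference distance and reference salt concentration equal to
#' one reduced energy unit (the scale of a native contact):
#' \deqn{K\,B(\kappa)\,e^{-\kappa r_{ref}}/(\epsilon_r r_{ref}) = 1\ \epsilon_0.}
#'
#' @param r_ref Reference separation (Angstrom), default 5.
#' @param C_ref Reference salt concentration (molar), default 0.15.
#' @param eps_r Relative dielectric, default 80.
#' @param a Ion-exclusion radius (Angstrom).
#' @return K_coulomb in eps0 * Angstrom / e^2.
#' @export
calibrate_kcoulomb <- function(r_ref = 5, C_ref = 0.15, eps_r = 80, a = 1.425) {
  kappa <- debye_kappa(C_ref)
  eps_r * r_ref * exp(kappa * r_ref) / dh_prefactor(kappa, a)
}

#' Electrostatics parameter set
#'
#' Bundles the salt concentration with the derived screening length and
#' prefactor.  If `K_coulomb` is not supplied it is set by
#' [calibrate_kcoulomb()] at its defaults (DH energy of an opposite-charge
#' pair at 5 Angstrom and 0.15 M equals one contact unit).
#'
#' @param C Salt concentration (molar).
#' @param eps_r Relative dielectric constant (80).
#' @param ion_radius_a Ion-exclusion radius (Angstrom).
#' @param K_coulomb Electric conversion factor; NA/NULL triggers calibration.
#' @param enabled Logical; FALSE turns electrostatics off entirely.
#' @return List of class `dh_params` with fields C, kappa, B, K_coulomb,
#'   eps_r, ion_radius_a, enabled.
#' @export
electrostatics_params <- function(C = 0.15, eps_r = 80, ion_radius_a = 1.425,
                                  K_coulomb = NULL, enabled = TRUE) {
  kappa <- debye_kappa(C)
  if (is.null(K_coulomb) || !is.finite(K_coulomb))
    K_coulomb <- calibrate_kcoulomb(eps_r = eps_r, a = ion_radius_a)
  structure(list(C = C, kappa = kappa, B = dh_prefactor(kappa, ion_radius_a),
                 K_coulomb = K_coulomb, eps_r = eps_r,
                 ion_radius_a = ion_radius_a, enabled = enabled),
            class = "dh_params")
}

#' Debye-Hueckel pair energy
#'
#' \eqn{V = K B q_i q_j e^{-\kappa r} / (\epsilon_r r)}; used directly for the
#' salt-bridge rescaling and exposed for diagnostics.
#'
#' @param r Separation (Angstrom).
#' @param qi,qj Charges (e).
#' @param params A `dh_params` object.
#' @return Energy in eps0.
#' @export
dh_pair_energy <- function(r, qi, qj, params) {
  params$K_coulomb * params$B * qi * qj * exp(-params$kappa * r) /
    (params$eps_r * r)
}

#' Non-bonded control parameters
#'
#' Excluded-volume and confining-wall settings for energy evaluation and
#' simulation.  The soft spherical wall (off by default for plain energy
#' calls) keeps dissociated chains re-encounterable in kinetic runs,
#' mimicking a finite concentration.
#'
#' @param ev_sigma Excluded-volume diameter (Angstrom).
#' @param ev_epsilon Excluded-volume strength (eps0); 0 disables.
#' @param wall_radius Wall radius (Angstrom); 0 disables.
#' @param wall_k Wall stiffness (eps0/Angstrom^2).
#' @return List of class `ff_control`.
#' @export
ff_control <- function(ev_sigma = 4.0, ev_epsilon = 1.0,
                       wall_radius = 0, wall_k = 0.5) {
  structure(list(ev_sigma = ev_sigma, ev_epsilon = ev_epsilon,
                 wall_radius = wall_radius, wall_k = wall_k),
            class = "ff_control")
}

# Assemble the flat term list consumed by the compiled core.
cpp_terms <- function(topology, elec, control) {
  excl <- nonbonded_exclusions(topology)
  contacts <- cbind(topology$contacts$i, topology$contacts$j,
                    topology$contacts$r_native, topology$contacts$epsilon)
  if (nrow(topology$contacts) == 0) contacts <- empty_term(4)
  dh_pref <- if (isTRUE(elec$enabled))
    elec$K_coulomb * elec$B / elec$eps_r else -1
  list(bonds = topology$bonds, angles = topology$angles,
       dihedrals = topology$dihedrals, chirality = topology$chirality,
       contacts = contacts, charges = as.numeric(topology$beads$charge),
       exclusions = if (nrow(excl) > 0) matrix(as.integer(excl), ncol = 2)
                    else matrix(integer(0), ncol = 2),
       dh_pref = dh_pref, kappa = elec$kappa,
       ev_eps = control$ev_epsilon, ev_sigma = control$ev_sigma,
       wall_k = control$wall_k, wall_r = control$wall_radius)
}

#' Total energy of a frame
#'
#' Evaluates every Hamiltonian term (bond, angle, backbone dihedral,
#' side-chain chirality, 12-10 native contact, excluded volume,
#' Debye-Hueckel electrostatics, confining wall) and their sum.
#'
#' @param frame n x 3 coordinate matrix (Angstrom).
#' @param topology A `cg_topology`.
#' @param elec A `dh_params` object; default physiological 0.15 M.
#' @param control An `ff_control` object.
#' @return An `energy_report`: named list of component energies plus `total`
#'   (all in eps0).
#' @export
total_energy <- function(frame, topology, elec = electrostatics_params(),
                         control = ff_control()) {
  frame <- as.matrix(frame)
  if (any(!is.finite(frame))) stop("frame contains non-finite coordinates")
  if (nrow(frame) != nrow(topology$beads))
    stop("frame/topology bead count mismatch")
  comp <- cpp_eval(frame, cpp_terms(topology, elec, control), FALSE)$components
  out <- as.list(comp)
  out$total <- sum(comp)
  structure(out, class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-16s %14.6f\n", nm, x[[nm]]))
  invisible(x)
}

#' Analytic forces on every bead
#'
#' Exact gradient of the same Hamiltonian as [total_energy()].
#'
#' @inheritParams total_energy
#' @return n x 3 matrix of forces (eps0/Angstrom).
#' @export
forces <- function(frame, topology, elec = electrostatics_params(),
                   control = ff_control()) {
  frame <- as.matrix(frame)
  if (any(!is.finite(frame))) stop("frame contains non-finite coordinates")
  cpp_eval(frame, cpp_terms(topology, elec, control), TRUE)$forces
}

#' Reduced temperature from a kelvin label
#'
#' The model works in reduced units (k_B = 1, energies in eps0).  Kelvin
#' temperature labels in the structure-based-model literature follow the
#' convention
#' k_B = 0.00831451 reduced-energy/K, so e.g. the kinetic label "55 K" maps to
#' kT = 0.457 eps0.
#'
#' @param kelvin Temperature label in K.
#' @return kT in eps0.
#' @export
reduced_temperature <- function(kelvin) 0.00831451 * kelvin
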