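# The coarse-grained topology container and its (de)serialization.

#' Construct a coarse-grained topology
#'
#' Low-level constructor assembling beads, bonded terms, chirality terms and
#' native contacts into a `cg_topology`.  Most users build topologies with
#' [build_topology()] (from a PDB) or the fixture generators; this constructor
#' is exposed so tiny hand-made systems (single bonds, toy coils) can be
#' simulated and tested directly.
#'
#' Index convention: all term tables reference beads by 1-based row number in
#' `beads`; the `index` column of `beads` carries the 0-based global id used in
#' the serialized schema.
#'
#' @param beads data.frame with columns `kind` ("BB"/"SC"), `residue_name`,
#'   `chain_id`, `resid`, `x`, `y`, `z`, `charge`.
#' @param bonds matrix with columns (i, j, r0, K).
#' @param angles matrix with columns (i, j, k, theta0, K).
#' @param dihedrals matrix with columns (i, j, k, l, phi0, Kd); backbone class.
#' @param chirality matrix with columns (i_prev, i, i_next, i_sc, C0, Kc).
#' @param contacts data.frame with columns `i`, `j`, `pair_kind`
#'   ("BBBB"/"SCSC"), `span` ("intra"/"inter"), `r_native`, `epsilon`,
#'   `salt_bridge`.
#' @param scale_factors named numeric: `lambda_dih_bb`, `lambda_dih_sc`,
#'   `lambda_contact` (cumulative factors applied by [balance_energies()]).
#' @param electrostatics list: `eps_r`, `K_coulomb`, `ion_radius_a`,
#'   `ref_salt_molar` (see [electrostatics_params()]).
#' @param metadata free-form list (balance bookkeeping, provenance).
#' @return An object of class `cg_topology`.
#' @export
new_topology <- function(beads,
                         bonds = empty_term(4), angles = empty_term(5),
                         dihedrals = empty_term(6), chirality = empty_term(6),
                         contacts = empty_contacts(),
                         scale_factors = c(lambda_dih_bb = 1, lambda_dih_sc = 1,
                                           lambda_contact = 1),
                         electrostatics = list(eps_r = 80, K_coulomb = NA_real_,
                                               ion_radius_a = 1.425,
                                               ref_salt_molar = 0.15),
                         metadata = list()) {
  stopifnot(is.data.frame(beads), nrow(beads) >= 1,
            all(c("kind", "residue_name", "chain_id", "resid",
                  "x", "y", "z", "charge") %in% names(beads)))
  beads$index <- seq_len(nrow(beads)) - 1L
  n <- nrow(beads)
  check_idx <- function(m, k) {
    if (nrow(m) > 0 && (any(m[, 1:k] < 1) || any(m[, 1:k] > n)))
      stop("bonded term references a non-existent bead")
  }
  check_idx(bonds, 2); check_idx(angles, 3); check_idx(dihedrals, 4)
  check_idx(chirality, 4)
  if (nrow(contacts) > 0) {
    if (any(contacts$i < 1 | contacts$i > n | contacts$j < 1 | contacts$j > n))
      stop("contact references a non-existent bead")
    if (any(contacts$pair_kind == "BBSC"))
      stop("backbone-side chain contacts are not part of the model")
    if (any(contacts$epsilon <= 0) || any(contacts$r_native <= 0))
      stop("contacts require positive epsilon and r_native")
  }
  structure(list(beads = beads, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, chirality = chirality,
                 contacts = contacts, scale_factors = scale_factors,
                 electrostatics = electrostatics, metadata = metadata),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("cg_topology:", nrow(x$beads), "beads (",
      sum(x$beads$kind == "BB"), "BB /", sum(x$beads$kind == "SC"), "SC ),",
      length(unique(x$beads$chain_id)), "chain(s)\n")
  cat("  bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " dihedrals:", nrow(x$dihedrals), " chirality:", nrow(x$chirality), "\n")
  cat("  native contacts:", nrow(x$contacts),
      "(", sum(x$contacts$span == "inter"), "inter-chain,",
      sum(x$contacts$salt_bridge), "salt bridges )\n")
  cat("  net charge:", sum(x$beads$charge), "e\n")
  invisible(x)
}

empty_term <- function(k) matrix(numeric(0), ncol = k, nrow = 0)

empty_contacts <- function() {
  data.frame(i = integer(0), j = integer(0), pair_kind = character(0),
             span = character(0), r_native = numeric(0), epsilon = numeric(0),
             salt_bridge = logical(0), dh_comp = numeric(0))
}

#' Native coordinates of a topology
#'
#' @param topology A `cg_topology`.
#' @return Numeric n x 3 matrix of bead coordinates (Angstrom).
#' @export
topology_xyz <- function(topology) {
  as.matrix(topology$beads[, c("x", "y", "z")])
}

#' Non-bonded exclusion pairs
#'
#' Pairs sharing a bond or an angle are excluded from native contacts,
#' excluded volume and Debye-Hueckel electrostatics.
#'
#' @param topology A `cg_topology`.
#' @return Two-column integer matrix of 1-based bead pairs.
#' @export
nonbonded_exclusions <- function(topology) {
  p <- rbind(
    if (nrow(topology$bonds) > 0) topology$bonds[, 1:2, drop = FALSE],
    if (nrow(topology$angles) > 0) topology$angles[, c(1, 2), drop = FALSE],
    if (nrow(topology$angles) > 0) topology$angles[, c(2, 3), drop = FALSE],
    if (nrow(topology$angles) > 0) topology$angles[, c(1, 3), drop = FALSE])
  if (is.null(p) || nrow(p) == 0)
    return(matrix(integer(0), ncol = 2))
  p <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  unique(p)
}

#' Re-derive the energy-balance ratios of a topology
#'
#' Recomputes, from the stored term tables alone, the two ratios that
#' [balance_energies()] enforces: backbone-dihedral to side-chain-chirality
#' strength, and total-contact to total-dihedral-class strength.  A
#' salt-bridge contact counts at its combined Go + Debye-Hueckel strength
#' (its stored depth plus the recorded `dh_comp` compensation), which equals
#' the standard side-chain contact depth it was rescaled to match.
#'
#' @param topology A balanced `cg_topology`.
#' @return Named numeric vector `c(dihedral_ratio, contact_ratio)`.
#' @export
energy_balance_ratios <- function(topology) {
  sd_bb <- if (nrow(topology$dihedrals) > 0) sum(topology$dihedrals[, 6]) else 0
  sd_sc <- if (nrow(topology$chirality) > 0) sum(topology$chirality[, 6]) else 0
  dh_comp <- if ("dh_comp" %in% names(topology$contacts))
    topology$contacts$dh_comp else 0
  se <- sum(topology$contacts$epsilon + dh_comp)
  c(dihedral_ratio = if (sd_sc > 0) sd_bb / sd_sc else NA_real_,
    contact_ratio = if (sd_bb + sd_sc > 0) se / (sd_bb + sd_sc) else NA_real_)
}

#' Serialize a topology to JSON
#'
#' Writes a versioned, structured-text representation of the full topology
#' (beads, bonded terms, contacts, charges, scale factors, electrostatics).
#'
#' @param topology A `cg_topology`.
#' @param path Output file path.
#' @export
write_topology <- function(topology, path) {
  obj <- list(schema = "cg_topology/1.0",
              beads = topology$beads,
              bonds = as.data.frame(topology$bonds),
              angles = as.data.frame(topology$angles),
              dihedrals = as.data.frame(topology$dihedrals),
              chirality = as.data.frame(topology$chirality),
              contacts = topology$contacts,
              scale_factors = as.list(topology$scale_factors),
              electrostatics = topology$electrostatics,
              metadata = topology$metadata)
  names(obj$bonds) <- c("i", "j", "r0", "K")[seq_len(ncol(obj$bonds))]
  names(obj$angles) <- c("i", "j", "k", "theta0", "K")[seq_len(ncol(obj$angles))]
  names(obj$dihedrals) <- c("i", "j", "k", "l", "phi0", "Kd")[seq_len(ncol(obj$dihedrals))]
  names(obj$chirality) <- c("a", "b", "c", "d", "C0", "Kc")[seq_len(ncol(obj$chirality))]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a topology serialized by [write_topology()]
#'
#' @param path JSON file path.
#' @return A `cg_topology`.
#' @export
read_topology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "cg_topology/1.0"))
    stop("unrecognized topology schema: ", obj$schema)
  as_mat <- function(df, k) {
    if (is.null(df) || NROW(df) == 0) empty_term(k) else as.matrix(df)
  }
  contacts <- if (is.null(obj$contacts) || NROW(obj$contacts) == 0)
    empty_contacts() else as.data.frame(obj$contacts)
  sf <- unlist(obj$scale_factors)
  new_topology(beads = as.data.frame(obj$beads),
               bonds = as_mat(obj$bonds, 4), angles = as_mat(obj$angles, 5),
               dihedrals = as_mat(obj$dihedrals, 6),
               chirality = as_mat(obj$chirality, 6),
               contacts = contacts, scale_factors = sf,
               electrostatics = obj$electrostatics, metadata = obj$metadata)
}
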