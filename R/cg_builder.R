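# From an all-atom multi-chain PDB to a fully parameterized two-bead topology.

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' Parse a protein structure
#'
#' Reads ATOM records of a PDB file (via bio3d), keeping the first MODEL of
#' NMR ensembles, dropping HETATM/waters/hydrogens and keeping altloc A.
#'
#' @param pdb_path Path to a PDB file.
#' @return An `aa_model`: list of chains in file order, each a list of
#'   residues carrying name, PDB residue number and heavy-atom coordinates.
#' @export
parse_structure <- function(pdb_path) {
  if (!file.exists(pdb_path)) stop("no such file: ", pdb_path)
  pdb <- bio3d::read.pdb(pdb_path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  elt <- at$elesy
  hyd <- (!is.na(elt) & elt %in% c("H", "D")) |
    ((is.na(elt) | elt == "") & grepl("^[0-9]*H", at$elety))
  at <- at[!hyd, , drop = FALSE]
  if (nrow(at) == 0) stop("no protein chains: file has no usable ATOM records")
  at$chain[is.na(at$chain)] <- " "
  chain_ids <- unique(at$chain)
  chains <- lapply(chain_ids, function(cid) {
    ca <- at[at$chain == cid, , drop = FALSE]
    keys <- unique(paste(ca$resno, ca$insert))
    residues <- lapply(keys, function(k) {
      ra <- ca[paste(ca$resno, ca$insert) == k, , drop = FALSE]
      list(name = toupper(ra$resid[1]), resid = ra$resno[1],
           atoms = data.frame(name = ra$elety, x = ra$x, y = ra$y, z = ra$z,
                              stringsAsFactors = FALSE))
    })
    list(chain_id = cid, residues = residues)
  })
  model <- structure(list(chains = chains), class = "aa_model")
  for (ch in model$chains) {
    for (r in ch$residues) {
      if (!("CA" %in% r$atoms$name))
        stop("residue ", r$name, " ", r$resid, " in chain ", ch$chain_id,
             " has no CA atom")
    }
  }
  model
}

#' Map an all-atom model to two-bead coordinates
#'
#' One backbone (BB) bead at the CA position per residue; one side-chain (SC)
#' bead at the unweighted geometric centroid of the side-chain heavy atoms per
#' non-glycine residue.  Beads are ordered residue by residue in chain order,
#' BB before SC.
#'
#' @param model An `aa_model` from [parse_structure()].
#' @return data.frame of beads (columns kind, residue_name, chain_id, resid,
#'   x, y, z, charge; charges all 0 until [assign_charges()]).
#' @export
coarse_grain <- function(model) {
  rows <- list()
  for (ch in model$chains) {
    for (r in ch$residues) {
      ca <- r$atoms[r$atoms$name == "CA", , drop = FALSE]
      rows[[length(rows) + 1]] <-
        data.frame(kind = "BB", residue_name = r$name, chain_id = ch$chain_id,
                   resid = r$resid, x = ca$x[1], y = ca$y[1], z = ca$z[1],
                   charge = 0, stringsAsFactors = FALSE)
      if (r$name != "GLY") {
        sc <- r$atoms[!(r$atoms$name %in% .backbone_atoms), , drop = FALSE]
        if (nrow(sc) == 0)
          stop("non-glycine residue ", r$name, " ", r$resid, " in chain ",
               ch$chain_id, " has no side-chain heavy atoms")
        rows[[length(rows) + 1]] <-
          data.frame(kind = "SC", residue_name = r$name, chain_id = ch$chain_id,
                     resid = r$resid, x = mean(sc$x), y = mean(sc$y),
                     z = mean(sc$z), charge = 0, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Assign integer point charges to side-chain beads
#'
#' Arg and Lys side chains get +1, Asp and Glu get -1; every other bead
#' (including all backbone beads) is neutral.
#'
#' @param beads Bead data.frame from [coarse_grain()].
#' @return The beads with the `charge` column filled.
#' @export
assign_charges <- function(beads) {
  beads$charge <- 0
  sc <- beads$kind == "SC"
  beads$charge[sc & beads$residue_name %in% c("ARG", "LYS")] <- 1
  beads$charge[sc & beads$residue_name %in% c("ASP", "GLU")] <- -1
  beads
}

# Flat per-atom table with global residue index and bead bookkeeping.
flatten_atoms <- function(model) {
  out <- list()
  gidx <- 0
  for (ch in model$chains) {
    for (r in ch$residues) {
      gidx <- gidx + 1
      a <- r$atoms
      a$res_global <- gidx
      a$chain_id <- ch$chain_id
      a$resid <- r$resid
      a$res_name <- r$name
      a$is_bb <- a$name %in% .backbone_atoms
      out[[gidx]] <- a
    }
  }
  do.call(rbind, out)
}

#' Build the native contact map
#'
#' Structural-unit-style detection with a single heavy-atom cutoff: a residue
#' pair is in native contact when any heavy-atom pair across the two residues
#' is within `cutoff`.  The contact is typed by the closest-approach atoms:
#' both backbone gives BB-BB, both side chain gives SC-SC; mixed approaches go
#' to SC-SC when both residues carry an SC bead, else BB-BB.  BB-BB weights
#' follow the flavored Miyazawa-Jernigan scheme ([mj_flavored_epsilon()]);
#' SC-SC contacts are weighted uniformly (1 before global scaling).
#' Backbone-side chain contacts are never created.  Intra-chain pairs need a
#' sequence separation of at least `min_seq_sep_bb` (BB-BB) or
#' `min_seq_sep_sc` (SC-SC).
#'
#' @param model An `aa_model`.
#' @param beads Beads from [coarse_grain()] on the same model.
#' @param cutoff Heavy-atom contact cutoff (Angstrom).
#' @param alpha Flavoring strength (0 = plain Go, 1 = flavored).
#' @param min_seq_sep_bb,min_seq_sep_sc Minimum |delta resid| for intra-chain
#'   contacts.
#' @return Contact data.frame (i, j bead rows, pair_kind, span, r_native,
#'   epsilon, salt_bridge, dh_comp).
#' @export
build_native_contacts <- function(model, beads, cutoff = 4.5, alpha = 1,
                                  min_seq_sep_bb = 4, min_seq_sep_sc = 3) {
  at <- flatten_atoms(model)
  nres <- max(at$res_global)
  # residue-level bookkeeping
  res_chain <- tapply(at$chain_id, at$res_global, function(v) v[1])
  res_resid <- tapply(at$resid, at$res_global, function(v) v[1])
  res_name <- tapply(at$res_name, at$res_global, function(v) v[1])
  bead_row_bb <- integer(nres); bead_row_sc <- rep(NA_integer_, nres)
  g <- 0
  for (b in seq_len(nrow(beads))) {
    if (beads$kind[b] == "BB") { g <- g + 1; bead_row_bb[g] <- b }
    else bead_row_sc[g] <- b
  }
  if (g != nres) stop("beads do not align with the all-atom model")

  axyz <- as.matrix(at[, c("x", "y", "z")])
  asplit <- split(seq_len(nrow(at)), at$res_global)
  # coarse screen on CA distance
  ca_xyz <- as.matrix(beads[bead_row_bb, c("x", "y", "z")])
  rows <- list()
  for (ri in seq_len(nres - 1)) {
    d2 <- rowSums(sweep(ca_xyz[(ri + 1):nres, , drop = FALSE], 2,
                        ca_xyz[ri, ], "-")^2)
    cand <- (ri + 1):nres
    cand <- cand[d2 < (cutoff + 12)^2]
    ai <- axyz[asplit[[ri]], , drop = FALSE]
    for (rj in cand) {
      aj <- axyz[asplit[[rj]], , drop = FALSE]
      dm <- outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * ai %*% t(aj)
      mn <- which.min(dm)
      if (sqrt(max(dm[mn], 0)) >= cutoff) next
      ia <- asplit[[ri]][(mn - 1) %% nrow(ai) + 1]
      ja <- asplit[[rj]][(mn - 1) %/% nrow(ai) + 1]
      both_bb <- at$is_bb[ia] && at$is_bb[ja]
      both_sc <- !at$is_bb[ia] && !at$is_bb[ja]
      have_sc <- !is.na(bead_row_sc[ri]) && !is.na(bead_row_sc[rj])
      kind <- if (both_bb) "BBBB"
      else if (both_sc) {
        if (!have_sc) "BBBB" else "SCSC"
      } else if (have_sc) "SCSC" else "BBBB"
      intra <- res_chain[ri] == res_chain[rj]
      sep <- abs(res_resid[rj] - res_resid[ri])
      if (intra && kind == "BBBB" && sep < min_seq_sep_bb) next
      if (intra && kind == "SCSC" && sep < min_seq_sep_sc) next
      bi <- if (kind == "BBBB") bead_row_bb[ri] else bead_row_sc[ri]
      bj <- if (kind == "BBBB") bead_row_bb[rj] else bead_row_sc[rj]
      rn <- sqrt(sum((as.numeric(beads[bi, c("x", "y", "z")]) -
                      as.numeric(beads[bj, c("x", "y", "z")]))^2))
      rows[[length(rows) + 1]] <-
        data.frame(i = bi, j = bj, pair_kind = kind,
                   span = if (intra) "intra" else "inter",
                   r_native = rn, epsilon = 1, salt_bridge = FALSE,
                   dh_comp = 0, res_i = res_name[ri], res_j = res_name[rj],
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    warning("no native contacts found")
    out <- empty_contacts()
    out$res_i <- character(0); out$res_j <- character(0)
    return(out)
  }
  contacts <- do.call(rbind, rows)
  bb <- contacts$pair_kind == "BBBB"
  if (any(bb)) {
    mj <- mj_matrix()
    w <- mj[cbind(contacts$res_i[bb], contacts$res_j[bb])]
    contacts$epsilon[bb] <-
      mj_flavored_epsilon(contacts$res_i[bb], contacts$res_j[bb],
                          alpha = alpha, mean_mj = mean(w), mj = mj)
  }
  contacts
}

#' Flag and rescale salt-bridge contacts
#'
#' Every SC-SC native contact between oppositely charged side chains is
#' flagged and its well depth reduced so that the Go well plus the
#' Debye-Hueckel attraction at the native distance and reference salt
#' concentration together equal the standard side-chain contact depth.  The
#' reduced depth is floored at `floor_frac` of the standard depth (a very
#' close pair would otherwise become purely electrostatic); the amount
#' actually subtracted is recorded in `dh_comp` so total contact strength
#' stays exactly bookkeepable.
#'
#' @param contacts Contact data.frame.
#' @param beads Charged beads ([assign_charges()] already applied).
#' @param elec A `dh_params` at the reference salt concentration.
#' @param floor_frac Minimum retained fraction of the standard depth.
#' @return The contacts with salt_bridge, epsilon and dh_comp updated.
#' @export
flag_salt_bridges <- function(contacts, beads,
                              elec = electrostatics_params(C = 0.15),
                              floor_frac = 0.05) {
  if (nrow(contacts) == 0) return(contacts)
  qi <- beads$charge[contacts$i]
  qj <- beads$charge[contacts$j]
  sb <- contacts$pair_kind == "SCSC" & qi * qj < 0
  contacts$salt_bridge <- sb
  if (any(sb)) {
    vdh <- abs(dh_pair_energy(contacts$r_native[sb], qi[sb], qj[sb], elec))
    eps_std <- contacts$epsilon[sb]
    eps_red <- pmax(eps_std - vdh, floor_frac * eps_std)
    contacts$dh_comp[sb] <- eps_std - eps_red
    contacts$epsilon[sb] <- eps_red
  }
  contacts
}

# Dihedral angle with the same sign convention as the compiled core.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Normalized scalar triple product used by the chirality potential.
chirality_value <- function(a, b, c, d) {
  v1 <- b - a; v2 <- c - b; v3 <- d - b
  sum(cross3(v1, v2) * v3) /
    (sqrt(sum(v1^2)) * sqrt(sum(v2^2)) * sqrt(sum(v3^2)))
}

#' Build bonded terms from the native bead geometry
#'
#' Bonds between consecutive backbone beads in a chain and between each
#' residue's BB and SC bead; angles over consecutive BB triples and
#' (BB, BB, SC) triples; SBM cosine dihedrals (periods 1 and 3) over
#' consecutive BB quadruplets; one harmonic chirality term per SC bead of an
#' interior residue, acting on the normalized scalar triple product of the
#' local backbone/side-chain vectors.  All equilibrium values are taken from
#' the native structure, so every bonded energy vanishes exactly there.
#'
#' @param beads Bead data.frame.
#' @param Kb,Ka,Kd,Kc Force constants (eps0/A^2, eps0/rad^2, eps0, eps0).
#' @return List with elements bonds, angles, dihedrals, chirality.
#' @export
build_bonded_terms <- function(beads, Kb = 100, Ka = 20, Kd = 1, Kc = 20) {
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  bonds <- list(); angles <- list(); dihedrals <- list(); chir <- list()
  dist <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  ang <- function(i, j, k) {
    u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }
  for (cid in unique(beads$chain_id)) {
    rows <- which(beads$chain_id == cid)
    bb <- rows[beads$kind[rows] == "BB"]
    nb <- length(bb)
    # BB-SC bonds and per-residue SC index
    sc_of <- rep(NA_integer_, nb)
    for (t in seq_len(nb)) {
      b <- bb[t]
      nxt <- b + 1L
      if (nxt <= nrow(beads) && beads$kind[nxt] == "SC" &&
          beads$chain_id[nxt] == cid && beads$resid[nxt] == beads$resid[b]) {
        sc_of[t] <- nxt
        bonds[[length(bonds) + 1]] <- c(b, nxt, dist(b, nxt), Kb)
      }
    }
    for (t in seq_len(nb - 1))
      bonds[[length(bonds) + 1]] <- c(bb[t], bb[t + 1], dist(bb[t], bb[t + 1]), Kb)
    for (t in seq_len(max(nb - 2, 0)))
      angles[[length(angles) + 1]] <-
        c(bb[t], bb[t + 1], bb[t + 2], ang(bb[t], bb[t + 1], bb[t + 2]), Ka)
    for (t in seq_len(nb)[-1]) {
      if (!is.na(sc_of[t]))
        angles[[length(angles) + 1]] <-
          c(bb[t - 1], bb[t], sc_of[t], ang(bb[t - 1], bb[t], sc_of[t]), Ka)
    }
    if (nb >= 4) {
      for (t in seq_len(nb - 3)) {
        q <- bb[t:(t + 3)]
        dihedrals[[length(dihedrals) + 1]] <-
          c(q, dihedral_angle(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ],
                              xyz[q[4], ]), Kd)
      }
    } else if (nb > 0) {
      warning("chain ", cid, " shorter than 4 residues: no backbone dihedrals")
    }
    for (t in seq_len(nb)) {
      if (t == 1 || t == nb || is.na(sc_of[t])) next
      quad <- c(bb[t - 1], bb[t], bb[t + 1], sc_of[t])
      C0 <- chirality_value(xyz[quad[1], ], xyz[quad[2], ], xyz[quad[3], ],
                            xyz[quad[4], ])
      chir[[length(chir) + 1]] <- c(quad, C0, Kc)
    }
  }
  as_m <- function(lst, k) if (length(lst) == 0) empty_term(k)
    else do.call(rbind, lst)
  list(bonds = as_m(bonds, 4), angles = as_m(angles, 5),
       dihedrals = as_m(dihedrals, 6), chirality = as_m(chir, 6))
}

#' Balance dihedral and contact energy scales
#'
#' Rescales the chirality (side-chain dihedral-class) and contact strengths so
#' that the total backbone-dihedral strength is twice the total chirality
#' strength, and the total contact strength is twice the total dihedral-class
#' strength.  The backbone dihedral scale is the anchor (unchanged).  The
#' applied factors accumulate in `scale_factors` and the strength sums are
#' recorded in `metadata$balance`; the operation is idempotent.
#'
#' @param topology A `cg_topology`.
#' @return The balanced topology.
#' @export
balance_energies <- function(topology) {
  sd_bb <- if (nrow(topology$dihedrals) > 0) sum(topology$dihedrals[, 6]) else 0
  sd_sc <- if (nrow(topology$chirality) > 0) sum(topology$chirality[, 6]) else 0
  se <- sum(topology$contacts$epsilon + topology$contacts$dh_comp)
  lam_bb <- 1; lam_sc <- 1; lam_ct <- 1
  skipped <- character(0)
  if (sd_bb == 0) {
    warning("no backbone dihedral terms: balance factors left at 1")
    skipped <- c(skipped, "dihedral_ratio", "contact_ratio")
  } else {
    if (sd_sc == 0) {
      skipped <- c(skipped, "dihedral_ratio")
    } else {
      lam_sc <- sd_bb / (2 * sd_sc)
      topology$chirality[, 6] <- topology$chirality[, 6] * lam_sc
    }
    if (se == 0) {
      skipped <- c(skipped, "contact_ratio")
    } else {
      lam_ct <- 2 * (sd_bb + sum(topology$chirality[, 6])) / se
      topology$contacts$epsilon <- topology$contacts$epsilon * lam_ct
      topology$contacts$dh_comp <- topology$contacts$dh_comp * lam_ct
    }
  }
  sf <- topology$scale_factors
  topology$scale_factors <- c(lambda_dih_bb = unname(sf["lambda_dih_bb"] * lam_bb),
                              lambda_dih_sc = unname(sf["lambda_dih_sc"] * lam_sc),
                              lambda_contact = unname(sf["lambda_contact"] * lam_ct))
  topology$metadata$balance <- list(
    dihedral_bb_sum = sd_bb * lam_bb,
    chirality_sum = if (nrow(topology$chirality) > 0)
      sum(topology$chirality[, 6]) else 0,
    contact_sum = sum(topology$contacts$epsilon + topology$contacts$dh_comp),
    skipped = skipped)
  topology
}

#' Build a parameterized topology from a PDB file
#'
#' Full pipeline: parse, coarse-grain, assign charges, detect native contacts,
#' build bonded terms, balance the energy scales, then flag and rescale
#' salt bridges (in final energy units, so the rescaling identity holds in the
#' serialized topology).
#'
#' @param pdb Path to a PDB file, or an `aa_model`.
#' @param contact_cutoff Heavy-atom contact cutoff (Angstrom).
#' @param alpha Flavoring strength for BB-BB weights.
#' @param ref_salt Reference salt concentration (molar) for the salt-bridge
#'   rescaling.
#' @param eps_r Relative dielectric constant.
#' @param ion_radius_a Ion-exclusion radius (Angstrom).
#' @param Kb,Ka,Kd,Kc Base force constants (see [build_bonded_terms()]).
#' @return A balanced `cg_topology`.
#' @export
build_topology <- function(pdb, contact_cutoff = 4.5, alpha = 1,
                           ref_salt = 0.15, eps_r = 80, ion_radius_a = 1.425,
                           Kb = 100, Ka = 20, Kd = 1, Kc = 20) {
  model <- if (inherits(pdb, "aa_model")) pdb else parse_structure(pdb)
  beads <- assign_charges(coarse_grain(model))
  contacts <- build_native_contacts(model, beads, cutoff = contact_cutoff,
                                    alpha = alpha)
  terms <- build_bonded_terms(beads, Kb = Kb, Ka = Ka, Kd = Kd, Kc = Kc)
  elec <- list(eps_r = eps_r,
               K_coulomb = calibrate_kcoulomb(eps_r = eps_r, a = ion_radius_a),
               ion_radius_a = ion_radius_a, ref_salt_molar = ref_salt)
  topo <- new_topology(beads = beads, bonds = terms$bonds,
                       angles = terms$angles, dihedrals = terms$dihedrals,
                       chirality = terms$chirality, contacts = contacts,
                       electrostatics = elec,
                       metadata = list(source = if (is.character(pdb)) basename(pdb)
                                       else "aa_model",
                                       contact_cutoff = contact_cutoff,
                                       alpha = alpha))
  topo <- balance_energies(topo)
  ep <- electrostatics_params(C = ref_salt, eps_r = eps_r,
                              ion_radius_a = ion_radius_a,
                              K_coulomb = elec$K_coulomb)
  topo$contacts <- flag_salt_bridges(topo$contacts, topo$beads, elec = ep)
  topo
}
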