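test_that("parse_structure reads toy PDBs and rejects degenerate input", {
  model <- parse_structure(fx_mixed$pdb_path)
  expect_length(model$chains, 2)
  expect_equal(sum(lengths(lapply(model$chains, `[[`, "residues"))), 10)
  expect_equal(model$chains[[1]]$chain_id, "A")

  empty <- file.path(fixture_dir, "empty.pdb")
  writeLines(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000",
               "END"), empty)
  expect_error(parse_structure(empty), "no protein chains|no usable")
  expect_error(parse_structure(file.path(fixture_dir, "nope.pdb")),
               "no such file")
})

test_that("coarse graining: CA backbone beads, centroid side chains, no SC for Gly", {
  model <- parse_structure(fx_fifty$pdb_path)
  beads <- coarse_grain(model)
  expect_equal(nrow(beads), 50)
  gly <- which(beads$residue_name == "GLY")
  expect_true(all(beads$kind[gly] == "BB"))
  # BB bead sits exactly on the CA atom
  r1 <- model$chains[[1]]$residues[[1]]
  ca <- r1$atoms[r1$atoms$name == "CA", ]
  expect_equal(unlist(beads[1, c("x", "y", "z")], use.names = FALSE),
               c(ca$x, ca$y, ca$z))
  # single-atom side chain: centroid is that atom; two-atom: midpoint
  sc_at <- r1$atoms[!(r1$atoms$name %in% c("N", "CA", "C", "O")), ]
  expect_equal(unlist(beads[2, c("x", "y", "z")], use.names = FALSE),
               c(mean(sc_at$x), mean(sc_at$y), mean(sc_at$z)))
  # ordering: BB before SC within each residue, residues in chain order
  expect_equal(beads$kind[1:4], c("BB", "SC", "BB", "SC"))
})

test_that("charge assignment follows the four charged residue types", {
  beads <- fx_salt_topo$beads
  expect_true(all(beads$charge[beads$kind == "BB"] == 0))
  expect_true(all(beads$charge[beads$residue_name == "GLU" &
                               beads$kind == "SC"] == -1))
  expect_true(all(beads$charge[beads$residue_name == "LYS" &
                               beads$kind == "SC"] == 1))
  # sequence-derived formal charge
  seqs <- fx_fifty_topo$beads[fx_fifty_topo$beads$kind == "BB", "residue_name"]
  expect_equal(sum(fx_fifty_topo$beads$charge),
               sum(seqs %in% c("ARG", "LYS")) - sum(seqs %in% c("ASP", "GLU")))
})

test_that("native contact detection matches the fixture manifest", {
  for (fx in list(list(fx_salt, fx_salt_topo), list(fx_mixed, fx_mixed_topo),
                  list(fx_dimer, fx_dimer_topo), list(fx_gly, fx_gly_topo))) {
    manifest <- fx[[1]]$manifest
    topo <- fx[[2]]
    got <- data.frame(
      chain_i = topo$beads$chain_id[topo$contacts$i],
      resid_i = topo$beads$resid[topo$contacts$i],
      chain_j = topo$beads$chain_id[topo$contacts$j],
      resid_j = topo$beads$resid[topo$contacts$j],
      pair_kind = topo$contacts$pair_kind, span = topo$contacts$span,
      stringsAsFactors = FALSE)
    ord <- function(d) d[order(d$chain_i, d$resid_i, d$chain_j, d$resid_j), ]
    expect_equal(ord(got), ord(manifest), ignore_attr = TRUE)
  }
})

test_that("no contact is ever backbone-side chain and separations are honored", {
  for (topo in list(fx_salt_topo, fx_mixed_topo, fx_dimer_topo, fx_gly_topo,
                    fx_fifty_topo)) {
    expect_true(all(topo$contacts$pair_kind %in% c("BBBB", "SCSC")))
    intra_bb <- topo$contacts$pair_kind == "BBBB" & topo$contacts$span == "intra"
    if (any(intra_bb)) {
      sep <- abs(topo$beads$resid[topo$contacts$i[intra_bb]] -
                 topo$beads$resid[topo$contacts$j[intra_bb]])
      expect_true(all(sep >= 4))
    }
    expect_true(all(topo$contacts$epsilon > 0))
    expect_true(all(topo$contacts$r_native > 0))
  }
})

test_that("residues far apart yield no contact", {
  fx <- toy_pdb("apart", toy_spec("EEKLE", "KKELV",
                                  arrangement = "separated", seed = 2))
  expect_warning(topo <- build_topology(fx$pdb_path), "no native contacts")
  expect_equal(nrow(topo$contacts), 0)
})

test_that("flavored MJ weights follow the interpolation formula", {
  mj <- mj_matrix()
  expect_true(isSymmetric(mj))
  expect_true(all(mj > 0))
  # alpha = 0 collapses to the plain Go model
  expect_equal(mj_flavored_epsilon("LEU", "LEU", alpha = 0, mean_mj = 3), 1)
  # pair at 1.5x the system mean maps to 1.5
  m <- mj["LEU", "LEU"]
  expect_equal(mj_flavored_epsilon("LEU", "LEU", alpha = 1,
                                   mean_mj = m / 1.5), 1.5)
  # identical-pair system: every weight is the mean, so 1 regardless of alpha
  expect_equal(mj_flavored_epsilon("TRP", "TYR", alpha = 0.7,
                                   mean_mj = mj["TRP", "TYR"]), 1)
  # heterogeneity: different pairs get different positive weights
  e1 <- mj_flavored_epsilon("LEU", "LEU", alpha = 1, mean_mj = 3)
  e2 <- mj_flavored_epsilon("LYS", "GLU", alpha = 1, mean_mj = 3)
  expect_true(e1 != e2 && e1 > 0 && e2 > 0)
  expect_error(mj_flavored_epsilon("XXX", "LEU", mean_mj = 3),
               "unknown residue")
})

test_that("salt bridges are flagged and rescaled to the defining identity", {
  topo <- fx_salt_topo
  sb <- topo$contacts$salt_bridge
  expect_true(all(sb))  # every interface contact pairs Glu with Lys
  el <- topo$electrostatics
  ep <- electrostatics_params(C = el$ref_salt_molar, eps_r = el$eps_r,
                              ion_radius_a = el$ion_radius_a,
                              K_coulomb = el$K_coulomb)
  ct <- topo$contacts[sb, ]
  eps_std <- ct$epsilon + ct$dh_comp
  vdh <- abs(dh_pair_energy(ct$r_native, 1, -1, ep))
  # reduction is min(V_DH at native distance, the floor allowance)
  expect_equal(ct$dh_comp, pmin(vdh, 0.95 * eps_std), tolerance = 1e-12)
  # unfloored pairs satisfy eps_reduced + V_DH(r_native, C_ref) = eps_standard
  unfloored <- vdh < 0.95 * eps_std
  if (any(unfloored))
    expect_equal(ct$epsilon[unfloored] + vdh[unfloored], eps_std[unfloored],
                 tolerance = 1e-12)
  # uncharged SC-SC pairs untouched
  mixed <- fx_mixed_topo$contacts
  lnl <- which(!mixed$salt_bridge)
  expect_true(all(mixed$dh_comp[lnl] == 0))
})

test_that("bonded terms vanish exactly at the native structure", {
  for (topo in list(fx_mixed_topo, fx_dimer_topo, fx_fifty_topo)) {
    e <- total_energy(topology_xyz(topo), topo, no_elec, no_pairs)
    expect_equal(e$bond, 0, tolerance = 1e-12)
    expect_equal(e$angle, 0, tolerance = 1e-12)
    expect_equal(e$dihedral, 0, tolerance = 1e-12)
    expect_equal(e$chirality, 0, tolerance = 1e-12)
    expect_equal(e$native_contact,
                 -sum(topo$contacts$epsilon), tolerance = 1e-9)
  }
})

test_that("bonded term counts follow the chain layout", {
  # 5-residue single chain, no glycine: 4 BB-BB + 5 BB-SC bonds, 3 BB angles
  fx <- toy_pdb("penta", toy_spec("LVKEA", "L", arrangement = "separated",
                                  seed = 4))
  model <- parse_structure(fx$pdb_path)
  beads <- coarse_grain(model)
  a <- beads$chain_id == "A"
  terms <- suppressWarnings(build_bonded_terms(beads[a, , drop = FALSE]))
  expect_equal(nrow(terms$bonds), 4 + 5)
  bb_angles <- sum(apply(terms$angles, 1, function(r)
    all(beads$kind[a][r[1:3]] == "BB")))
  expect_equal(bb_angles, 3)
  expect_equal(nrow(terms$dihedrals), 2)
  expect_equal(nrow(terms$chirality), 3)  # interior residues only
})

test_that("mirror-imaging the side chain flips the chirality sign and costs energy", {
  topo <- fx_dimer_topo
  fr <- topology_xyz(topo)
  ch <- topo$chirality[1, ]
  C0 <- ch[5]
  expect_gt(abs(C0), 1e-4)
  # reflect the SC bead through the plane of the three backbone beads
  a <- fr[ch[1], ]; b <- fr[ch[2], ]; cc <- fr[ch[3], ]; d <- fr[ch[4], ]
  nrm <- cgchaperone:::cross3(b - a, cc - b)
  nrm <- nrm / sqrt(sum(nrm^2))
  fr2 <- fr
  fr2[ch[4], ] <- d - 2 * sum((d - b) * nrm) * nrm
  Cm <- cgchaperone:::chirality_value(a, b, cc, fr2[ch[4], ])
  expect_equal(Cm, -C0, tolerance = 1e-9)
  e <- total_energy(fr2, topo, no_elec, no_pairs)
  expect_gte(e$chirality, ch[6] * (2 * C0)^2 - 1e-9)
})

test_that("energy balance enforces the two 2.0 ratios and is idempotent", {
  for (topo in list(fx_mixed_topo, fx_dimer_topo, fx_fifty_topo)) {
    expect_equal(unname(energy_balance_ratios(topo)), c(2, 2),
                 tolerance = 1e-12)
    again <- balance_energies(topo)
    expect_equal(again$contacts$epsilon, topo$contacts$epsilon,
                 tolerance = 1e-12)
    expect_equal(again$chirality, topo$chirality, tolerance = 1e-12)
  }
})

test_that("doubling contact strengths before balancing changes nothing after", {
  model <- parse_structure(fx_mixed$pdb_path)
  beads <- assign_charges(coarse_grain(model))
  contacts <- build_native_contacts(model, beads)
  terms <- build_bonded_terms(beads)
  mk <- function(ct) balance_energies(new_topology(
    beads = beads, bonds = terms$bonds, angles = terms$angles,
    dihedrals = terms$dihedrals, chirality = terms$chirality, contacts = ct))
  doubled <- contacts
  doubled$epsilon <- doubled$epsilon * 2
  expect_equal(mk(doubled)$contacts$epsilon, mk(contacts)$contacts$epsilon,
               tolerance = 1e-12)
})

test_that("degenerate systems skip ratios with a warning, factors stay 1", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  topo <- new_topology(bead_df(xyz, res = "GLY"),
                       bonds = rbind(c(1, 2, 3.8, 100), c(2, 3, 3.8, 100)))
  expect_warning(out <- balance_energies(topo), "no backbone dihedral")
  expect_equal(unname(out$scale_factors), c(1, 1, 1))
})

test_that("alpha = 0 gives the plain Go model energies", {
  topo0 <- build_topology(fx_mixed$pdb_path, alpha = 0)
  bb <- topo0$contacts$pair_kind == "BBBB"
  sc <- topo0$contacts$pair_kind == "SCSC" & !topo0$contacts$salt_bridge
  if (any(bb) && any(sc)) {
    # uniform weights: all contacts share one post-balance depth
    expect_equal(max(topo0$contacts$epsilon[bb | sc]),
                 min(topo0$contacts$epsilon[bb | sc]), tolerance = 1e-12)
  }
  expect_equal(unname(energy_balance_ratios(topo0)), c(2, 2),
               tolerance = 1e-12)
})

test_that("topology JSON serialization round-trips energies exactly", {
  path <- file.path(fixture_dir, "roundtrip.json")
  write_topology(fx_salt_topo, path)
  back <- read_topology(path)
  fr <- random_frame(fx_salt_topo, seed = 31)
  e1 <- total_energy(fr, fx_salt_topo)
  e2 <- total_energy(fr, back)
  expect_equal(e1$total, e2$total, tolerance = 1e-12)
  expect_equal(unname(energy_balance_ratios(back)), c(2, 2),
               tolerance = 1e-12)
})
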