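# Shared fixtures, built once per test run.

fixture_dir <- file.path(tempdir(), "cgchaperone-fixtures")
dir.create(fixture_dir, showWarnings = FALSE)

toy_pdb <- function(name, spec) {
  path <- file.path(fixture_dir, paste0(name, ".pdb"))
  res <- make_toy_complex(spec, path)
  res$pdb_path <- path
  res
}

# charged paired strands: inter-chain SC-SC contacts, all salt bridges
fx_salt <- toy_pdb("salt", toy_spec("EEEE", "KKKK", separation = 4.2, seed = 5))
fx_salt_topo <- build_topology(fx_salt$pdb_path)

# mixed paired strands (some charged, some not)
fx_mixed <- toy_pdb("mixed", toy_spec("EEKLVE", "KKEL", seed = 3))
fx_mixed_topo <- build_topology(fx_mixed$pdb_path)

# hairpin dimer: folded chain A with intra contacts + binder chain B
fx_dimer <- toy_pdb("dimer", toy_spec("LVALKEIV", "EKLV",
                                      arrangement = "hairpin_dimer", seed = 9))
fx_dimer_topo <- build_topology(fx_dimer$pdb_path)

# uncharged strong-binding variant of the dimer (for kinetic completion tests)
fx_strong <- toy_pdb("strong", toy_spec("LVALLAIV", "VLLV",
                                        arrangement = "hairpin_dimer", seed = 9))
fx_strong_topo <- build_topology(fx_strong$pdb_path)
fx_strong_topo$contacts$epsilon <- fx_strong_topo$contacts$epsilon * 4

# glycine-rich hairpin: exercises BB-BB classification (no SC bead available)
fx_gly <- toy_pdb("gly", toy_spec("GGLVLKGG", "VL",
                                  arrangement = "hairpin_dimer", seed = 12))
fx_gly_topo <- suppressWarnings(build_topology(fx_gly$pdb_path))

# 50-bead two-chain system for the energy-oracle comparisons
fx_fifty <- toy_pdb("fifty", toy_spec("LKELVADEKRVHL", "GKELVADEKRLVG",
                                      seed = 17))
fx_fifty_topo <- build_topology(fx_fifty$pdb_path)
stopifnot(nrow(fx_fifty_topo$beads) == 50)

no_elec <- electrostatics_params(enabled = FALSE)
no_pairs <- ff_control(ev_epsilon = 0)

# single-bead data.frame helper for hand-made topologies
bead_df <- function(xyz, kind = "BB", res = "ALA", chain = "A",
                    resid = seq_len(nrow(xyz))) {
  data.frame(kind = kind, residue_name = res, chain_id = chain, resid = resid,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = 0,
             stringsAsFactors = FALSE)
}

# smallest distance over pairs not excluded as bonded (those are the pairs
# that feel excluded volume / electrostatics and must not collide)
min_nonbonded_dist <- function(topology, fr) {
  excl <- nonbonded_exclusions(topology)
  d <- as.matrix(dist(fr))
  d[cbind(excl[, 1], excl[, 2])] <- Inf
  d[cbind(excl[, 2], excl[, 1])] <- Inf
  diag(d) <- Inf
  min(d)
}

# random frame for a topology: perturbed native plus a rigid shift of the
# second chain, rejecting frames whose nonbonded pairs come too close
random_frame <- function(topology, seed, sd = 0.3, min_dist = 1.5) {
  set.seed(seed)
  repeat {
    fr <- topology_xyz(topology) +
      matrix(rnorm(3 * nrow(topology$beads), sd = sd), ncol = 3)
    chains <- topology$beads$chain_id
    if (length(unique(chains)) > 1) {
      b <- chains == unique(chains)[2]
      fr[b, ] <- fr[b, ] + matrix(rnorm(3, sd = 2), nrow = sum(b), ncol = 3,
                                  byrow = TRUE)
    }
    if (min_nonbonded_dist(topology, fr) > min_dist) return(fr)
  }
}

# finite-difference force check; returns max |analytic - central difference|
fd_force_error <- function(topology, frame, elec, control, h = 1e-5) {
  fa <- forces(frame, topology, elec, control)
  err <- 0
  for (i in seq_len(nrow(frame))) {
    for (d in 1:3) {
      fp <- frame; fp[i, d] <- fp[i, d] + h
      fm <- frame; fm[i, d] <- fm[i, d] - h
      fn <- -(total_energy(fp, topology, elec, control)$total -
              total_energy(fm, topology, elec, control)$total) / (2 * h)
      err <- max(err, abs(fn - fa[i, d]))
    }
  }
  err
}

five_state_generator <- function(kUE = 0.02, kEU = 0.02, kEI1 = 0.010,
                                 kEI2 = 0.008, kI1B = 0.015, kI2B = 0.012) {
  st <- c("U", "E", "I1", "I2", "B")
  G <- matrix(0, 5, 5, dimnames = list(st, st))
  G["U", "E"] <- kUE; G["E", "U"] <- kEU
  G["E", "I1"] <- kEI1; G["E", "I2"] <- kEI2
  G["I1", "B"] <- kI1B; G["I2", "B"] <- kI2B
  G
}
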