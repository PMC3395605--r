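# Synthetic structures, topologies and stochastic series: every module is
# testable without an external structure download.

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
             E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
             M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
             Y = "TYR", V = "VAL")

#' Toy-complex specification
#'
#' @param seq_a,seq_b One-letter sequences of the two chains.
#' @param arrangement "paired" (two antiparallel extended strands with
#'   side chains facing across the interface), "hairpin_dimer" (chain A folds
#'   back on itself so it has intra-chain contacts; chain B lies along the top
#'   of the hairpin), or "separated" (no inter-chain contacts).
#' @param separation Interface gap (Angstrom) between facing side-chain atoms.
#' @param jitter Seeded coordinate noise (Angstrom) that breaks exact
#'   collinearity of the ideal geometry.
#' @param seed RNG seed; the emitted PDB is byte-identical for a fixed spec.
#' @return List of class `toy_spec`.
#' @export
toy_spec <- function(seq_a, seq_b, arrangement = c("paired", "hairpin_dimer",
                                                   "separated"),
                     separation = 4.2, jitter = 0.15, seed = 1) {
  arrangement <- match.arg(arrangement)
  ok <- function(s) all(strsplit(s, "")[[1]] %in% names(.aa1to3))
  if (!ok(seq_a) || !ok(seq_b)) stop("sequences must use the 20 standard codes")
  if (nchar(seq_a) < 1 || nchar(seq_b) < 1) stop("chains must be non-empty")
  structure(list(seq_a = seq_a, seq_b = seq_b, arrangement = arrangement,
                 separation = separation, jitter = jitter, seed = seed),
            class = "toy_spec")
}

# Atoms of one residue of the minimal all-atom-lite geometry.  `flip` mirrors
# the side-chain direction (+y vs -y).
toy_residue_atoms <- function(res3, ca, flip = 1) {
  at <- rbind(N = ca + c(-1.20, -0.70 * flip, 0),
              CA = ca,
              C = ca + c(1.20, -0.70 * flip, 0),
              O = ca + c(1.40, -1.90 * flip, 0))
  if (res3 != "GLY") at <- rbind(at, CB = ca + c(0, 1.53 * flip, 0))
  at
}

#' Generate a synthetic two-chain complex
#'
#' Writes an all-atom-lite PDB (backbone N/CA/C/O plus one CB-like side-chain
#' atom per non-glycine residue) realizing the requested arrangement, and a
#' manifest of the residue pairs a contact builder must find, computed by a
#' direct atom-distance oracle with the same classification rule the builder
#' documents (any heavy-atom pair within `cutoff`; typed by the
#' closest-approach atoms).
#'
#' @param spec A `toy_spec`.
#' @param pdb_path Output PDB path.
#' @param cutoff Heavy-atom contact cutoff used for the manifest (Angstrom).
#' @return Invisibly, a list: `pdb_path` and `manifest` (data.frame with
#'   chain/resid pairs, pair_kind, span).
#' @export
make_toy_complex <- function(spec, pdb_path, cutoff = 4.5) {
  sa <- strsplit(spec$seq_a, "")[[1]]
  sb <- strsplit(spec$seq_b, "")[[1]]
  na <- length(sa); nb <- length(sb)
  gap <- spec$separation
  atoms <- list()
  zig <- function(k) c(0, 0, 0.45 * (-1)^k)  # out-of-plane zigzag keeps
  # backbone quadruplets away from collinearity
  add_res <- function(chain, resno, res3, ca, flip) {
    ca <- ca + zig(resno)
    a <- toy_residue_atoms(res3, ca, flip)
    atoms[[length(atoms) + 1]] <<-
      data.frame(chain = chain, resno = resno, res3 = res3,
                 name = rownames(a), x = unname(a[, 1]), y = unname(a[, 2]),
                 z = unname(a[, 3]), row.names = NULL,
                 stringsAsFactors = FALSE)
  }
  if (spec$arrangement == "paired") {
    # A along +x with CB up; B antiparallel above with CB down
    for (k in seq_len(na))
      add_res("A", k, .aa1to3[sa[k]], c((k - 1) * 3.8, 0, 0), 1)
    ytop <- 1.53 + gap + 1.53
    for (m in seq_len(nb))
      add_res("B", m, .aa1to3[sb[m]], c((nb - m) * 3.8, ytop, 0), -1)
  } else if (spec$arrangement == "hairpin_dimer") {
    if (na < 6 || na %% 2 != 0)
      stop("hairpin chain needs an even length >= 6")
    h <- 1.53 + gap + 1.53
    half <- na / 2
    for (k in seq_len(half))          # lower strand, CB up
      add_res("A", k, .aa1to3[sa[k]], c((k - 1) * 3.8, 0, 0), 1)
    for (k in (half + 1):na)          # upper strand, CB down
      add_res("A", k, .aa1to3[sa[k]], c((na - k) * 3.8, h, 0), -1)
    ytop <- h + 0.70 + spec$separation + 1.53   # B above the hairpin, CB down
    for (m in seq_len(nb))
      add_res("B", m, .aa1to3[sb[m]], c((nb - m) * 3.8, ytop, 0), -1)
  } else {
    for (k in seq_len(na))
      add_res("A", k, .aa1to3[sa[k]], c((k - 1) * 3.8, 0, 0), 1)
    for (m in seq_len(nb))
      add_res("B", m, .aa1to3[sb[m]], c((m - 1) * 3.8, 60, 0), 1)
  }
  at <- do.call(rbind, atoms)
  set.seed(spec$seed)
  at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
    matrix(rnorm(3 * nrow(at), sd = spec$jitter), ncol = 3)
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = pdb_path, xyz = round(xyz, 3),
                   resno = at$resno, chain = at$chain, resid = at$res3,
                   elety = at$name, eleno = seq_len(nrow(at)))
  invisible(list(pdb_path = pdb_path,
                 manifest = toy_contact_manifest(at, cutoff)))
}

# Ground-truth contact list by direct distance enumeration over the toy atoms.
toy_contact_manifest <- function(at, cutoff = 4.5,
                                 min_seq_sep_bb = 4, min_seq_sep_sc = 3) {
  key <- paste(at$chain, at$resno)
  res_keys <- unique(key)
  out <- list()
  for (a in seq_along(res_keys)) {
    for (b in seq_along(res_keys)) {
      if (b <= a) next
      ia <- which(key == res_keys[a]); ib <- which(key == res_keys[b])
      best <- Inf; besta <- NA; bestb <- NA
      for (p in ia) for (q in ib) {
        d <- sqrt((at$x[p] - at$x[q])^2 + (at$y[p] - at$y[q])^2 +
                  (at$z[p] - at$z[q])^2)
        if (d < best) { best <- d; besta <- p; bestb <- q }
      }
      if (best >= cutoff) next
      bb_a <- at$name[besta] %in% c("N", "CA", "C", "O")
      bb_b <- at$name[bestb] %in% c("N", "CA", "C", "O")
      has_sc <- function(i) any(!(at$name[i] %in% c("N", "CA", "C", "O")))
      kind <- if (bb_a && bb_b) "BBBB"
      else if (!bb_a && !bb_b) {
        if (has_sc(ia) && has_sc(ib)) "SCSC" else "BBBB"
      } else if (has_sc(ia) && has_sc(ib)) "SCSC" else "BBBB"
      intra <- at$chain[ia[1]] == at$chain[ib[1]]
      sep <- abs(at$resno[ia[1]] - at$resno[ib[1]])
      if (intra && kind == "BBBB" && sep < min_seq_sep_bb) next
      if (intra && kind == "SCSC" && sep < min_seq_sep_sc) next
      out[[length(out) + 1]] <-
        data.frame(chain_i = at$chain[ia[1]], resid_i = at$resno[ia[1]],
                   chain_j = at$chain[ib[1]], resid_j = at$resno[ib[1]],
                   pair_kind = kind, span = if (intra) "intra" else "inter",
                   stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chain_i = character(0), resid_i = integer(0),
                      chain_j = character(0), resid_j = integer(0),
                      pair_kind = character(0), span = character(0)))
  do.call(rbind, out)
}

#' Bipolar charged coil topology
#'
#' A single flexible chain carrying one block of -1 side chains and one block
#' of +1 side chains, with no native contacts at all, so any compaction is
#' driven purely by non-native Debye-Hueckel attraction between the blocks.
#' This is the testbed for the salt-dependent collapse of a bipolar motif:
#' at low ionic strength the oppositely charged blocks attract over the
#' screening length and the coil compacts; high salt screens the attraction.
#'
#' @param n Residues (default 30).
#' @param acidic_block,basic_block Residue index ranges (vectors), default
#'   5:10 and 20:25.
#' @param charged Logical; FALSE builds the identical chain with all charges
#'   zero.
#' @param Kb,Ka Bond and angle force constants.
#' @return A `cg_topology` (coil: no dihedral, chirality or contact terms).
#' @export
make_bipolar_idp <- function(n = 30, acidic_block = 5:10, basic_block = 20:25,
                             charged = TRUE, Kb = 100, Ka = 10) {
  if (length(intersect(acidic_block, basic_block)) > 0)
    stop("acidic and basic blocks overlap")
  if (min(acidic_block, basic_block) < 1 || max(acidic_block, basic_block) > n)
    stop("blocks must lie within 1..n")
  theta0 <- 2.0
  phi <- rep(c(1, -1), length.out = n - 1) * (pi - theta0) / 2
  ca <- matrix(0, n, 3)
  for (k in 2:n)
    ca[k, ] <- ca[k - 1, ] + 3.8 * c(cos(phi[k - 1]), sin(phi[k - 1]), 0)
  rows <- list()
  for (k in seq_len(n)) {
    res <- if (k %in% acidic_block) "GLU"
    else if (k %in% basic_block) "LYS" else "SER"
    rows[[length(rows) + 1]] <-
      data.frame(kind = c("BB", "SC"), residue_name = res, chain_id = "A",
                 resid = k,
                 x = c(ca[k, 1], ca[k, 1]), y = c(ca[k, 2], ca[k, 2]),
                 z = c(0, 2.3 * (-1)^k),
                 charge = 0, stringsAsFactors = FALSE)
  }
  beads <- do.call(rbind, rows)
  if (charged) beads <- assign_charges(beads)
  bb <- which(beads$kind == "BB")
  bonds <- list(); angles <- list()
  for (t in seq_len(n)) {
    bonds[[length(bonds) + 1]] <- c(bb[t], bb[t] + 1, 2.3, Kb)  # BB-SC
    if (t < n) bonds[[length(bonds) + 1]] <- c(bb[t], bb[t + 1], 3.8, Kb)
    if (t < n - 1)
      angles[[length(angles) + 1]] <- c(bb[t], bb[t + 1], bb[t + 2], theta0, Ka)
  }
  new_topology(beads = beads, bonds = do.call(rbind, bonds),
               angles = do.call(rbind, angles),
               metadata = list(fixture = "bipolar_idp", n = n,
                               acidic_block = range(acidic_block),
                               basic_block = range(basic_block)))
}

#' Gillespie-sampled discrete state series
#'
#' Exact continuous-time Markov simulation over the five binding states,
#' discretized onto a uniform frame grid.  The generator is the ground truth
#' for validating the rate estimators.
#'
#' @param generator 5 x 5 rate matrix with rows/columns named
#'   U, E, I1, I2, B; off-diagonal entries are transition rates (1/time),
#'   diagonal ignored.
#' @param n_frames Frames to emit.
#' @param dt Frame spacing (time units).
#' @param seed RNG seed.
#' @param init Initial state (default "U").
#' @return A `state_series`.
#' @export
make_markov_series <- function(generator, n_frames, dt = 1, seed = 1,
                               init = "U") {
  st <- .state_levels
  if (!all(rownames(generator) == st) || !all(colnames(generator) == st))
    stop("generator must be 5 x 5 with rows/cols named U, E, I1, I2, B")
  if (any(generator[row(generator) != col(generator)] < 0))
    stop("negative transition rate")
  set.seed(seed)
  t_end <- (n_frames - 1) * dt
  jump_t <- 0; jump_s <- init
  tt <- 0; s <- init
  while (tt < t_end) {
    out_rates <- generator[s, ]; out_rates[s] <- 0
    tot <- sum(out_rates)
    if (tot <= 0) break
    tt <- tt + stats::rexp(1, tot)
    if (tt >= t_end) break
    s <- sample(st, 1, prob = out_rates)
    jump_t <- c(jump_t, tt); jump_s <- c(jump_s, s)
  }
  frame_times <- (seq_len(n_frames) - 1) * dt
  states <- jump_s[findInterval(frame_times, jump_t)]
  new_state_series(states, frame_times)
}
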