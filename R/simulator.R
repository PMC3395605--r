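# Langevin dynamics engine: thermodynamic and kinetic trajectories.

#' Simulation parameter set
#'
#' Temperatures are reduced (kT in eps0, k_B = 1); use
#' [reduced_temperature()] to map conventional kelvin temperature labels.  Time is in the
#' reduced unit tau (bead mass 1).
#'
#' @param temperature kT in eps0.
#' @param salt_molar Salt concentration (molar) for the electrostatics.
#' @param timestep Integration step (tau).
#' @param friction Langevin friction gamma (1/tau); 0 gives NVE velocity
#'   Verlet (no thermostat).
#' @param n_steps Number of integration steps.
#' @param save_interval Steps between saved frames.
#' @param seed RNG seed; a fixed seed gives a bitwise-reproducible trajectory.
#' @param initial "native", "frame" (supply `frame`), or an n x 3 matrix.
#' @param frame Optional starting coordinates when `initial = "frame"`.
#' @return List of class `sim_params`.
#' @export
simulation_params <- function(temperature = 1.0, salt_molar = 0.15,
                              timestep = 0.0005, friction = 1.0,
                              n_steps = 1e5, save_interval = 1000,
                              seed = 1, initial = "native", frame = NULL) {
  stopifnot(timestep > 0, n_steps >= 1, save_interval >= 1)
  structure(list(temperature = temperature, salt_molar = salt_molar,
                 timestep = timestep, friction = friction,
                 n_steps = n_steps, save_interval = save_interval,
                 seed = seed, initial = initial, frame = frame),
            class = "sim_params")
}

#' Run a Langevin dynamics trajectory
#'
#' BAOAB-split Langevin integration (or velocity Verlet when `friction = 0`)
#' of the full coarse-grained Hamiltonian.  Initial velocities are drawn from
#' the Maxwell-Boltzmann distribution at the target temperature under the
#' trajectory seed, so a (seed, platform) pair reproduces the trajectory
#' exactly.
#'
#' @param topology A `cg_topology`.
#' @param params A `sim_params`.
#' @param control An `ff_control`; kinetic runs typically enable the
#'   spherical wall.
#' @param elec Optional `dh_params`; by default derived from
#'   `params$salt_molar` and the topology's stored electrostatics constants.
#' @param stop_at_qb Early-stop threshold on the fraction of formed
#'   inter-chain native contacts (NA = never stop early).
#' @param stop_hold Saved frames the threshold must hold before stopping.
#' @param save_velocities Keep per-frame velocities (for thermostat checks).
#' @return A `cg_trajectory`: frames array (frame x bead x 3), per-frame
#'   energy components, times (tau), kinetic temperature, stop reason, params.
#' @export
run <- function(topology, params, control = ff_control(), elec = NULL,
                stop_at_qb = NA, stop_hold = 10, save_velocities = FALSE) {
  if (is.null(elec)) {
    el <- topology$electrostatics
    elec <- electrostatics_params(C = params$salt_molar, eps_r = el$eps_r,
                                  ion_radius_a = el$ion_radius_a,
                                  K_coulomb = el$K_coulomb)
  }
  xyz0 <- if (is.matrix(params$initial)) params$initial
  else if (identical(params$initial, "frame")) {
    if (is.null(params$frame)) stop("initial = 'frame' needs params$frame")
    as.matrix(params$frame)
  } else topology_xyz(topology)
  if (any(!is.finite(xyz0))) stop("non-finite initial coordinates")
  n <- nrow(xyz0)
  set.seed(params$seed)
  v0 <- matrix(rnorm(3 * n, sd = sqrt(max(params$temperature, 0))), n, 3)
  stop_rows <- integer(0)
  if (!is.na(stop_at_qb)) {
    stop_rows <- which(topology$contacts$span == "inter")
    if (length(stop_rows) == 0) stop("stop_at_qb set but no inter-chain contacts")
  }
  res <- cpp_langevin(xyz0, v0, cpp_terms(topology, elec, control),
                      params$timestep, params$friction, params$temperature,
                      params$n_steps, as.integer(params$save_interval),
                      as.integer(stop_rows),
                      if (is.na(stop_at_qb)) 2 else stop_at_qb,
                      as.integer(stop_hold), 1.2, save_velocities)
  if (identical(res$stop_reason, "blowup"))
    stop("energy blow-up at step ", res$stop_step,
         " (|E| > 1e8): reduce the timestep or relax the start")
  ns <- res$n_saved
  # compiled rows are bead-major (x1 y1 z1 x2 ...): unflatten accordingly
  unflat <- function(m) aperm(array(m, dim = c(ns, 3, n)), c(1, 3, 2))
  frames <- unflat(res$frames)
  vel <- if (save_velocities) unflat(res$velocities) else NULL
  last_step <- if (res$stop_step > 0) res$stop_step
    else params$n_steps - params$n_steps %% params$save_interval
  structure(list(frames = frames,
                 energies = as.data.frame(res$energies),
                 times = seq(0, by = params$timestep * params$save_interval,
                             length.out = ns),
                 velocities = vel,
                 kinetic_temperature = res$kinetic_temperature,
                 stop_reason = res$stop_reason,
                 params = params, salt_molar = params$salt_molar,
                 seed = params$seed),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", dim(x$frames)[1], "frames x", dim(x$frames)[2],
      "beads; kT =", x$params$temperature, "; salt =", x$salt_molar,
      "M; stop:", x$stop_reason, "\n")
  invisible(x)
}

#' Extract one frame of a trajectory
#'
#' @param trajectory A `cg_trajectory`.
#' @param t Frame index (1-based).
#' @return n x 3 coordinate matrix.
#' @export
get_frame <- function(trajectory, t) trajectory$frames[t, , ]

# Subset a topology to the beads of one chain (bonded terms + intra contacts).
chain_subtopology <- function(topology, chain_id) {
  keep <- which(topology$beads$chain_id == chain_id)
  remap <- rep(NA_integer_, nrow(topology$beads))
  remap[keep] <- seq_along(keep)
  take <- function(m, k) {
    if (nrow(m) == 0) return(m)
    ok <- apply(m[, 1:k, drop = FALSE], 1, function(r) all(!is.na(remap[r])))
    m <- m[ok, , drop = FALSE]
    if (nrow(m) > 0) m[, 1:k] <- remap[m[, 1:k]]
    m
  }
  contacts <- topology$contacts[!is.na(remap[topology$contacts$i]) &
                                !is.na(remap[topology$contacts$j]), , drop = FALSE]
  if (nrow(contacts) > 0) {
    contacts$i <- remap[contacts$i]; contacts$j <- remap[contacts$j]
  }
  new_topology(beads = topology$beads[keep, , drop = FALSE],
               bonds = take(topology$bonds, 2),
               angles = take(topology$angles, 3),
               dihedrals = take(topology$dihedrals, 4),
               chirality = take(topology$chirality, 4),
               contacts = contacts,
               scale_factors = topology$scale_factors,
               electrostatics = topology$electrostatics,
               metadata = topology$metadata)
}

#' Generate a dissociated starting frame
#'
#' Disorders the flexible (IDP) chain by a short high-temperature run of that
#' chain alone, keeps the other chain at its native conformation, then places
#' the two with a centroid separation of at least `min_separation` and no
#' inter-chain native contact formed.
#'
#' @param topology Two-chain `cg_topology`.
#' @param seed RNG seed.
#' @param min_separation Minimum centroid separation (Angstrom).
#' @param idp_chain Chain id of the disordered chain; default the chain with
#'   fewer residues.
#' @param melt_temperature kT of the disordering run (eps0).
#' @param melt_steps Steps of the disordering run.
#' @return n x 3 starting coordinates.
#' @export
generate_dissociated_start <- function(topology, seed = 1, min_separation = 40,
                                       idp_chain = NULL,
                                       melt_temperature = 2.5,
                                       melt_steps = 2e4) {
  chains <- unique(topology$beads$chain_id)
  if (length(chains) != 2) stop("need a two-chain topology")
  if (is.null(idp_chain)) {
    sizes <- table(topology$beads$chain_id[topology$beads$kind == "BB"])
    idp_chain <- names(sizes)[which.min(sizes)]
  }
  sub <- chain_subtopology(topology, idp_chain)
  melted <- run(sub, simulation_params(temperature = melt_temperature,
                                       timestep = 0.002, friction = 1,
                                       n_steps = melt_steps,
                                       save_interval = melt_steps, seed = seed),
                elec = electrostatics_params(enabled = FALSE))
  idp_xyz <- get_frame(melted, dim(melted$frames)[1])
  idp_rows <- which(topology$beads$chain_id == idp_chain)
  other_rows <- setdiff(seq_len(nrow(topology$beads)), idp_rows)
  xyz <- topology_xyz(topology)
  inter <- topology$contacts[topology$contacts$span == "inter", , drop = FALSE]
  set.seed(seed + 104729L)
  for (attempt in seq_len(100)) {
    # random direction and orientation for the IDP chain
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    th <- runif(1, 0, 2 * pi); ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    cen <- colMeans(idp_xyz)
    placed <- sweep(idp_xyz, 2, cen) %*% t(R)
    target <- colMeans(xyz[other_rows, , drop = FALSE]) +
      u * (min_separation * runif(1, 1, 1.4))
    placed <- sweep(placed, 2, target, "+")
    cand <- xyz
    cand[idp_rows, ] <- placed
    sep <- sqrt(sum((colMeans(cand[idp_rows, , drop = FALSE]) -
                     colMeans(cand[other_rows, , drop = FALSE]))^2))
    if (sep < min_separation) next
    if (nrow(inter) > 0) {
      d <- sqrt(rowSums((cand[inter$i, , drop = FALSE] -
                         cand[inter$j, , drop = FALSE])^2))
      if (any(d < 1.2 * inter$r_native)) next
    }
    # no steric overlap across chains
    cross <- outer(rowSums(cand[idp_rows, , drop = FALSE]^2),
                   rowSums(cand[other_rows, , drop = FALSE]^2), "+") -
      2 * cand[idp_rows, , drop = FALSE] %*% t(cand[other_rows, , drop = FALSE])
    if (min(cross) < 3.5^2) next
    return(cand)
  }
  stop("could not place chains at the requested separation in 100 attempts")
}

#' Run a batch of kinetic binding trajectories
#'
#' Independent seeded low-temperature trajectories from dissociated starts at
#' each salt concentration, stopping early once binding completes (fraction of
#' inter-chain native contacts above `stop_at_qb`, sustained) or at the step
#' cap.
#'
#' @param topology Two-chain `cg_topology`.
#' @param salt_list Salt concentrations (molar).
#' @param n_traj_per_salt Trajectories per concentration.
#' @param seed0 Base seed; trajectory seeds are `seed0 + 0:(total-1)`.
#' @param params Template `sim_params` (temperature, timestep, friction,
#'   n_steps cap, save_interval).
#' @param control `ff_control`; enable the wall so escaped chains return.
#' @param stop_at_qb Binding-completion threshold (default 0.9).
#' @param stop_hold Saved frames the threshold must hold before stopping.
#' @param min_separation Initial centroid separation (Angstrom).
#' @return List of `cg_trajectory` with a `manifest` attribute (data.frame:
#'   trajectory, salt, seed, stop_reason).
#' @export
run_kinetic_batch <- function(topology, salt_list, n_traj_per_salt, seed0 = 1,
                              params = simulation_params(
                                temperature = reduced_temperature(55),
                                timestep = 0.002, friction = 1,
                                n_steps = 5e5, save_interval = 500),
                              control = ff_control(wall_radius = 120),
                              stop_at_qb = 0.9, stop_hold = 10,
                              min_separation = 40) {
  stopifnot(length(salt_list) >= 1, n_traj_per_salt >= 1)
  out <- list(); manifest <- list(); k <- 0
  for (s in salt_list) {
    for (t in seq_len(n_traj_per_salt)) {
      k <- k + 1
      seed <- as.integer(seed0 + k - 1)
      start <- generate_dissociated_start(topology, seed = seed,
                                          min_separation = min_separation)
      p <- params
      p$seed <- seed; p$salt_molar <- s
      p$initial <- "frame"; p$frame <- start
      tr <- run(topology, p, control = control, stop_at_qb = stop_at_qb,
                stop_hold = stop_hold)
      out[[k]] <- tr
      manifest[[k]] <- data.frame(trajectory = k, salt = s, seed = seed,
                                  stop_reason = tr$stop_reason)
    }
  }
  attr(out, "manifest") <- do.call(rbind, manifest)
  out
}
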