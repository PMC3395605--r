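# Independent brute-force energy oracle: plain scalar double loops, written
# separately from the compiled implementation it cross-checks.

oracle_energy <- function(frame, topology, elec, control) {
  n <- nrow(frame)
  d3 <- function(i, j) sqrt(sum((frame[i, ] - frame[j, ])^2))
  e_bond <- 0
  if (nrow(topology$bonds) > 0)
    for (r in seq_len(nrow(topology$bonds))) {
      b <- topology$bonds[r, ]
      e_bond <- e_bond + 0.5 * b[4] * (d3(b[1], b[2]) - b[3])^2
    }
  e_angle <- 0
  if (nrow(topology$angles) > 0)
    for (r in seq_len(nrow(topology$angles))) {
      a <- topology$angles[r, ]
      u <- frame[a[1], ] - frame[a[2], ]; v <- frame[a[3], ] - frame[a[2], ]
      th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
      e_angle <- e_angle + 0.5 * a[5] * (th - a[4])^2
    }
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  e_dih <- 0
  if (nrow(topology$dihedrals) > 0)
    for (r in seq_len(nrow(topology$dihedrals))) {
      q <- topology$dihedrals[r, ]
      b1 <- frame[q[2], ] - frame[q[1], ]; b2 <- frame[q[3], ] - frame[q[2], ]
      b3 <- frame[q[4], ] - frame[q[3], ]
      n1 <- xp(b1, b2); n2 <- xp(b2, b3)
      phi <- atan2(sum(xp(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
      dp <- phi - q[5]
      e_dih <- e_dih + q[6] * ((1 - cos(dp)) + 0.5 * (1 - cos(3 * dp)))
    }
  e_chir <- 0
  if (nrow(topology$chirality) > 0)
    for (r in seq_len(nrow(topology$chirality))) {
      q <- topology$chirality[r, ]
      v1 <- frame[q[2], ] - frame[q[1], ]; v2 <- frame[q[3], ] - frame[q[2], ]
      v3 <- frame[q[4], ] - frame[q[2], ]
      C <- sum(xp(v1, v2) * v3) /
        (sqrt(sum(v1^2)) * sqrt(sum(v2^2)) * sqrt(sum(v3^2)))
      e_chir <- e_chir + q[6] * (C - q[5])^2
    }
  e_ct <- 0
  ct <- topology$contacts
  if (nrow(ct) > 0)
    for (r in seq_len(nrow(ct))) {
      s <- ct$r_native[r] / d3(ct$i[r], ct$j[r])
      e_ct <- e_ct + ct$epsilon[r] * (5 * s^12 - 6 * s^10)
    }
  excl <- nonbonded_exclusions(topology)
  is_excl <- function(i, j) {
    if (nrow(excl) == 0) return(FALSE)
    any(excl[, 1] == min(i, j) & excl[, 2] == max(i, j))
  }
  is_native <- function(i, j)
    any((ct$i == i & ct$j == j) | (ct$i == j & ct$j == i))
  e_ev <- 0
  rc <- 4 * control$ev_sigma
  shift <- control$ev_epsilon * (1 / 4)^12
  if (control$ev_epsilon > 0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (is_excl(i, j) || is_native(i, j)) next
      r <- d3(i, j)
      if (r < rc)
        e_ev <- e_ev + control$ev_epsilon * (control$ev_sigma / r)^12 - shift
    }
  e_dh <- 0
  q <- topology$beads$charge
  if (isTRUE(elec$enabled))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (q[i] == 0 || q[j] == 0 || is_excl(i, j)) next
      r <- d3(i, j)
      e_dh <- e_dh + elec$K_coulomb * elec$B * q[i] * q[j] *
        exp(-elec$kappa * r) / (elec$eps_r * r)
    }
  e_wall <- 0
  if (control$wall_radius > 0)
    for (i in seq_len(n)) {
      r <- sqrt(sum(frame[i, ]^2))
      if (r > control$wall_radius)
        e_wall <- e_wall + 0.5 * control$wall_k * (r - control$wall_radius)^2
    }
  c(bond = e_bond, angle = e_angle, dihedral = e_dih, chirality = e_chir,
    native_contact = e_ct, excluded_volume = e_ev, electrostatic = e_dh,
    wall = e_wall, total = e_bond + e_angle + e_dih + e_chir + e_ct + e_ev +
      e_dh + e_wall)
}
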