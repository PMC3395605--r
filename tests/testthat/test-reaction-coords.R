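dimer_regions <- list(n_helix = c(1, 2), motif = c(0, 0), c_helix = c(3, 4))

test_that("Q coordinates hit their limits on native and separated frames", {
  topo <- fx_dimer_topo
  native <- topology_xyz(topo)
  for (nm in c("Qb", "Qf"))
    expect_equal(fraction_native(native, topo,
                                 q_definition(topo, nm, idp_chain = "A")), 1)
  apart <- native
  b <- topo$beads$chain_id == "B"
  apart[b, 1] <- apart[b, 1] + 500
  expect_equal(fraction_native(apart, topo, q_definition(topo, "Qb")), 0)
})

test_that("a frame with exactly half the subset formed scores 0.5", {
  topo <- fx_salt_topo  # 4 inter contacts, one per residue pair
  qb <- q_definition(topo, "Qb")
  fr <- topology_xyz(topo)
  ct <- topo$contacts[qb$subset, ]
  # break two of the four contacts by displacing their A-side beads
  fr[ct$i[1:2], 3] <- fr[ct$i[1:2], 3] + 50
  formed <- sum(sqrt(rowSums((fr[ct$i, ] - fr[ct$j, ])^2)) <
                  1.2 * ct$r_native)  # independent count
  expect_equal(formed, 2)
  expect_equal(fraction_native(fr, topo, qb), 0.5)
})

test_that("Q never increases under uniform dilation away from native", {
  topo <- fx_dimer_topo
  qb <- q_definition(topo, "Qb")
  center <- colMeans(topology_xyz(topo))
  qs <- vapply(c(1, 1.1, 1.2, 1.35, 1.5, 2, 3), function(s) {
    fr <- sweep(sweep(topology_xyz(topo), 2, center) * s, 2, center, "+")
    fraction_native(fr, topo, qb)
  }, numeric(1))
  expect_true(all(diff(qs) <= 1e-12))
  expect_equal(qs[1], 1)
})

test_that("transition-state selection is an inclusive window", {
  q <- c(0, 0.10, 0.5, 0.13, 0.06, 0.059)
  expect_equal(select_transition_state(q), c(2, 4, 5))
  expect_equal(select_transition_state(q, c(0, 1)), seq_along(q))
  expect_warning(empty <- select_transition_state(c(0.5, 0.9)), "empty")
  expect_length(empty, 0)
})

test_that("phi-values: 1 on the bound ensemble, 0 on the dissociated, 0.5 halfway", {
  topo <- fx_dimer_topo
  native <- topology_xyz(topo)
  apart <- native
  b <- topo$beads$chain_id == "B"
  apart[b, 1] <- apart[b, 1] + 500
  pb <- phi_values(list(native), topo, idp_chain = "B")
  has <- pb$n_bound > 0
  expect_true(any(has))
  expect_true(all(pb$phi[has] == 1))
  pu <- phi_values(list(apart), topo, idp_chain = "B")
  expect_true(all(pu$phi[has] == 0))
  expect_true(all(is.na(pb$phi[!has])))
  # two-frame ensemble, all contacts formed in exactly one frame
  ph <- phi_values(list(native, apart), topo, idp_chain = "B")
  expect_true(all(ph$phi[has] == 0.5))
})

test_that("cutoff contact maps count native and non-native proximity", {
  topo <- fx_dimer_topo
  native <- topology_xyz(topo)
  cm <- cutoff_contact_map(list(native), topo, mode = "BB")
  # every native-contact cell is occupied in the native frame
  expect_true(all(cm$matrix[cm$native_mask] == 1))
  expect_true(all(cm$matrix >= 0 & cm$matrix <= 1))
  expect_true(isSymmetric(cm$matrix))
  # two-frame ensemble: pair within cutoff in exactly one frame scores 0.5
  apart <- native
  b <- topo$beads$chain_id == "B"
  apart[b, 1] <- apart[b, 1] + 500
  cm2 <- cutoff_contact_map(list(native, apart), topo, mode = "BB")
  inter <- outer(cm$mean_contacts$chain_id, cm$mean_contacts$chain_id, "!=")
  touched <- cm$matrix > 0 & inter
  expect_true(all(cm2$matrix[touched] == 0.5))
  # charged-SC map of an uncharged system is empty
  plain <- topo
  plain$beads$charge <- 0
  cmq <- cutoff_contact_map(list(native), plain, mode = "SC-charged")
  expect_true(all(cmq$matrix == 0))
  expect_error(cutoff_contact_map(list(native), topo, mode = "bogus"))
})

test_that("the charged-SC map sees an interface salt bridge", {
  topo <- fx_salt_topo
  cm <- cutoff_contact_map(list(topology_xyz(topo)), topo,
                           mode = "SC-charged")
  expect_gt(sum(cm$matrix), 0)
})

test_that("free-energy surfaces: uniform flatness, two-level gap, 2-D shape", {
  set.seed(5)
  u <- runif(1e6)
  fes <- free_energy_surface(u, bins = 20, limits = list(c(0, 1)))
  expect_lt(max(fes$F, na.rm = TRUE), 0.2)
  # two-level system with occupancy ratio e has a 1 kT gap
  n2 <- 1e4; n1 <- round(exp(1) * n2)
  x <- c(rep(0.25, n1), rep(0.75, n2))
  f2 <- free_energy_surface(x, bins = 2, limits = list(c(0, 1)))
  expect_equal(f2$F[1], 0)
  expect_equal(f2$F[2], 1, tolerance = 1e-3)
  # 2-D surface dimensions follow the bin spec; empty bins are NA not 0
  xy <- cbind(Qb = runif(500), Qf = runif(500))
  f3 <- free_energy_surface(xy, bins = c(8, 6))
  expect_equal(dim(f3$F), c(8, 6))
  expect_true(all(is.na(f3$F[f3$counts == 0])))
  # histogram invariance: duplicating every sample changes nothing
  f4 <- free_energy_surface(c(x, x), bins = 2, limits = list(c(0, 1)))
  expect_equal(f4$F, f2$F)
})

test_that("collapse diagnostics have their closed-form values", {
  one <- matrix(1.5, 4, 3)
  expect_equal(radius_of_gyration(one), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  expect_equal(centroid_distance(rbind(c(0, 0, 0), c(3, 4, 0)), 1, 2), 5)
  expect_error(radius_of_gyration(two, integer(0)), "empty")
  m <- mean_sidechain_distance_map(list(topology_xyz(fx_salt_topo)),
                                   fx_salt_topo)
  expect_true(isSymmetric(unname(m)))
  expect_true(all(diag(m) == 0))
})

test_that("binned profiles average y within x bins", {
  x <- seq(0, 1, length.out = 1000)
  bp <- binned_profile(x, rep(2.5, 1000), bins = 10)
  expect_true(all(bp$mean == 2.5))
  bp2 <- binned_profile(x, x, bins = 10)
  expect_equal(bp2$mean, bp2$center, tolerance = 0.01)
  # a step at x = 0.3 is reproduced bin by bin
  y <- ifelse(x < 0.3, 0, 1)
  bp3 <- binned_profile(x, y, bins = 10)
  expect_true(all(bp3$mean[bp3$center < 0.3] == 0))
  expect_true(all(bp3$mean[bp3$center > 0.3] == 1))
  expect_error(binned_profile(1:3, 1:4), "lengths differ")
})

test_that("regional Q definitions partition the binding interface", {
  topo <- fx_dimer_topo
  qn <- q_definition(topo, "QN", idp_chain = "B", regions = dimer_regions)
  qc <- q_definition(topo, "QC", idp_chain = "B", regions = dimer_regions)
  qb <- q_definition(topo, "Qb")
  expect_length(intersect(qn$subset, qc$subset), 0)
  expect_true(all(c(qn$subset, qc$subset) %in% qb$subset))
  # default region profile carries the documented residue ranges
  expect_equal(chz_regions()$motif, c(94, 115))
  expect_equal(chz_regions()$acidic, c(94, 103))
})
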