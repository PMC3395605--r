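# Order parameters and ensemble analyses: Q coordinates, free-energy
# surfaces, binding phi-values, cutoff contact maps, collapse diagnostics.

#' Define a fraction-of-native-contacts coordinate
#'
#' A Q coordinate is a subset of the native contact list plus a tolerance: a
#' contact is "formed" in a frame when its bead-bead distance is below
#' `tolerance_factor` times its native distance.
#'
#' @param topology A `cg_topology`.
#' @param name One of "Qb" (all inter-chain contacts), "Qf" (intra-chain
#'   contacts of `idp_chain`), "QN"/"QC"/"QMotif" (inter-chain contacts whose
#'   IDP-side residue falls in the named region), or "custom" with explicit
#'   `subset`.
#' @param idp_chain Chain id of the disordered chain (default: fewest
#'   residues).
#' @param regions Named list of residue-id ranges for the regional
#'   coordinates; default [chz_regions()].
#' @param subset Integer rows of `topology$contacts` (for `name = "custom"`).
#' @param tolerance_factor Contact-formed tolerance (default 1.2).
#' @return List of class `q_definition` (name, subset rows, tolerance).
#' @export
q_definition <- function(topology, name = c("Qb", "Qf", "QN", "QC", "QMotif",
                                            "custom"),
                         idp_chain = NULL, regions = chz_regions(),
                         subset = NULL, tolerance_factor = 1.2) {
  name <- match.arg(name)
  ct <- topology$contacts
  if (is.null(idp_chain)) {
    sizes <- table(topology$beads$chain_id[topology$beads$kind == "BB"])
    idp_chain <- names(sizes)[which.min(sizes)]
  }
  chain_i <- topology$beads$chain_id[ct$i]
  chain_j <- topology$beads$chain_id[ct$j]
  resid_i <- topology$beads$resid[ct$i]
  resid_j <- topology$beads$resid[ct$j]
  pick_region <- function(range) {
    idp_res <- ifelse(chain_i == idp_chain, resid_i,
                      ifelse(chain_j == idp_chain, resid_j, NA))
    which(ct$span == "inter" & !is.na(idp_res) &
          idp_res >= range[1] & idp_res <= range[2])
  }
  rows <- switch(name,
    Qb = which(ct$span == "inter"),
    Qf = which(ct$span == "intra" & chain_i == idp_chain),
    QN = pick_region(regions$n_helix),
    QC = pick_region(regions$c_helix),
    QMotif = pick_region(regions$motif),
    custom = subset)
  if (length(rows) == 0) stop("empty contact subset for ", name)
  structure(list(name = name, subset = as.integer(rows),
                 tolerance_factor = tolerance_factor, idp_chain = idp_chain),
            class = "q_definition")
}

#' Region profile of the Chz1 chaperone core
#'
#' Residue-id ranges of the N-terminal helix, the bipolar Chz motif (with its
#' acidic, neutral and basic sub-blocks) and the C-terminal helix, the named
#' default for the chaperone-histone system; override for other systems.
#'
#' @return Named list of c(first, last) residue ids.
#' @export
chz_regions <- function() {
  list(n_helix = c(81, 93), motif = c(94, 115), c_helix = c(116, 132),
       acidic = c(94, 103), neutral = c(104, 111), basic = c(112, 115))
}

#' Fraction of formed native contacts in a frame
#'
#' @param frame n x 3 coordinate matrix.
#' @param topology A `cg_topology`.
#' @param qdef A `q_definition`.
#' @return Q in [0, 1].
#' @export
fraction_native <- function(frame, topology, qdef) {
  ct <- topology$contacts[qdef$subset, , drop = FALSE]
  d <- sqrt(rowSums((frame[ct$i, , drop = FALSE] -
                     frame[ct$j, , drop = FALSE])^2))
  mean(d < qdef$tolerance_factor * ct$r_native)
}

#' Q time series over a trajectory
#'
#' @param trajectory A `cg_trajectory`.
#' @param topology A `cg_topology`.
#' @param qdef A `q_definition`.
#' @return Numeric vector, one Q per saved frame.
#' @export
q_series <- function(trajectory, topology, qdef) {
  vapply(seq_len(dim(trajectory$frames)[1]),
         function(t) fraction_native(trajectory$frames[t, , ], topology, qdef),
         numeric(1))
}

#' Select the transition-state ensemble
#'
#' Frames whose binding coordinate lies inside the (inclusive) window; the
#' default window targets the barrier-top region of the binding free-energy
#' profile.
#'
#' @param q Numeric Q series (one value per frame).
#' @param window Inclusive c(lo, hi); default c(0.06, 0.13).
#' @return Integer frame indices (possibly empty, with a warning).
#' @export
select_transition_state <- function(q, window = c(0.06, 0.13)) {
  idx <- which(q >= window[1] & q <= window[2])
  if (length(idx) == 0) warning("empty transition-state selection")
  idx
}

#' Per-residue binding phi-values
#'
#' For each residue of the disordered chain, the mean number of its native
#' inter-chain contacts formed over the transition-state ensemble divided by
#' its number of native inter-chain contacts in the bound reference.  Only
#' native binding contacts are counted.  Residues with no binding contacts
#' get NA rather than a division by zero.
#'
#' @param frames List of n x 3 matrices, or a trajectory frames array subset.
#' @param topology A `cg_topology`.
#' @param idp_chain Chain id of the disordered chain (default: fewest
#'   residues).
#' @param tolerance_factor Contact-formed tolerance.
#' @return data.frame (resid, n_bound, n_ts_mean, phi) for every residue of
#'   the disordered chain.
#' @export
phi_values <- function(frames, topology, idp_chain = NULL,
                       tolerance_factor = 1.2) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[1]), function(t) frames[t, , ])
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) == 0) stop("empty ensemble")
  if (is.null(idp_chain)) {
    sizes <- table(topology$beads$chain_id[topology$beads$kind == "BB"])
    idp_chain <- names(sizes)[which.min(sizes)]
  }
  ct <- topology$contacts
  inter <- which(ct$span == "inter")
  chain_i <- topology$beads$chain_id[ct$i]
  idp_res <- ifelse(chain_i == idp_chain, topology$beads$resid[ct$i],
                    topology$beads$resid[ct$j])
  residues <- sort(unique(topology$beads$resid[
    topology$beads$chain_id == idp_chain]))
  n_bound <- vapply(residues, function(r) sum(idp_res[inter] == r), numeric(1))
  formed_mean <- rowMeans(vapply(frames, function(fr) {
    d <- sqrt(rowSums((fr[ct$i[inter], , drop = FALSE] -
                       fr[ct$j[inter], , drop = FALSE])^2))
    formed <- d < tolerance_factor * ct$r_native[inter]
    vapply(residues, function(r) sum(formed[idp_res[inter] == r]), numeric(1))
  }, numeric(length(residues))))
  phi <- ifelse(n_bound > 0, formed_mean / n_bound, NA_real_)
  data.frame(resid = residues, n_bound = n_bound, n_ts_mean = formed_mean,
             phi = phi)
}

#' Cutoff contact map over an ensemble
#'
#' Counts native and non-native proximity alike: the probability, over the
#' ensemble, that two residues are within a plain distance cutoff.  Mode "BB"
#' uses backbone beads (default cutoff 8 Angstrom); mode "SC-charged" uses
#' side-chain beads restricted to oppositely charged residue pairs (default
#' 6 Angstrom).  Also returns the per-residue mean number of inter-chain
#' partners within the cutoff.
#'
#' @param frames Ensemble (list of n x 3 matrices or frames array).
#' @param topology A `cg_topology`.
#' @param mode "BB" or "SC-charged".
#' @param cutoff Distance cutoff (Angstrom); default 8 (BB) / 6 (SC-charged).
#' @return List of class `contact_frequency_map`: probability matrix over
#'   residues (global residue order), `native_mask` marking native-contact
#'   cells, `mean_contacts` per residue, `mode`, `cutoff`.
#' @export
cutoff_contact_map <- function(frames, topology, mode = c("BB", "SC-charged"),
                               cutoff = NULL) {
  mode <- match.arg(mode)
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[1]), function(t) frames[t, , ])
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) == 0) stop("empty ensemble")
  if (is.null(cutoff)) cutoff <- if (mode == "BB") 8 else 6
  b <- topology$beads
  bb_rows <- which(b$kind == "BB")
  nres <- length(bb_rows)
  res_chain <- b$chain_id[bb_rows]
  rows <- if (mode == "BB") bb_rows else {
    sc <- rep(NA_integer_, nres)
    is_sc <- which(b$kind == "SC")
    key_bb <- paste(b$chain_id[bb_rows], b$resid[bb_rows])
    key_sc <- paste(b$chain_id[is_sc], b$resid[is_sc])
    sc[match(key_sc, key_bb)] <- is_sc
    sc
  }
  qres <- ifelse(is.na(rows), 0, b$charge[ifelse(is.na(rows), 1, rows)])
  allowed <- if (mode == "BB") matrix(TRUE, nres, nres)
  else outer(qres, qres, "*") < 0
  P <- matrix(0, nres, nres)
  ok <- which(!is.na(rows))
  for (fr in frames) {
    xy <- fr[rows[ok], , drop = FALSE]
    d2 <- outer(rowSums(xy^2), rowSums(xy^2), "+") - 2 * xy %*% t(xy)
    hit <- matrix(0, nres, nres)
    hit[ok, ok] <- (d2 < cutoff^2) * 1
    P <- P + hit * allowed
  }
  P <- P / length(frames)
  diag(P) <- 0
  native <- matrix(FALSE, nres, nres)
  ct <- topology$contacts
  key_bb <- paste(b$chain_id[bb_rows], b$resid[bb_rows])
  ri <- match(paste(b$chain_id[ct$i], b$resid[ct$i]), key_bb)
  rj <- match(paste(b$chain_id[ct$j], b$resid[ct$j]), key_bb)
  native[cbind(ri, rj)] <- TRUE; native[cbind(rj, ri)] <- TRUE
  inter <- outer(res_chain, res_chain, "!=")
  mean_contacts <- rowSums(P * inter)
  structure(list(matrix = P, native_mask = native,
                 mean_contacts = data.frame(chain_id = res_chain,
                                            resid = b$resid[bb_rows],
                                            mean_inter_contacts = mean_contacts),
                 mode = mode, cutoff = cutoff),
            class = "contact_frequency_map")
}

#' Free-energy surface from samples
#'
#' Histograms 1-3 reaction coordinates, converts occupancy to
#' \eqn{F = -kT \ln P} and shifts the minimum to zero.  Empty bins are NA
#' (missing), never zero, so barrier measurements stay explicit.  F is
#' reported in kT units when `kT = 1` (the default).
#'
#' @param samples Numeric vector, or matrix/data.frame with one column per
#'   coordinate.
#' @param bins Number of bins per axis (scalar or per-axis vector).
#' @param kT Temperature factor multiplying ln P.
#' @param limits Optional list of c(lo, hi) per axis.
#' @return List of class `free_energy_surface`: `F` (array), `counts`,
#'   `edges` (list of bin edges), `axes` (names).
#' @export
free_energy_surface <- function(samples, bins = 30, kT = 1, limits = NULL) {
  x <- as.matrix(samples)
  d <- ncol(x)
  if (d > 3) stop("at most 3 coordinates")
  if (nrow(x) < 1) stop("no samples")
  bins <- as.integer(rep(bins, length.out = d))
  edges <- lapply(seq_len(d), function(k) {
    lim <- if (!is.null(limits)) limits[[k]] else range(x[, k])
    if (diff(lim) == 0) lim <- lim + c(-0.5, 0.5)
    seq(lim[1], lim[2], length.out = bins[k] + 1)
  })
  idx <- vapply(seq_len(d), function(k) {
    i <- findInterval(x[, k], edges[[k]], rightmost.closed = TRUE)
    pmin(pmax(i, 1L), bins[k])
  }, integer(nrow(x)))
  idx <- matrix(idx, ncol = d)
  counts <- array(0L, dim = bins)
  tab <- table(apply(idx, 1, paste, collapse = ","))
  for (nm in names(tab)) {
    pos <- as.integer(strsplit(nm, ",")[[1]])
    counts[matrix(pos, 1)] <- as.integer(tab[[nm]])
  }
  if (sum(counts > 0) == 1) warning("all samples fall in a single bin")
  P <- counts / sum(counts)
  F <- ifelse(P > 0, -kT * log(P), NA)
  F <- F - min(F, na.rm = TRUE)
  axes <- colnames(x)
  if (is.null(axes)) axes <- paste0("q", seq_len(d))
  structure(list(F = F, counts = counts, edges = edges, axes = axes, kT = kT),
            class = "free_energy_surface")
}

#' Radius of gyration of a bead selection
#'
#' Mass-uniform Rg about the selection centroid.
#'
#' @param frame n x 3 coordinate matrix.
#' @param selection Integer bead rows (default all).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frame, selection = seq_len(nrow(frame))) {
  if (length(selection) == 0) stop("empty selection")
  x <- frame[selection, , drop = FALSE]
  sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
}

#' Distance between two group centroids
#'
#' @param frame n x 3 coordinate matrix.
#' @param groupA,groupB Integer bead rows.
#' @return Distance in Angstrom between the unweighted centroids.
#' @export
centroid_distance <- function(frame, groupA, groupB) {
  if (length(groupA) == 0 || length(groupB) == 0) stop("empty selection")
  sqrt(sum((colMeans(frame[groupA, , drop = FALSE]) -
            colMeans(frame[groupB, , drop = FALSE]))^2))
}

#' Mean side-chain distance map over an ensemble
#'
#' @param frames Ensemble (list of n x 3 matrices or frames array).
#' @param topology A `cg_topology`.
#' @return Symmetric matrix of mean SC-SC distances (Angstrom), with
#'   chain/resid labels as attributes.
#' @export
mean_sidechain_distance_map <- function(frames, topology) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[1]), function(t) frames[t, , ])
  if (is.matrix(frames)) frames <- list(frames)
  sc <- which(topology$beads$kind == "SC")
  if (length(sc) == 0) stop("no side-chain beads")
  M <- matrix(0, length(sc), length(sc))
  for (fr in frames) {
    x <- fr[sc, , drop = FALSE]
    d2 <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * x %*% t(x)
    M <- M + sqrt(pmax(d2, 0))
  }
  M <- M / length(frames)
  diag(M) <- 0
  attr(M, "chain_id") <- topology$beads$chain_id[sc]
  attr(M, "resid") <- topology$beads$resid[sc]
  M
}

#' Mean of y in bins of x
#'
#' @param x,y Equal-length numeric vectors.
#' @param bins Bin count or explicit break vector for x.
#' @return data.frame (bin center, n, mean, stderr); empty bins carry NA.
#' @export
binned_profile <- function(x, y, bins = 20) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  breaks <- if (length(bins) == 1)
    seq(min(x), max(x), length.out = bins + 1) else bins
  i <- findInterval(x, breaks, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(breaks) - 1L)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  out <- data.frame(center = centers, n = 0L, mean = NA_real_,
                    stderr = NA_real_)
  for (b in seq_along(centers)) {
    yy <- y[i == b]
    out$n[b] <- length(yy)
    if (length(yy) > 0) {
      out$mean[b] <- mean(yy)
      out$stderr[b] <- if (length(yy) > 1) sd(yy) / sqrt(length(yy)) else NA
    }
  }
  out
}
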