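# Discrete-state decomposition of binding trajectories and the six-rate
# encounter / intermediate / bound kinetic analysis.

.state_levels <- c("U", "E", "I1", "I2", "B")

#' State-assignment thresholds
#'
#' The binding process is discretized over five states: unbound (U, no
#' inter-chain proximity), encounter (E, any inter-chain bead pair within the
#' encounter cutoff), two intermediates defined on the regional binding
#' coordinates (I1: QN high and QC low; I2: QC high and QN low), and bound
#' (B, overall Qb high).  States are evaluated in priority order
#' B > I1/I2 > E > U; `qlo < qhi` makes the I1/I2 patterns mutually
#' exclusive.
#'
#' @param qhi,qlo Regional thresholds (defaults 0.6 / 0.2).
#' @param qbound Bound threshold on Qb (default 0.8).
#' @param encounter_cutoff Inter-chain bead distance (Angstrom) defining an
#'   encounter (default 8).
#' @param debounce Saved-frame window; state changes shorter than this are
#'   suppressed (default 5).
#' @return List of class `state_thresholds`.
#' @export
state_thresholds <- function(qhi = 0.6, qlo = 0.2, qbound = 0.8,
                             encounter_cutoff = 8, debounce = 5) {
  stopifnot(qlo < qhi, qhi <= 1)
  structure(list(qhi = qhi, qlo = qlo, qbound = qbound,
                 encounter_cutoff = encounter_cutoff, debounce = debounce),
            class = "state_thresholds")
}

# Merge runs shorter than w frames into the preceding run.
debounce_states <- function(states, w) {
  if (w <= 1 || length(states) < 2) return(states)
  r <- rle(states)
  while (length(r$lengths) > 1 && any(r$lengths[-1] < w)) {
    k <- which(r$lengths[-1] < w)[1] + 1
    r$values[k] <- r$values[k - 1]
    r <- rle(inverse.rle(r))
  }
  inverse.rle(r)
}

#' Assign discrete binding states along a trajectory
#'
#' @param trajectory A `cg_trajectory`.
#' @param topology A `cg_topology` (two chains).
#' @param thresholds A `state_thresholds`.
#' @param regions Region profile for QN/QC (default [chz_regions()]); when
#'   the topology has no contacts in a region the corresponding intermediate
#'   is simply never assigned.
#' @return A `state_series`: list with per-frame `state` factor, `times`,
#'   `salt`, `seed`.
#' @export
assign_states <- function(trajectory, topology,
                          thresholds = state_thresholds(),
                          regions = chz_regions()) {
  qb <- q_series(trajectory, topology, q_definition(topology, "Qb"))
  qn <- tryCatch(q_series(trajectory, topology,
                          q_definition(topology, "QN", regions = regions)),
                 error = function(e) rep(0, length(qb)))
  qc <- tryCatch(q_series(trajectory, topology,
                          q_definition(topology, "QC", regions = regions)),
                 error = function(e) rep(0, length(qb)))
  chains <- topology$beads$chain_id
  a <- which(chains == unique(chains)[1])
  b <- which(chains != unique(chains)[1])
  enc <- vapply(seq_len(dim(trajectory$frames)[1]), function(t) {
    fr <- trajectory$frames[t, , ]
    xa <- fr[a, , drop = FALSE]; xb <- fr[b, , drop = FALSE]
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    min(d2) < thresholds$encounter_cutoff^2
  }, logical(1))
  st <- ifelse(qb >= thresholds$qbound, "B",
        ifelse(qn >= thresholds$qhi & qc <= thresholds$qlo, "I1",
        ifelse(qc >= thresholds$qhi & qn <= thresholds$qlo, "I2",
        ifelse(enc, "E", "U"))))
  st <- debounce_states(st, thresholds$debounce)
  new_state_series(st, trajectory$times, salt = trajectory$salt_molar,
                   seed = trajectory$seed)
}

#' Construct a state series
#'
#' @param states Character vector over the alphabet U, E, I1, I2, B.
#' @param times Monotone time stamps (same length).
#' @param salt,seed Metadata.
#' @return A `state_series`.
#' @export
new_state_series <- function(states, times = seq_along(states) - 1,
                             salt = NA, seed = NA) {
  if (!all(states %in% .state_levels))
    stop("states outside the {U, E, I1, I2, B} alphabet")
  if (length(times) != length(states) || is.unsorted(times))
    stop("times must be monotone and match the states")
  structure(list(state = states, times = as.numeric(times), salt = salt,
                 seed = seed), class = "state_series")
}

.rate_transitions <- data.frame(
  name = c("k1", "k_minus1", "k2_I1", "k2_I2", "k3_I1", "k3_I2"),
  from = c("U", "E", "E", "E", "I1", "I2"),
  to = c("E", "U", "I1", "I2", "B", "B"), stringsAsFactors = FALSE)

#' Per-event first-passage times of a transition
#'
#' For each entry into the origin state, the waiting time until the series
#' leaves it; the event is recorded when the exit goes to the requested
#' target.  The origin is re-armed after every completed event.
#'
#' @param series A `state_series`.
#' @param from,to State labels.
#' @return Numeric vector of waiting times (possibly empty).
#' @export
first_passage_times <- function(series, from, to) {
  r <- rle(series$state)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  out <- numeric(0)
  for (k in seq_along(r$values)) {
    if (r$values[k] != from || k == length(r$values)) next
    if (r$values[k + 1] == to) {
      t_in <- series$times[starts[k]]
      t_out <- series$times[starts[k + 1]]
      out <- c(out, t_out - t_in)
    }
  }
  out
}

# Total time spent in a state; include_censored keeps the trailing
# (unfinished) episode.
time_in_state <- function(series, state, include_censored = FALSE) {
  r <- rle(series$state)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  tot <- 0
  for (k in seq_along(r$values)) {
    if (r$values[k] != state) next
    if (k == length(r$values) && !include_censored) next
    t_in <- series$times[starts[k]]
    t_out <- if (k == length(r$values)) series$times[length(series$times)]
    else series$times[starts[k + 1]]
    tot <- tot + (t_out - t_in)
  }
  tot
}

count_transitions <- function(series, from, to) {
  s <- series$state
  r <- rle(s)$values
  sum(r[-length(r)] == from & r[-1] == to)
}

#' Six-rate decomposition of a trajectory collection
#'
#' Pools transition counts and origin-state occupation times over all series
#' at each salt concentration and reports, for each of the six steps of the
#' binding machine (U->E, E->U, E->I1, E->I2, I1->B, I2->B), the transition
#' count N, the mean passage time MPT = T_origin/N and the rate k = N /
#' T_origin (the maximum-likelihood estimator for competing exits).  A rate
#' with N = 0 is NA.  Uncertainties come from a seeded bootstrap over
#' trajectories.  Trailing censored episodes contribute observation time to
#' their origin state (without this exposure time the estimator is biased
#' upward for slow exits).
#'
#' @param series_list List of `state_series`.
#' @param n_boot Bootstrap resamples (default 200).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return data.frame of class `rate_table`: salt, rate name, from, to, N,
#'   T_origin, MPT, k, k_se (bootstrap), k_lo, k_hi (2.5/97.5 percentiles).
#' @export
rates <- function(series_list, n_boot = 200, boot_seed = 1) {
  stopifnot(length(series_list) >= 1)
  salts <- vapply(series_list, function(s) as.numeric(s$salt), numeric(1))
  salts[is.na(salts)] <- -1
  out <- list()
  pooled_k <- function(idx, tr) {
    N <- sum(vapply(idx, function(j)
      count_transitions(series_list[[j]], tr$from, tr$to), numeric(1)))
    Torig <- sum(vapply(idx, function(j)
      time_in_state(series_list[[j]], tr$from, include_censored = TRUE),
      numeric(1)))
    c(N = N, T = Torig, k = if (N > 0 && Torig > 0) N / Torig else NA_real_)
  }
  for (s in unique(salts)) {
    idx <- which(salts == s)
    for (r in seq_len(nrow(.rate_transitions))) {
      tr <- .rate_transitions[r, ]
      est <- pooled_k(idx, tr)
      set.seed(boot_seed + r)
      kb <- vapply(seq_len(n_boot), function(b) {
        pooled_k(sample(idx, length(idx), replace = TRUE), tr)[["k"]]
      }, numeric(1))
      kb <- kb[is.finite(kb)]
      out[[length(out) + 1]] <- data.frame(
        salt = if (s < 0) NA else s, rate = tr$name, from = tr$from,
        to = tr$to, N = est[["N"]], T_origin = est[["T"]],
        MPT = if (est[["N"]] > 0) est[["T"]] / est[["N"]] else NA_real_,
        k = est[["k"]],
        k_se = if (length(kb) > 1) sd(kb) else NA_real_,
        k_lo = if (length(kb) > 1) unname(quantile(kb, 0.025)) else NA_real_,
        k_hi = if (length(kb) > 1) unname(quantile(kb, 0.975)) else NA_real_)
    }
  }
  structure(do.call(rbind, out), class = c("rate_table", "data.frame"))
}

#' Classify binding pathways
#'
#' For every series that reaches the bound state: the pathway is the identity
#' of the last intermediate visited before first binding ("direct" if none).
#' Optional regional Q series give the first region whose binding coordinate
#' exceeds the completion threshold.  Pathway populations are normalized over
#' bound trajectories; censored (never-bound) series are reported separately.
#'
#' @param series_list List of `state_series`.
#' @param regional_q Optional list (one element per series) of data.frames /
#'   lists with named regional Q series (e.g. N, Motif, C).
#' @param threshold Regional completion threshold (default 0.8).
#' @return List: `records` (per-trajectory pathway and first binder),
#'   `populations` (over {I1, I2, direct}), `n_bound`, `n_censored`.
#' @export
classify_pathways <- function(series_list, regional_q = NULL, threshold = 0.8) {
  recs <- list()
  for (j in seq_along(series_list)) {
    s <- series_list[[j]]
    ib <- match("B", s$state)
    pathway <- "none"
    if (!is.na(ib)) {
      before <- s$state[seq_len(ib - 1)]
      inter <- before[before %in% c("I1", "I2")]
      pathway <- if (length(inter) == 0) "direct" else tail(inter, 1)
    }
    first_binder <- "none"
    if (!is.null(regional_q) && !is.na(ib)) {
      qs <- regional_q[[j]]
      fpt <- vapply(qs, function(q) {
        i <- which(q >= threshold)[1]
        if (is.na(i)) Inf else s$times[i]
      }, numeric(1))
      if (any(is.finite(fpt))) first_binder <- names(qs)[which.min(fpt)]
    }
    recs[[j]] <- data.frame(trajectory = j, bound = !is.na(ib),
                            pathway = pathway, first_binder = first_binder)
  }
  records <- do.call(rbind, recs)
  bound <- records[records$bound, , drop = FALSE]
  pops <- if (nrow(bound) > 0)
    prop.table(table(factor(bound$pathway, c("I1", "I2", "direct"))))
  else table(factor(character(0), c("I1", "I2", "direct")))
  list(records = records, populations = pops, n_bound = nrow(bound),
       n_censored = sum(!records$bound))
}
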