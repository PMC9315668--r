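#' IP3-binding occupancy factors of the IP3 receptor
#'
#' Hill-type saturations of IP3 that scale the calcium affinity of the
#' Active, Open and Inactive states of the four-state receptor model.
#' The inactivation factor uses the condition-dependent prefactor `a3`
#' (the WT/AD difference in inactivation would otherwise be lost).
#'
#' @param ip3 IP3 concentration (uM), vectorized.
#' @param params a [bouton_params()] object (the `$ip3r` block is used).
#' @return A tibble with columns `ip3`, `KO`, `KA`, `KI`.
#' @export
ip3r_occupancy <- function(ip3, params) {
  if (any(ip3 < 0)) stop("ip3 must be >= 0", call. = FALSE)
  g <- params$ip3r
  hill <- function(x, n, K) {
    # overflow-stable form 1 / (1 + (K/x)^n)
    out <- 1 / (1 + (K / x)^n)
    out[x == 0] <- 0
    out
  }
  tibble::tibble(
    ip3 = ip3,
    KO = g$a1 * hill(ip3, g$nO, g$KOd),
    KA = g$a2 * hill(ip3, g$nA, g$KAd),
    KI = g$a3 * hill(ip3, g$nI, g$KId)
  )
}

#' Ligand-dependent transition rates of the four-state IP3R
#'
#' The receptor moves between Rest (R, no Ca2+ bound), Active (A, 2),
#' Open (O, 2) and Inactive (I, 5 Ca2+ bound) along R<->A<->O<->I plus a
#' direct R<->I path.  Each rate is the harmonic composition of
#' sequential Ca2+-binding steps scaled by the occupancy factors; the
#' identities `kAO * KA = kOA * KO = j22` hold for all ligands.
#'
#' @param ca microdomain Ca2+ around the receptor cluster (uM), vectorized.
#' @param ip3 IP3 (uM), scalar or vectorized with `ca`.
#' @param params a [bouton_params()] object.
#' @return A tibble with `ca`, `ip3` and the eight rates (ms^-1)
#'   `kRA, kAR, kAO, kOA, kOI, kIO, kRI, kIR`.
#' @export
ip3r_rates <- function(ca, ip3, params) {
  if (any(ca < 0) || any(ip3 < 0)) stop("ligands must be >= 0", call. = FALSE)
  n <- max(length(ca), length(ip3))
  ca <- rep_len(ca, n); ip3 <- rep_len(ip3, n)
  g <- params$ip3r
  occ <- ip3r_occupancy(ip3, params)

  inv <- function(x) ifelse(x > 0, 1 / x, Inf)
  # series (harmonic) composition of sequential binding steps
  s_ra <- inv(g$j01 * ca) + inv(g$j12 * ca^2)
  s_oi <- inv(g$j23 * ca^3) + inv(g$j45 * ca^5)
  s_ri <- inv(g$jt01 * ca) + inv(g$jt45 * ca^5)

  tibble::tibble(
    ca = ca, ip3 = ip3,
    kRA = 1 / s_ra,
    kAR = 1 / (occ$KA * ca^2 * s_ra),
    kAO = g$j22 / occ$KA,
    kOA = g$j22 / occ$KO,
    kOI = 1 / (occ$KO * ca^2 * s_oi),
    kIO = 1 / (occ$KI * ca^5 * s_oi),
    kRI = 1 / s_ri,
    kIR = 1 / (occ$KI * ca^5 * s_ri)
  )
}

#' Stationary open probability of the IP3 receptor
#'
#' The four-state chain satisfies detailed balance (every cycle balances),
#' so its stationary law has the closed form
#' `pi = (1, KA Ca^2, KO Ca^2, KI Ca^5) / Z` over (R, A, O, I) and
#' `Po = KO Ca^2 / Z`.  The closed form is exact for all ligand values;
#' degenerate ligands (`ca = 0` with `ip3 > 0`) give an absorbing rest
#' state and `Po = 0`.
#'
#' @inheritParams ip3r_rates
#' @return A tibble with `ca`, `ip3`, the stationary probabilities
#'   `pR, pA, pO, pI`, and `po` (= `pO`, the open probability).
#' @export
ip3r_open_probability <- function(ca, ip3, params) {
  if (any(ca < 0) || any(ip3 < 0)) stop("ligands must be >= 0", call. = FALSE)
  n <- max(length(ca), length(ip3))
  ca <- rep_len(ca, n); ip3 <- rep_len(ip3, n)
  occ <- ip3r_occupancy(ip3, params)
  wR <- rep(1, n)
  wA <- occ$KA * ca^2
  wO <- occ$KO * ca^2
  wI <- occ$KI * ca^5
  z <- wR + wA + wO + wI
  if (any(!is.finite(z) | z <= 0)) {
    stop("degenerate ligand values give a singular stationary problem",
         call. = FALSE)
  }
  tibble::tibble(ca = ca, ip3 = ip3,
                 pR = wR / z, pA = wA / z, pO = wO / z, pI = wI / z,
                 po = wO / z)
}

#' Open-probability surface over a ligand grid
#'
#' @param ca,ip3 numeric vectors defining the grid.
#' @param params a [bouton_params()] object.
#' @return A tibble with one row per (ca, ip3) pair and column `po`.
#' @export
ip3r_po_surface <- function(ca, ip3, params) {
  grid <- tidyr::expand_grid(ca = ca, ip3 = ip3)
  ip3r_open_probability(grid$ca, grid$ip3, params)
}

#' Stochastically simulate a single IP3 receptor
#'
#' Fixed-step discrete-time Markov chain, equivalent to the Gillespie
#' algorithm in the small-step limit: per step the channel leaves its
#' state with probability `1 - exp(-k_tot dt)` and the destination is
#' drawn proportionally to the individual rates.  The step is refined
#' automatically (sub-stepping) whenever `k_tot * dt` exceeds 0.05, so
#' the single-transition approximation stays accurate even where exit
#' rates reach thousands per ms.
#'
#' @param ca,ip3 clamped ligand concentrations (uM); scalars.
#' @param t_end simulated time (ms).
#' @param params a [bouton_params()] object.
#' @param dt time step (ms), default 0.001 (1 us).
#' @param seed integer seed; the trajectory is reproducible bit-for-bit.
#' @param state0 initial state, one of `"R"`, `"A"`, `"O"`, `"I"`.
#' @return An object of class `ip3r_trajectory`: a tibble of sojourns
#'   with columns `state` (factor R/A/O/I), `enter` (ms), `duration`
#'   (ms), plus attributes `t_end`, `dt`, `po_emp` (fraction of time
#'   open) and `batch_po` (20 batch-wise open fractions, for Monte-Carlo
#'   standard errors).
#' @export
simulate_ip3r <- function(ca, ip3, t_end, params, dt = 0.001, seed = 1L,
                          state0 = c("R", "A", "O", "I")) {
  stopifnot(length(ca) == 1, length(ip3) == 1, ca >= 0, ip3 >= 0, t_end > 0,
            dt > 0)
  state0 <- match.arg(state0)
  res <- ip3r_simulate_cpp(ca, ip3, t_end, dt,
                           as.integer(seed),
                           match(state0, c("R", "A", "O", "I")) - 1L,
                           unclass(params), 20L)
  traj <- tibble::tibble(
    state = factor(c("R", "A", "O", "I")[res$states + 1L],
                   levels = c("R", "A", "O", "I")),
    enter = res$enter,
    duration = res$duration
  )
  attr(traj, "t_end") <- t_end
  attr(traj, "dt") <- dt
  attr(traj, "po_emp") <- res$po_emp
  attr(traj, "batch_po") <- res$batch_po
  class(traj) <- c("ip3r_trajectory", class(traj))
  traj
}

#' Dwell-time statistics of a channel trajectory
#'
#' Mean open time is the mean contiguous O sojourn; mean closed time is
#' the mean contiguous non-O stretch between openings.  The first and
#' last (censored) sojourns are discarded.
#'
#' @param traj a sojourn tibble as returned by [simulate_ip3r()]
#'   (columns `state`, `enter`, `duration`).
#' @return A one-row tibble: `tau_o` (ms), `tau_c` (ms), `po_emp`,
#'   `n_openings`.
#' @export
dwell_time_stats <- function(traj) {
  open <- traj$state == "O"
  if (!any(open)) {
    stop("trajectory contains no openings; dwell statistics undefined",
         call. = FALSE)
  }
  # collapse consecutive non-O sojourns into closed stretches
  grp <- cumsum(c(TRUE, diff(open) != 0))
  runs <- tibble::tibble(open = open, dur = traj$duration) |>
    dplyr::mutate(grp = grp) |>
    dplyr::summarise(open = dplyr::first(.data$open),
                     dur = sum(.data$dur), .by = "grp")
  n <- nrow(runs)
  if (n > 2) runs <- runs[2:(n - 1), , drop = FALSE] # censor both ends
  if (!any(runs$open) || !any(!runs$open)) {
    stop("too few complete sojourns for dwell statistics", call. = FALSE)
  }
  total_open <- sum(traj$duration[open])
  tibble::tibble(
    tau_o = mean(runs$dur[runs$open]),
    tau_c = mean(runs$dur[!runs$open]),
    po_emp = total_open / sum(traj$duration),
    n_openings = sum(runs$open)
  )
}

#' Open fraction of a channel cluster
#'
#' @param states integer or factor vector of per-channel states, coded
#'   as in [simulate_ip3r()] (`"O"` marks an open channel), or a logical
#'   vector of open indicators.
#' @return The fraction of channels open, in `{0, 1/N, ..., 1}`.
#' @export
cluster_open_fraction <- function(states) {
  if (length(states) < 1) stop("empty cluster", call. = FALSE)
  if (is.logical(states)) return(mean(states))
  mean(states == "O" | states == 2L)
}
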