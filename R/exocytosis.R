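#' Vesicle pool kinetics right-hand side
#'
#' Mass-action flow between the reserve (R), docked-unprimed (U), primed
#' channel-detached (V, the slow-releasing pool) and channel-attached
#' (W, the fast-releasing pool) populations:
#' R<->U at (`kmob * Ca_cyt`, `kdemob`); U->V at `kpriming * Ca_cyt`
#' gated by free non-refractory release sites; V->U at `kunpr`; V<->W at
#' (`kattach * Ca_AZ`, `kdetach`).  The availability gate is
#' `min(free, 1)`: priming proceeds at full rate while at least one site
#' is free.
#'
#' @param pools list or one-row data frame with `R`, `U`, `V`, `W`,
#'   `refractory` (vesicle/site counts, possibly fractional).
#' @param ca_cyt,ca_az driving Ca2+ concentrations (uM).
#' @param params a [bouton_params()] object.
#' @return A one-row tibble `dR`, `dU`, `dV`, `dW` (vesicles/ms);
#'   fusion and refractory-recovery terms are handled by the sensor and
#'   site machinery, not here.
#' @export
pool_rhs <- function(pools, ca_cyt, ca_az, params) {
  r <- params$release
  free <- params$pools$N_sites - pools$V - pools$W - pools$refractory
  gate <- pmin(pmax(free, 0), 1)
  f_mob <- r$kmob * ca_cyt * pools$R
  f_demob <- r$kdemob * pools$U
  f_prime <- r$kpriming * ca_cyt * pools$U * gate
  f_unpr <- r$kunpr * pools$V
  f_attach <- r$kattach * ca_az * pools$V
  f_detach <- r$kdetach * pools$W
  tibble::tibble(
    dR = f_demob - f_mob,
    dU = f_mob - f_demob - f_prime + f_unpr,
    dV = f_prime - f_unpr - f_attach + f_detach,
    dW = f_attach - f_detach
  )
}

#' Dual-sensor occupancy right-hand side
#'
#' The synchronous sensor S carries five Ca2+ binding sites (occupancy
#' `m`), the asynchronous sensor A two (occupancy `n`); both act in
#' parallel on each vesicle.  Forward binding is `(5-m) alpha Ca` and
#' `(2-n) lambda Ca`; unbinding is slowed by the cooperativity factor,
#' `m beta b^(m-1)` and `n delta b^(n-1)`.  Fusion hazards: `gamma2`
#' from any state with `m = 5` (synchronous), `gamma3 = a gamma2` from
#' any state with `n = 2` (asynchronous), and `gamma1` from `(0, 0)`
#' (spontaneous).
#'
#' @param occupancy 6 x 3 numeric matrix; entry `[m+1, n+1]` is the
#'   vesicle mass with `m` Ca2+ on S and `n` on A.
#' @param ca driving Ca2+ (uM).
#' @param params a [bouton_params()] object.
#' @return list with `doccupancy` (6 x 3 matrix of derivatives,
#'   excluding fusion losses), `fusion` (6 x 3 matrix of total fusion
#'   hazard x mass), and scalar expected rates `rate_sync`,
#'   `rate_async`, `rate_spont` (vesicles/ms).
#' @export
sensor_rhs <- function(occupancy, ca, params) {
  r <- params$release
  stopifnot(identical(dim(occupancy), c(6L, 3L)))
  if (any(occupancy < -1e-9)) stop("negative occupancy mass", call. = FALSE)
  d <- matrix(0, 6, 3)
  m_idx <- 0:5; n_idx <- 0:2
  for (m in m_idx) {
    for (n in n_idx) {
      x <- occupancy[m + 1, n + 1]
      out <- 0
      if (m < 5) { f <- (5 - m) * r$alpha * ca * x; out <- out + f; d[m + 2, n + 1] <- d[m + 2, n + 1] + f }
      if (m > 0) { f <- m * r$beta * r$b^(m - 1) * x; out <- out + f; d[m, n + 1] <- d[m, n + 1] + f }
      if (n < 2) { f <- (2 - n) * r$lambda * ca * x; out <- out + f; d[m + 1, n + 2] <- d[m + 1, n + 2] + f }
      if (n > 0) { f <- n * r$delta * r$b^(n - 1) * x; out <- out + f; d[m + 1, n] <- d[m + 1, n] + f }
      d[m + 1, n + 1] <- d[m + 1, n + 1] - out
    }
  }
  gamma3 <- r$a * r$gamma2
  haz <- matrix(0, 6, 3)
  haz[6, ] <- haz[6, ] + r$gamma2
  haz[, 3] <- haz[, 3] + gamma3
  haz[1, 1] <- haz[1, 1] + r$gamma1
  fusion <- haz * occupancy
  list(
    doccupancy = d,
    fusion = fusion,
    rate_sync = r$gamma2 * sum(occupancy[6, ]),
    rate_async = gamma3 * sum(occupancy[, 3]),
    rate_spont = r$gamma1 * occupancy[1, 1]
  )
}

#' Stationary dual-sensor occupancy at clamped Ca2+
#'
#' Closed form for the birth-death chains of each sensor:
#' `pi_m ∝ C(5,m) (alpha Ca / beta)^m b^{-m(m-1)/2}` (S sensor) and
#' the analogous two-site law for A.
#'
#' @param ca clamped Ca2+ (uM).
#' @param params a [bouton_params()] object.
#' @return list with `pS` (length 6), `pA` (length 3), and `p00`.
#' @export
sensor_stationary <- function(ca, params) {
  r <- params$release
  xs <- r$alpha * ca / r$beta
  xa <- r$lambda * ca / r$delta
  m <- 0:5; n <- 0:2
  wS <- choose(5, m) * xs^m * r$b^(-m * (m - 1) / 2)
  wA <- choose(2, n) * xa^n * r$b^(-n * (n - 1) / 2)
  pS <- wS / sum(wS); pA <- wA / sum(wA)
  list(pS = pS, pA = pA, p00 = pS[1] * pA[1])
}

#' Resting spontaneous release rate
#'
#' Total spontaneous ((0,0)-state) fusion hazard of the default vesicle
#' configuration with sensors relaxed at the clamped Ca2+ levels: the
#' detached (V) vesicles read the cytosolic clamp, the channel-attached
#' (W) fraction reads the resting active-zone Ca2+.  Pool sizes stay at
#' their defaults (the fully primed readily-releasable pool); the slow
#' R<->U<->V redistribution, which operates on a timescale of minutes
#' and is maintained by processes outside the model, is deliberately
#' excluded from "resting".
#'
#' @param ca_cyt_rest clamped cytosolic Ca2+ (uM); default 0.1.
#' @param params a [bouton_params()] object.
#' @param ca_az_rest active-zone Ca2+ (uM); default the resting value.
#' @return Spontaneous release rate in ms^-1.
#' @export
steady_state_spontaneous_rate <- function(ca_cyt_rest = 0.1, params,
                                          ca_az_rest = params$calcium$ca_az0) {
  r <- params$release
  wfrac <- r$kattach * ca_az_rest / (r$kattach * ca_az_rest + r$kdetach)
  rrp <- params$pools$N_sites
  p00_V <- sensor_stationary(ca_cyt_rest, params)$p00
  p00_W <- sensor_stationary(ca_az_rest, params)$p00
  r$gamma1 * rrp * ((1 - wfrac) * p00_V + wfrac * p00_W)
}

#' Release probability from an event log
#'
#' Vesicles released during the scoring window divided by the initial
#' size of the readily releasable pool (V + W at simulation start).
#'
#' @param events event-log tibble with a `time` column (ms), as in
#'   [simulate_bouton()] results.
#' @param window length-2 numeric `(start, end)` in ms; defaults to the
#'   whole log.
#' @param initial_rrp initial RRP size (> 0).
#' @return Release probability in `[0, 1]` (can exceed 1 only if sites
#'   re-prime and re-release within the window; by construction of the
#'   scoring windows this does not occur).
#' @export
release_probability <- function(events, window = c(-Inf, Inf), initial_rrp) {
  if (initial_rrp <= 0) stop("initial RRP must be > 0", call. = FALSE)
  n <- sum(events$time >= window[1] & events$time < window[2])
  n / initial_rrp
}

# default deterministic initial condition for the release subsystem:
# all sites primed, V/W split at the resting attach/detach equilibrium,
# sensors empty, reserve full.
release_init_state <- function(params, ca_az0 = params$calcium$ca_az0) {
  r <- params$release
  ns <- params$pools$N_sites
  wfrac <- r$kattach * ca_az0 / (r$kattach * ca_az0 + r$kdetach)
  xV <- matrix(0, 6, 3); xW <- matrix(0, 6, 3)
  xV[1, 1] <- ns * (1 - wfrac)
  xW[1, 1] <- ns * wfrac
  c(as.vector(xV), as.vector(xW), U = 0, R = params$pools$N_reserve,
    FR = 0, cum_spont = 0, cum_sync = 0, cum_async = 0)
}

#' Deterministic (mass-action expectation) release dynamics
#'
#' Integrates the occupancy-density ODEs of the full release scheme —
#' pools, dual sensors for the V (cytosol-driven) and W (AZ-driven)
#' vesicles, fusion and site refractoriness — for a prescribed Ca2+
#' waveform.  This is the expectation of the stochastic per-vesicle
#' model with the same rate definitions.
#'
#' @param ca_cyt,ca_az either scalars (clamp) or functions of time (ms)
#'   returning uM.
#' @param t_end integration time (ms).
#' @param params a [bouton_params()] object.
#' @param dt_out output sampling interval (ms).
#' @return A tibble with `time`, pool masses (`R`, `U`, `V`, `W`,
#'   `refractory`), release rates (`rate_total`, `rate_sync`,
#'   `rate_async`, `rate_spont`, vesicles/ms) and cumulative releases.
#' @export
release_ode <- function(ca_cyt, ca_az, t_end, params, dt_out = 0.5) {
  fcyt <- if (is.function(ca_cyt)) ca_cyt else function(t) ca_cyt
  faz <- if (is.function(ca_az)) ca_az else function(t) ca_az
  r <- params$release
  ns <- params$pools$N_sites
  gamma3 <- r$a * r$gamma2

  rhs <- function(t, y, parms) {
    xV <- matrix(y[1:18], 6, 3)
    xW <- matrix(y[19:36], 6, 3)
    U <- y[37]; R <- y[38]; FR <- y[39]
    cc <- fcyt(t); cz <- faz(t)

    sV <- sensor_rhs(xV, cc, params)
    sW <- sensor_rhs(xW, cz, params)

    free <- ns - sum(xV) - sum(xW) - FR
    gate <- min(max(free, 0), 1)
    f_mob <- r$kmob * cc * R
    f_demob <- r$kdemob * U
    f_prime <- r$kpriming * cc * U * gate
    f_unpr_m <- r$kunpr * xV            # per-state unpriming (V only)
    f_att_m <- r$kattach * cz * xV      # V -> W, sensors carried
    f_det_m <- r$kdetach * xW

    dV <- sV$doccupancy - sV$fusion - f_unpr_m - f_att_m + f_det_m
    dW <- sW$doccupancy - sW$fusion + f_att_m - f_det_m
    dV[1, 1] <- dV[1, 1] + f_prime
    dU <- f_mob - f_demob - f_prime + sum(f_unpr_m)
    dR <- f_demob - f_mob
    fus_tot <- sum(sV$fusion) + sum(sW$fusion)
    dFR <- fus_tot - r$kRF * FR
    list(c(as.vector(dV), as.vector(dW), dU, dR, dFR,
           sV$rate_spont + sW$rate_spont,
           sV$rate_sync + sW$rate_sync,
           sV$rate_async + sW$rate_async))
  }

  y0 <- release_init_state(params, faz(0))
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::ode(y = unname(y0), times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  xVs <- sol[, 2:19, drop = FALSE]
  xWs <- sol[, 20:37, drop = FALSE]
  # fusion-state masses: m = 5 rows are indices 6,12,18 of the 6x3
  # column-major layout; n = 2 states are indices 13:18; (0,0) is 1.
  m5 <- c(6, 12, 18); n2 <- 13:18
  rate_sync <- r$gamma2 * (rowSums(xVs[, m5, drop = FALSE]) +
                             rowSums(xWs[, m5, drop = FALSE]))
  rate_async <- gamma3 * (rowSums(xVs[, n2, drop = FALSE]) +
                            rowSums(xWs[, n2, drop = FALSE]))
  rate_spont <- r$gamma1 * (xVs[, 1] + xWs[, 1])
  tibble::tibble(
    time = sol[, 1],
    R = sol[, 39], U = sol[, 38],
    V = rowSums(xVs), W = rowSums(xWs),
    refractory = sol[, 40],
    rate_sync = rate_sync, rate_async = rate_async, rate_spont = rate_spont,
    rate_total = rate_sync + rate_async + rate_spont,
    cum_spont = sol[, 41], cum_sync = sol[, 42], cum_async = sol[, 43]
  )
}

#' Stochastic release on a prescribed Ca2+ waveform
#'
#' Per-vesicle discrete-time Markov simulation of the release scheme
#' with the same rate definitions as [release_ode()].
#'
#' @param ca_cyt,ca_az scalars (clamp) or numeric vectors sampled at
#'   `dt` (uM).
#' @param t_end simulated time (ms).
#' @param params a [bouton_params()] object.
#' @param dt time step (ms).
#' @param seed,trial integers selecting the random substream.
#' @param record_every store every k-th step in the pool trace; 0
#'   disables the trace.
#' @return list with `trace` (tibble: time, release_rate, pools,
#'   cumulative releases), `events` (tibble: time, mode, pool) and
#'   `cum_release` (named vector).
#' @export
release_stochastic <- function(ca_cyt, ca_az, t_end, params, dt = 0.001,
                               seed = 1L, trial = 0L, record_every = 100L) {
  res <- release_simulate_cpp(as.numeric(ca_cyt), as.numeric(ca_az),
                              t_end, dt, unclass(params), as.integer(seed),
                              as.integer(trial), as.integer(record_every))
  nr <- as.integer(res$n_rec)
  tr <- res$trace[seq_len(nr), , drop = FALSE]
  colnames(tr) <- c("time", "release_rate", "R", "U", "V", "W",
                    "refractory", "cum_spont", "cum_sync", "cum_async")
  list(
    trace = tibble::as_tibble(tr),
    events = tibble::tibble(
      time = res$events$time,
      mode = factor(c("spont", "sync", "async")[res$events$mode],
                    levels = c("spont", "sync", "async")),
      pool = factor(c("V", "W")[res$events$pool + 1L], levels = c("V", "W"))
    ),
    cum_release = stats::setNames(res$cum_release, c("spont", "sync", "async")),
    vesicles_left = res$vesicles_left,
    n_refractory = res$n_refractory
  )
}

#' Apply fusion-driven refractoriness to release sites
#'
#' A site whose vesicle fused cannot accept a new primed vesicle until
#' it recovers, which happens at rate `kRF` (mean refractory dwell
#' `1/kRF`, 100 ms at the default 0.01 ms^-1).  This operation marks
#' fused sites refractory and, when a time step is given, recovers
#' refractory sites stochastically with probability `1 - exp(-kRF dt)`.
#'
#' @param sites a tibble/data frame with a `status` column coded
#'   `"free"`, `"refractory"` or `"occupied"`.
#' @param fused integer indices of sites whose vesicle fused this step.
#' @param params a [bouton_params()] object.
#' @param dt optional time step (ms) over which refractory sites may
#'   recover (uses R's RNG; set a seed for reproducibility).
#' @return The updated site tibble.
#' @export
apply_refractoriness <- function(sites, fused = integer(0), params,
                                 dt = NULL) {
  status <- as.character(sites$status)
  if (length(fused) > 0) {
    stopifnot(all(status[fused] == "occupied"))
    status[fused] <- "refractory"
  }
  if (!is.null(dt)) {
    refr <- which(status == "refractory")
    if (length(refr) > 0) {
      p <- 1 - exp(-params$release$kRF * dt)
      rec <- refr[stats::runif(length(refr)) < p]
      status[rec] <- "free"
    }
  }
  sites$status <- factor(status, levels = c("free", "refractory", "occupied"))
  sites
}
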