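#' Voltage-dependent transition rates of the Cav2.1 channel
#'
#' Five-state kinetic scheme C1<->C2<->C3<->C4<->O.  Activation rates
#' grow e-fold per `k_i` mV, `alpha_i(V) = alpha_i0 exp(V/k_i)`;
#' deactivation rates fall e-fold per `k_i` mV,
#' `beta_i(V) = beta_i0 exp(-V/k_i)`, which gives the scheme its
#' high-threshold voltage dependence (the channel is essentially shut at
#' rest and activates during the action potential).
#'
#' @param V membrane potential (mV), vectorized.
#' @param params a [bouton_params()] object.
#' @return A tibble with `V` and columns `alpha1..alpha4`,
#'   `beta1..beta4` (ms^-1).
#' @export
vgcc_rates <- function(V, params) {
  g <- params$vgcc
  out <- tibble::tibble(V = V)
  for (i in 1:4) {
    out[[paste0("alpha", i)]] <- g$alpha0[i] * exp(V / g$k[i])
    out[[paste0("beta", i)]] <- g$beta0[i] * exp(-V / g$k[i])
  }
  out
}

#' Stationary distribution of the five-state Cav2.1 chain at fixed voltage
#'
#' @param V membrane potential (mV), scalar.
#' @param params a [bouton_params()] object.
#' @return A tibble with one row per state (`C1..C4`, `O`) and column
#'   `p`, the stationary probability.
#' @export
vgcc_stationary <- function(V, params) {
  r <- vgcc_rates(V, params)
  ratios <- vapply(1:4, function(i) r[[paste0("alpha", i)]] / r[[paste0("beta", i)]],
                   numeric(1))
  w <- cumprod(c(1, ratios))
  tibble::tibble(state = c("C1", "C2", "C3", "C4", "O"), p = w / sum(w))
}

#' Stochastically simulate a cluster of Cav2.1 channels
#'
#' Each channel is an independent discrete-time Markov chain driven by
#' the (possibly time-varying) voltage; the open fraction
#' `Po(t) = N_open / N` is recorded on the input time grid.
#'
#' @param V_trace numeric vector of membrane potential samples (mV),
#'   one per time step, or a scalar for a voltage clamp.
#' @param t_end simulated time (ms); the voltage trace is sampled at
#'   `dt` so `length(V_trace)` must be 1 or `round(t_end/dt)`.
#' @param params a [bouton_params()] object (`$vgcc$N_VGCC` channels).
#' @param dt time step (ms).
#' @param seed integer seed.
#' @return A tibble with columns `time` (ms), `open_fraction`, and
#'   `n_open`.
#' @export
simulate_vgcc_cluster <- function(V_trace, t_end, params, dt = 0.001,
                                  seed = 1L) {
  n_steps <- as.integer(round(t_end / dt))
  if (length(V_trace) == 1) V_trace <- rep(V_trace, n_steps)
  if (length(V_trace) != n_steps) {
    stop("V_trace must have length 1 or round(t_end/dt)", call. = FALSE)
  }
  res <- vgcc_simulate_cpp(V_trace, dt, as.integer(seed),
                           unclass(params))
  tibble::tibble(
    time = seq_len(n_steps) * dt,
    open_fraction = res$open_fraction,
    n_open = as.integer(res$n_open)
  )
}

#' Single-channel Cav2.1 current
#'
#' Ohmic form `Is = g * Po * (V - E_Ca)`; with pS and mV in, the result
#' is in fA.  Negative values are inward.
#'
#' @param V membrane potential (mV).
#' @param Po open probability (or open fraction) in `[0, 1]`.
#' @param params a [bouton_params()] object.
#' @return Current in fA (vectorized over `V`/`Po`).
#' @export
vgcc_current <- function(V, Po, params) {
  if (any(Po < 0 | Po > 1)) stop("Po must lie in [0, 1]", call. = FALSE)
  params$vgcc$g * Po * (V - params$vgcc$E_Ca)
}

#' Calcium flux through the VGCC cluster
#'
#' Converts the single-channel current to a bouton-referenced Ca2+ flux:
#' `ICa = [N_VGCC / (AZ_area * N_AZ)] * cluster_area * Is` and
#' `J_VGCC = -ICa / (z F V_eff)`.  The flux is positive for inward
#' current (Ca2+ added to the terminal); the active-zone equation scales
#' it by the volume ratio `delta3` to express the microdomain
#' concentration change.
#'
#' @param Is single-channel current (fA), from [vgcc_current()].
#' @param params a [bouton_params()] object.
#' @return Flux in uM/ms (bouton-referenced; vectorized).
#' @export
vgcc_flux <- function(Is, params) {
  g <- params$vgcc
  density <- g$N_VGCC / (g$AZ_area * g$N_AZ) # channels / um^2
  ica_fa <- density * g$cluster_area * Is
  # fA -> mol/s: 1e-15 / (zF); / V_eff [L] -> mol/L/s; -> uM/ms: x 1e3
  -ica_fa * 1e-15 / (g$z * g$Faraday * g$V_eff) * 1e3
}
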