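#' Hodgkin-Huxley gating rates of the bouton membrane
#'
#' Forward/backward rates for the K+ activation (`n`), Na+ inactivation
#' (`h`) and Na+ activation (`m`) gates.  The two removable
#' singularities (`alpha_n` at V = -34 mV, `alpha_m` at V = -30 mV) are
#' evaluated by their analytic limits.
#'
#' @param V membrane potential (mV), vectorized.
#' @return A tibble with `V`, `alpha_n`, `beta_n`, `alpha_h`, `beta_h`,
#'   `alpha_m`, `beta_m`, and `m_inf` (= `alpha_m/(alpha_m+beta_m)`,
#'   the instantaneous Na+ activation).
#' @export
hh_rates <- function(V) {
  lin_exp <- function(a, x, s) {
    # a * x / (1 - exp(-x/s)); limit a*s as x -> 0
    out <- a * x / (1 - exp(-x / s))
    out[abs(x) < 1e-9] <- a * s
    out
  }
  alpha_n <- lin_exp(0.01, V + 34, 10)
  beta_n <- 0.125 * exp(-(V + 44) / 80)
  alpha_h <- 0.07 * exp(-(V + 44) / 20)
  beta_h <- 1 / (1 + exp(-(V + 14) / 10))
  alpha_m <- lin_exp(0.1, V + 30, 10)
  beta_m <- 4 * exp(-(V + 55) / 18)
  tibble::tibble(V = V, alpha_n = alpha_n, beta_n = beta_n,
                 alpha_h = alpha_h, beta_h = beta_h,
                 alpha_m = alpha_m, beta_m = beta_m,
                 m_inf = alpha_m / (alpha_m + beta_m))
}

#' Membrane right-hand side
#'
#' Current balance of the bouton membrane:
#' `Cm dV/dt = Iapp + INa + IK + ICl - ICa/Area`, with
#' `INa = -(gNa m_inf^3 h)(V-ENa) - gNaleak (V-ENa)`,
#' `IK = -(gK n^4 + gAHP Ca/(1+Ca))(V-EK) - gKleak (V-EK)`,
#' `ICl = -gClleak (V-ECl)`, and the Na+ activation gate instantaneous.
#' The inward (negative) cluster Ca2+ current enters with a minus sign
#' so that Ca2+ influx depolarizes, consistent with the sign convention
#' of the other currents.  Gate kinetics are accelerated by `phi`.
#'
#' @param V membrane potential (mV).
#' @param n,h gating variables in `[0, 1]`.
#' @param Iapp applied current (uA/cm^2).
#' @param ca_cyt cytosolic Ca2+ (uM), for the after-hyperpolarization
#'   (AHP) K+ conductance.
#' @param I_Ca cluster Ca2+ current (fA; negative = inward).
#' @param params a [bouton_params()] object.
#' @return A tibble with `dV`, `dn`, `dh` (per ms) and the individual
#'   current densities `INa`, `IK`, `ICl`, `ICa_density` (uA/cm^2).
#' @export
membrane_rhs <- function(V, n, h, Iapp, ca_cyt, I_Ca, params) {
  m <- params$membrane
  r <- hh_rates(V)
  INa <- -(m$gNa * r$m_inf^3 * h) * (V - m$E_Na) - m$gNaleak * (V - m$E_Na)
  IK <- -(m$gK * n^4 + m$gAHP * ca_cyt / (1 + ca_cyt)) * (V - m$E_K) -
    m$gKleak * (V - m$E_K)
  ICl <- -m$gClleak * (V - m$E_Cl)
  ICa_density <- I_Ca * 1e-9 / m$area_cm2 # fA -> uA, per cm^2
  dV <- (Iapp + INa + IK + ICl - ICa_density) / m$Cm
  dn <- m$phi * (r$alpha_n * (1 - n) - r$beta_n * n)
  dh <- m$phi * (r$alpha_h * (1 - h) - r$beta_h * h)
  tibble::tibble(dV = dV, dn = dn, dh = dh,
                 INa = INa, IK = IK, ICl = ICl, ICa_density = ICa_density)
}

#' Build a stimulation protocol
#'
#' Rectangular current pulses that each evoke one action potential.
#' Defaults: single pulse at `t0`; paired pulses 40 ms apart; train of
#' 20 pulses at 20 Hz (50 ms spacing).
#'
#' @param kind `"single"`, `"paired"` or `"train"`.
#' @param t0 onset of the first pulse (ms).
#' @param interval inter-pulse interval (ms); 40 for `paired`, 50
#'   (20 Hz) for `train` by default.
#' @param n_pulses number of pulses (trains only; default 20).
#' @param amplitude pulse amplitude (uA/cm^2).
#' @param width pulse width (ms).
#' @return An object of class `stim_protocol`: list with `onsets` (ms),
#'   `amplitude`, `width`, `kind`.
#' @examples
#' make_protocol("paired")$onsets # 50, 90
#' @export
make_protocol <- function(kind = c("single", "paired", "train"),
                          t0 = 50, interval = NULL, n_pulses = NULL,
                          amplitude = 20, width = 1) {
  kind <- match.arg(kind)
  if (is.null(interval)) interval <- switch(kind, single = NA_real_,
                                            paired = 40, train = 50)
  if (kind != "single" && (!is.finite(interval) || interval <= 0)) {
    stop("interval must be positive", call. = FALSE)
  }
  onsets <- switch(kind,
    single = t0,
    paired = c(t0, t0 + interval),
    train = t0 + interval * (seq_len(if (is.null(n_pulses)) 20L else n_pulses) - 1)
  )
  structure(list(onsets = onsets, amplitude = amplitude, width = width,
                 kind = kind),
            class = "stim_protocol")
}

#' Count action potentials in a voltage trace
#'
#' An AP is an upward crossing of 0 mV.
#'
#' @param trace a tibble with columns `time` and `V` (as in
#'   [simulate_bouton()] traces).
#' @return Numeric vector of AP times (ms; time of the first sample at
#'   or above 0 mV in each crossing).
#' @export
ap_times <- function(trace) {
  above <- trace$V >= 0
  idx <- which(above & !c(FALSE, above[-length(above)]))
  trace$time[idx]
}
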